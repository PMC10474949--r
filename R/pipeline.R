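## Run configuration, SAXS data simulation, the end-to-end pipeline and
## its manifest/logging plumbing.

#' Simulate a noisy SAXS curve from a model
#'
#' Computes the Debye curve on the uniform grid `(0.005, q_max]` with
#' `n_points` points, then perturbs each intensity with Gaussian noise of
#' standard deviation `sigma_i = noise_frac * I_i + sigma_floor`; the
#' `sigma` column carries that true value. A noiseless curve
#' (`noise_frac = 0`, `sigma_floor = 0`) is returned unperturbed with a
#' nominal `sigma = 0.01 * I` so that chi-square remains defined; the
#' generating model then fits with chi-square exactly 0.
#'
#' @param model an `rna_model`.
#' @param q_max maximum scattering vector (1/A).
#' @param n_points number of grid points.
#' @param noise_frac relative noise level (e.g. 0.01 for 1\%).
#' @param seed seed for the noise draw.
#' @param sigma_floor absolute additive noise floor (default 0).
#' @return an `rna_saxs_curve` with `q`, `I`, `sigma`.
#' @export
simulate_saxs_with_noise <- function(model, q_max = 0.3, n_points = 256,
                                     noise_frac = 0.01, seed = 1,
                                     sigma_floor = 0) {
  step <- (q_max - 0.005) / n_points
  q <- 0.005 + step * seq_len(n_points)
  base <- compute_saxs_curve(model, q)
  sigma <- noise_frac * base$I + sigma_floor
  if (all(sigma == 0)) {
    return(new_saxs_curve(q, base$I, 0.01 * base$I))
  }
  I_obs <- with_seed(seed, base$I + rnorm(n_points, 0, sigma))
  new_saxs_curve(q, I_obs, sigma)
}

#' Create a pipeline run configuration
#'
#' @param mode one of `build`, `refine`, `score`, `simulate-saxs`,
#'   `make-library`.
#' @param ... mode-specific fields: `seq`, `ss`, `model`, `saxs`,
#'   `restraints`, `library`, `config`, `out`, `seed`, `beam_width`,
#'   `min_fragments`, `n_replicas`, `t_min`, `t_max`, `n_steps`,
#'   `swap_interval`, `q_max`, `n_points`, `noise_frac`, `verbose`.
#' @return a `rna_run_config` with defaults filled in.
#' @export
run_config <- function(mode, ...) {
  modes <- c("build", "refine", "score", "simulate-saxs", "make-library")
  if (!mode %in% modes) {
    stop("unknown mode '", mode, "' (expected one of ",
         paste(modes, collapse = ", "), ")")
  }
  cfg <- list(mode = mode, seq = NULL, ss = NULL, model = NULL, saxs = NULL,
              restraints = NULL, library = NULL, config = NULL, out = NULL,
              seed = 1L, beam_width = 100L, min_fragments = 10L,
              n_replicas = 8L, t_min = 0.5, t_max = 16, n_steps = 5000L,
              swap_interval = 50L, q_max = 0.3, n_points = 256L,
              noise_frac = 0.01, verbose = TRUE)
  extra <- list(...)
  bad <- setdiff(names(extra), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(extra)] <- extra
  structure(cfg, class = "rna_run_config")
}

check_config <- function(cfg) {
  need <- function(field, why) {
    if (is.null(cfg[[field]])) {
      stop("config error: mode '", cfg$mode, "' requires --", field, " (", why, ")")
    }
    if (field != "out" && !file.exists(cfg[[field]])) {
      stop("config error: ", field, " path not found: ", cfg[[field]])
    }
  }
  switch(cfg$mode,
    "build" = { need("seq", "sequence file"); need("ss", "dot-bracket file")
                need("library", "fragment library directory") },
    "refine" = { need("model", "starting model"); need("library", "fragment library directory") },
    "score" = { need("model", "model to score"); need("library", "fragment library directory") },
    "simulate-saxs" = need("model", "model to scatter from"),
    "make-library" = need("config", "library composition file"))
  if (is.null(cfg$out)) stop("config error: --out directory is required")
  invisible(cfg)
}

make_logger <- function(out_dir, verbose) {
  log_path <- file.path(out_dir, "run.log")
  function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    paste0(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(line)
  }
}

read_sequence_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, ">") & !startsWith(lines, "#")]
  if (!length(lines)) stop("no sequence in ", path)
  paste(lines, collapse = "")
}

write_manifest <- function(cfg, out_dir, inputs, outputs, extra = list()) {
  checks <- lapply(inputs, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  manifest <- c(list(
    mode = cfg$mode,
    seed = cfg$seed,
    config = cfg[!vapply(cfg, is.null, TRUE)],
    package_version = as.character(utils::packageVersion("rnamason")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    inputs = checks,
    outputs = outputs
  ), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

read_library_config <- function(path) {
  tb <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("signature", "count"),
                   colClasses = c("character", "integer"))
  setNames(tb$count, tb$signature)
}

## choose, for each motif node, the candidate fragment that best matches
## an existing model's coordinates (used to start refinement from an
## input 3D model)
choices_from_model <- function(graph, sets, model) {
  vapply(seq_along(graph$nodes), function(nid) {
    node <- graph$nodes[[nid]]
    ref <- rbind(model$P[node$layout, , drop = FALSE],
                 model$C4p[node$layout, , drop = FALSE],
                 model$N[node$layout, , drop = FALSE])
    rmsds <- vapply(sets[[nid]]$candidates, function(frag) {
      mov <- rbind(frag$P, frag$C4p, frag$N)
      ok <- !is.na(ref[, 1]) & !is.na(mov[, 1])
      if (sum(ok) < 3) return(Inf)
      tryCatch(superpose(mov[ok, , drop = FALSE], ref[ok, , drop = FALSE])$rmsd,
               error = function(e) Inf)
    }, 0)
    which.min(rmsds)
  }, 0L)
}

#' Run the modeling pipeline
#'
#' Executes one run according to the configuration: `build` goes from
#' sequence + dot-bracket to a refined model (parse, pseudoknot removal,
#' motif decomposition, fragment matching, beam-search assembly,
#' replica-exchange refinement, output); `refine` starts instead from an
#' input 3D model whose secondary structure is recovered by geometric
#' annotation; `score` reports the score breakdown of a model;
#' `simulate-saxs` writes a simulated noisy curve; `make-library`
#' generates and writes a synthetic fragment library. Every run writes a
#' `manifest.json` (configuration echo, seed, versions, input checksums,
#' outputs) and a `run.log` into the output directory.
#'
#' @param cfg an `rna_run_config` from [run_config()].
#' @return invisibly, a named list of result objects (mode-dependent).
#' @export
run_pipeline <- function(cfg) {
  check_config(cfg)
  out_dir <- cfg$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- make_logger(out_dir, isTRUE(cfg$verbose))
  log("mode ", cfg$mode, ", seed ", cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  inputs <- character(0)
  outputs <- list()
  results <- list()

  if (cfg$mode == "make-library") {
    counts <- stage("config", read_library_config(cfg$config))
    inputs <- cfg$config
    lib <- stage("generate", generate_synthetic_library(counts, seed = cfg$seed))
    lib_dir <- file.path(out_dir, "library")
    stage("write", write_fragment_library(lib, lib_dir))
    log("wrote ", sum(library_counts(lib)), " fragments to ", lib_dir)
    outputs$library <- lib_dir
    results$library <- lib
  } else if (cfg$mode == "simulate-saxs") {
    model <- stage("read model", read_model(cfg$model))
    inputs <- cfg$model
    curve <- stage("simulate", simulate_saxs_with_noise(
      model, q_max = cfg$q_max, n_points = cfg$n_points,
      noise_frac = cfg$noise_frac, seed = cfg$seed))
    path <- file.path(out_dir, "saxs.dat")
    write_saxs_curve(curve, path)
    log("wrote simulated curve (", cfg$n_points, " points) to ", path)
    outputs$saxs <- path
    results$curve <- curve
  } else {
    lib <- stage("read library", read_fragment_library(cfg$library))
    inputs <- c(inputs, file.path(cfg$library, "index.tsv"))
    table <- stage("derive potential", derive_potential(lib))
    exp_curve <- NULL
    if (!is.null(cfg$saxs)) {
      exp_curve <- stage("read SAXS", read_saxs_curve(cfg$saxs))
      inputs <- c(inputs, cfg$saxs)
    }
    user_restraints <- empty_restraints()
    if (!is.null(cfg$restraints)) {
      user_restraints <- stage("read restraints", read_restraints(cfg$restraints))
      inputs <- c(inputs, cfg$restraints)
    }

    if (cfg$mode == "score") {
      model <- stage("read model", read_model(cfg$model))
      inputs <- c(inputs, cfg$model)
      sc <- stage("score", total_score(model, table, user_restraints, exp_curve))
      path <- file.path(out_dir, "score.json")
      jsonlite::write_json(unclass(sc), path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      log(sprintf("total score %.4f (%d clashes)", sc$total, sc$e_clash))
      outputs$score <- path
      results$score <- sc
    } else {
      ## build / refine share the downstream
      start <- NULL
      if (cfg$mode == "build") {
        seq_str <- stage("read sequence", read_sequence_file(cfg$seq))
        ss_str <- stage("read structure", read_sequence_file(cfg$ss))
        inputs <- c(inputs, cfg$seq, cfg$ss)
        raw <- stage("parse", parse_dotbracket(seq_str, ss_str))
      } else {
        input_model <- stage("read model", read_model(cfg$model))
        inputs <- c(inputs, cfg$model)
        annotated <- stage("annotate", annotate_secondary_structure(input_model))
        raw <- new_secstruct(annotated$seq, annotated$pairs)
      }
      res <- stage("remove pseudoknots", remove_pseudoknots(raw))
      ss <- res$ss
      restraints <- rbind(res$restraints, user_restraints)
      graph <- stage("decompose", decompose_motifs(ss))
      log(length(graph$nodes), " motif nodes, ", nrow(res$restraints),
          " pseudoknot restraint(s)")
      sets <- stage("match fragments", lapply(graph$nodes, match_fragments,
                                              lib = lib,
                                              min_count = cfg$min_fragments,
                                              target_seq = ss$seq))
      start <- stage("assemble", {
        if (cfg$mode == "refine") {
          ch <- choices_from_model(graph, sets, input_model)
          ord <- assembly_order(graph, sets)
          m <- build_from_choices(graph, sets, ord, ch)
          attr(m, "assembly_order") <- ord
          m
        } else {
          assemble_starting_model(graph, sets, beam_width = cfg$beam_width,
                                  seed = cfg$seed)
        }
      })
      log("starting model assembled (", count_clashes(start), " clashes)")
      ref <- stage("refine", run_refinement(
        graph, sets, table, restraints = restraints, exp_curve = exp_curve,
        start = start, n_replicas = cfg$n_replicas, t_min = cfg$t_min,
        t_max = cfg$t_max, n_steps = cfg$n_steps,
        swap_interval = cfg$swap_interval, seed = cfg$seed))
      log(sprintf("refinement done: best total %.4f%s", ref$best_total,
                  if (is.finite(ref$score$chi2))
                    sprintf(", chi2 %.3f", ref$score$chi2) else ""))
      model_path <- file.path(out_dir, "model.pdb")
      write_model(ref$model, model_path)
      trace_path <- file.path(out_dir, "trace.tsv")
      write.table(ref$trace, trace_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      ss_paths <- write_secstruct_report(ss, file.path(out_dir, "secstruct"))
      outputs$model <- model_path
      outputs$trace <- trace_path
      outputs$secstruct <- as.list(ss_paths)
      results$refinement <- ref
      results$graph <- graph
      results$restraints <- restraints
    }
  }

  extra <- list()
  if (!is.null(results$restraints) && nrow(results$restraints)) {
    extra$restraints <- results$restraints
  }
  manifest <- write_manifest(cfg, out_dir, inputs, outputs, extra)
  log("manifest written to ", manifest)
  invisible(results)
}
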