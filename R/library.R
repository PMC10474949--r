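## Fragment library: generation of a synthetic library of idealized
## fragments, disk round trip (PDB coordinate files + TSV index), and
## matching of library fragments to motif-graph nodes.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

parse_signature <- function(sig) {
  parts <- strsplit(sig, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind == "stem" && length(parts) == 2) {
    return(list(kind = "stem", L = as.integer(parts[2])))
  }
  if (kind == "hairpin" && length(parts) == 2) {
    return(list(kind = "hairpin_loop", spacers = as.integer(parts[2])))
  }
  if (kind == "internal" && length(parts) == 2) {
    sp <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
    if (length(sp) == 2 && !anyNA(sp)) return(list(kind = "internal_loop", spacers = sp))
  }
  if (kind == "junction" && length(parts) == 3) {
    k <- as.integer(parts[2])
    sp <- as.integer(strsplit(parts[3], "-", fixed = TRUE)[[1]])
    if (!is.na(k) && length(sp) == k && !anyNA(sp)) {
      return(list(kind = "junction", spacers = sp))
    }
  }
  if (kind == "ss" && length(parts) == 2) {
    return(list(kind = "single_strand", spacers = as.integer(parts[2])))
  }
  stop("cannot parse fragment signature: ", sig)
}

#' Generate a synthetic fragment library
#'
#' Builds an idealized, reproducible fragment library: A-form helical
#' stems (rise 2.81 A, twist 32.7 deg/bp), and loops constructed by
#' placing rigid A-form closing-pair units around a circle joined by
#' smooth backbone arcs. Loop fragments of the same topology differ in
#' seeded random tilts/twists of their non-entry closing pairs (the
#' relative orientation of the helices they join) and all coordinates
#' receive a small Gaussian jitter, which creates the conformational
#' diversity the assembly and refinement stages search over.
#'
#' @param config named integer vector or data frame (`signature`,
#'   `count`): how many fragments to generate per topology signature
#'   (grammar: `stem:L`, `hairpin:L`, `internal:L1-L2`,
#'   `junction:k:L1-...-Lk`, `ss:L`). For `ss:L`, `count` fragments are
#'   generated for each attachment variant (5' tail, 3' tail, free
#'   strand).
#' @param seed integer seed fixing all randomness.
#' @param jitter Gaussian coordinate jitter sigma in Angstrom (default
#'   0.3).
#' @param max_tilt,max_twist half-ranges (radians) of the random closing
#'   pair reorientation in loop fragments.
#' @return an `rna_fragment_library`.
#' @examples
#' lib <- generate_synthetic_library(c("stem:4" = 3, "hairpin:4" = 3), seed = 1)
#' library_counts(lib)
#' @export
generate_synthetic_library <- function(config, seed = 1, jitter = 0.3,
                                       max_tilt = 45 * pi / 180,
                                       max_twist = 25 * pi / 180) {
  if (is.data.frame(config)) {
    counts <- setNames(as.integer(config$count), config$signature)
  } else {
    counts <- setNames(as.integer(config), names(config))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("config must name the signatures to generate")
  }
  frags <- list()
  with_seed(seed, {
    for (sig in names(counts)) {
      ps <- parse_signature(sig)
      out <- list()
      for (c_i in seq_len(counts[[sig]])) {
        id <- sprintf("%s#%d", sig, c_i)
        out_i <- switch(ps$kind,
          stem = list(build_stem_fragment(ps$L, jitter, source_id = id)),
          hairpin_loop = ,
          internal_loop = ,
          junction = list(build_loop_fragment(ps$kind, ps$spacers, jitter,
                                              max_tilt, max_twist,
                                              source_id = id)),
          single_strand = lapply(c("5p", "3p", "none"), function(at) {
            build_ss_fragment(ps$spacers[1], at, jitter,
                              source_id = paste0(id, "|", at))
          }))
        out <- c(out, out_i)
      }
      key <- out[[1]]$signature
      if (key != sig && !(ps$kind == "junction")) {
        stop("signature round trip failed for ", sig)
      }
      frags[[key]] <- c(frags[[key]], out)
    }
  })
  structure(list(fragments = frags,
                 meta = list(seed = seed, jitter = jitter,
                             counts = counts)),
            class = "rna_fragment_library")
}

#' @export
print.rna_fragment_library <- function(x, ...) {
  cat(sprintf("RNA fragment library: %d signatures, %d fragments\n",
              length(x$fragments), sum(lengths(x$fragments))))
  for (sig in names(x$fragments)) {
    cat(sprintf("  %-20s %d\n", sig, length(x$fragments[[sig]])))
  }
  invisible(x)
}

#' Per-signature fragment counts of a library
#' @param lib an `rna_fragment_library`.
#' @return named integer vector.
#' @export
library_counts <- function(lib) lengths(lib$fragments)

#' Write / read a fragment library
#'
#' The on-disk format is a directory holding one PDB coordinate file per
#' fragment plus a TSV index (`signature`, `file`, `kind`, `spacers`,
#' `attach`, `source_id`, `sequence`). Coordinates round trip at PDB
#' precision (1e-3 A).
#'
#' @param lib an `rna_fragment_library`.
#' @param path directory to write to / read from (index at
#'   `<path>/index.tsv`).
#' @return `write_fragment_library` returns the index path invisibly;
#'   `read_fragment_library` returns an `rna_fragment_library`.
#' @export
write_fragment_library <- function(lib, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  n <- 0L
  for (sig in names(lib$fragments)) {
    for (frag in lib$fragments[[sig]]) {
      n <- n + 1L
      file <- sprintf("frag%05d.pdb", n)
      write_fragment_pdb(frag, file.path(path, file))
      rows[[n]] <- data.frame(
        signature = sig, file = file, kind = frag$kind,
        spacers = paste(frag$spacers, collapse = "-"),
        L = ifelse(is.na(frag$L), "", as.character(frag$L)),
        attach = ifelse(is.na(frag$attach), "", frag$attach),
        source_id = frag$source_id,
        sequence = paste(frag$seq, collapse = ""))
    }
  }
  idx <- if (n) do.call(rbind, rows) else
    data.frame(signature = character(0), file = character(0), kind = character(0),
               spacers = character(0), L = character(0), attach = character(0),
               source_id = character(0), sequence = character(0))
  write.table(idx, file.path(path, "index.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file.path(path, "index.tsv"))
}

#' @rdname write_fragment_library
#' @export
read_fragment_library <- function(path) {
  idx_path <- if (dir.exists(path)) file.path(path, "index.tsv") else path
  if (!file.exists(idx_path)) stop("no library index found at ", idx_path)
  root <- dirname(idx_path)
  idx <- read.table(idx_path, sep = "\t", header = TRUE,
                    colClasses = "character", fill = TRUE,
                    comment.char = "", quote = "")
  frags <- list()
  if (nrow(idx) == 0L) warning("empty fragment library index")
  for (r in seq_len(nrow(idx))) {
    row <- idx[r, ]
    ok <- tryCatch({
      ps_spacers <- if (nzchar(row$spacers))
        as.integer(strsplit(row$spacers, "-", fixed = TRUE)[[1]]) else integer(0)
      if (anyNA(ps_spacers)) stop("bad spacers")
      TRUE
    }, error = function(e) FALSE)
    if (!ok || !nzchar(row$kind) || !nzchar(row$file)) {
      warning("skipping malformed library index row ", r)
      next
    }
    f <- file.path(root, row$file)
    if (!file.exists(f)) stop("library coordinate file missing: ", f)
    coords <- read_fragment_pdb(f)
    spacers <- if (nzchar(row$spacers))
      as.integer(strsplit(row$spacers, "-", fixed = TRUE)[[1]]) else integer(0)
    L <- if (nzchar(row$L)) as.integer(row$L) else NA_integer_
    pairs <- if (row$kind == "stem") {
      p <- rbind(c(1L, 2L * L)); if (L > 1L) p <- rbind(p, c(L, L + 1L)); p
    } else if (row$kind == "single_strand") {
      at <- row$attach
      Ls <- spacers[1]
      if (at == "3p") rbind(c(1L, 2L))
      else if (at == "5p") rbind(c(Ls + 1L, Ls + 2L))
      else NULL
    } else {
      loop_local_layout(spacers)$pairs
    }
    frag <- new_fragment(row$kind, spacers, strsplit(row$sequence, "")[[1]],
                         coords$P, coords$C4p, coords$N, pairs,
                         source_id = row$source_id,
                         attach = if (nzchar(row$attach)) row$attach else NA_character_,
                         L = L)
    frags[[frag$signature]] <- c(frags[[frag$signature]], list(frag))
  }
  structure(list(fragments = frags, meta = list(source = idx_path)),
            class = "rna_fragment_library")
}

write_fragment_pdb <- function(frag, path) {
  m <- fragment_size(frag)
  n_names <- ifelse(is_purine(frag$seq), "N9", "N1")
  xyz <- numeric(0); elety <- character(0); resno <- integer(0)
  resid <- character(0)
  for (t in seq_len(m)) {
    xyz <- c(xyz, frag$P[t, ], frag$C4p[t, ], frag$N[t, ])
    elety <- c(elety, "P", "C4'", n_names[t])
    resno <- c(resno, rep(t, 3))
    resid <- c(resid, rep(frag$seq[t], 3))
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep("A", length(elety)))
}

read_fragment_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  res <- unique(a$resno)
  m <- length(res)
  P <- C4p <- N <- matrix(NA_real_, m, 3)
  for (t in seq_len(m)) {
    sel <- a$resno == res[t]
    grab <- function(names) {
      r <- a[sel & a$elety %in% names, c("x", "y", "z")]
      if (!nrow(r)) stop("residue ", res[t], " in ", path, " lacks atoms ",
                         paste(names, collapse = "/"))
      as.numeric(r[1, ])
    }
    P[t, ] <- grab("P")
    C4p[t, ] <- grab(c("C4'", "C4*"))
    N[t, ] <- grab(c("N9", "N1"))
  }
  list(P = P, C4p = C4p, N = N)
}

## ---- matching ------------------------------------------------------------

rotate_left <- function(x, r) if (r %% length(x) == 0) x else c(x[-(seq_len(r))], x[seq_len(r)])

## rotations r such that rotate_left(frag$spacers, r) equals the node's
aligning_rotations <- function(frag_spacers, node_spacers) {
  k <- length(frag_spacers)
  if (k != length(node_spacers)) return(integer(0))
  which(vapply(0:(k - 1L), function(r) {
    all(rotate_left(frag_spacers, r) == node_spacers)
  }, TRUE)) - 1L
}

#' Match library fragments to a motif-graph node
#'
#' Returns all library fragments whose topology signature matches the
#' node. If fewer than `min_count` are found, the set is augmented first
#' by circular permutations (junction rotations, symmetric internal
#' loops), then by growing the nearest smaller fragments of the same kind
#' via [insert_residues()]. All candidates are finally mutated to the
#' node's target sequence.
#'
#' @param node a motif node from [decompose_motifs()].
#' @param lib an `rna_fragment_library`.
#' @param min_count augmentation threshold (default 10).
#' @param target_seq character vector: the full-molecule sequence the
#'   node's residues are taken from (defaults to no mutation when `NULL`).
#' @return an `rna_fragment_set`: list with `node_id`, `signature` and
#'   `candidates` (list of fragments aligned to the node's layout).
#' @export
match_fragments <- function(node, lib, min_count = 10, target_seq = NULL) {
  sig <- node$signature
  pool <- lib$fragments[[sig]]
  if (is.null(pool)) pool <- list()
  base <- list(); extra <- list()
  for (frag in pool) {
    if (node$kind == "junction") {
      rots <- aligning_rotations(frag$spacers, node$spacers)
      if (!length(rots)) next
      base <- c(base, list(rotate_loop_fragment(frag, rots[1])))
      for (r in rots[-1]) extra <- c(extra, list(rotate_loop_fragment(frag, r)))
    } else if (node$kind == "internal_loop") {
      if (!all(frag$spacers == node$spacers)) next
      base <- c(base, list(frag))
      for (p in circular_permutations(frag)) extra <- c(extra, list(p))
    } else if (node$kind == "single_strand") {
      at_node <- if (!is.null(node$attach)) node$attach else "none"
      at_frag <- if (is.na(frag$attach)) "none" else frag$attach
      if (at_node == at_frag) base <- c(base, list(frag))
    } else {
      base <- c(base, list(frag))
    }
  }
  cands <- base
  if (length(cands) < min_count) cands <- c(cands, extra)
  if (length(cands) < min_count && node$kind != "stem") {
    cands <- c(cands, grow_from_smaller(node, lib, min_count - length(cands)))
  }
  if (!length(cands)) {
    stop(sprintf("no fragments available for node signature '%s'", sig))
  }
  if (!is.null(target_seq)) {
    target <- target_seq[node$layout]
    cands <- lapply(cands, mutate_to_sequence, target = target)
  }
  structure(list(node_id = node$id, signature = sig, candidates = cands),
            class = "rna_fragment_set")
}

## augment by insertion from smaller donors of the same kind
grow_from_smaller <- function(node, lib, need) {
  donors <- list()
  for (key in names(lib$fragments)) {
    for (frag in lib$fragments[[key]]) {
      if (frag$kind != node$kind) next
      if (node$kind == "single_strand") {
        at_node <- if (!is.null(node$attach)) node$attach else "none"
        at_frag <- if (is.na(frag$attach)) "none" else frag$attach
        if (at_node != at_frag) next
        if (frag$spacers[1] >= node$spacers[1]) next
        donors[[length(donors) + 1L]] <- list(frag = frag, rot = 0L,
                                              deficit = node$spacers[1] - frag$spacers[1])
      } else {
        k <- length(frag$spacers)
        if (k != length(node$spacers)) next
        for (r in 0:(k - 1L)) {
          rs <- rotate_left(frag$spacers, r)
          if (all(rs <= node$spacers) && any(rs < node$spacers)) {
            donors[[length(donors) + 1L]] <- list(frag = frag, rot = r,
                                                  deficit = sum(node$spacers - rs))
            break
          }
        }
      }
    }
  }
  if (!length(donors)) return(list())
  donors <- donors[order(vapply(donors, `[[`, 0, "deficit"))]
  out <- list()
  for (d in donors) {
    if (length(out) >= need) break
    frag <- if (d$rot > 0L) rotate_loop_fragment(d$frag, d$rot) else d$frag
    ok <- tryCatch({
      for (t in seq_along(node$spacers)) {
        miss <- node$spacers[t] - frag$spacers[t]
        if (miss > 0) {
          frag <- insert_residues(frag, t, frag$spacers[t] %/% 2L, miss)
        }
      }
      TRUE
    }, error = function(e) FALSE)
    if (ok) out <- c(out, list(frag))
  }
  out
}
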