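## Refinement: parallel-tempering Monte Carlo over discrete fragment
## choices. Each move swaps one motif node's fragment for another
## candidate and rebuilds the model deterministically, so subtrees distal
## to the changed node move rigidly.

#' Geometric temperature ladder
#'
#' `T_k = t_min * (t_max/t_min)^(k/(n-1))` for `k = 0..n-1`.
#'
#' @param n_replicas number of replicas.
#' @param t_min,t_max lowest and highest temperature.
#' @return numeric vector of length `n_replicas`.
#' @export
temperature_ladder <- function(n_replicas = 8, t_min = 0.5, t_max = 16) {
  if (n_replicas == 1L) return(t_min)
  t_min * (t_max / t_min)^((seq_len(n_replicas) - 1) / (n_replicas - 1))
}

#' Metropolis acceptance
#' @param delta score change (lower is better).
#' @param temperature replica temperature.
#' @return logical; draws one uniform variate when `delta > 0`.
#' @export
metropolis_accept <- function(delta, temperature) {
  delta <= 0 || runif(1) < exp(-delta / temperature)
}

## nodes eligible for a move: at least two candidates
movable_nodes <- function(sets) {
  which(vapply(sets, function(s) length(s$candidates), 0L) >= 2L)
}

## propose a new choice vector differing at one random movable node
propose_move <- function(choices, sets, movable) {
  nid <- if (length(movable) == 1L) movable else movable[sample.int(length(movable), 1L)]
  k <- length(sets[[nid]]$candidates)
  alt <- seq_len(k)[-choices[nid]]
  new <- choices
  new[nid] <- if (length(alt) == 1L) alt else alt[sample.int(length(alt), 1L)]
  new
}

## evaluate a choice vector; list(ok, model, score) -- rebuild failures
## (anchor rejection) are reported, not raised
evaluate_choices <- function(graph, sets, order, choices, table, restraints,
                             exp_curve, anchor_tol) {
  model <- tryCatch(build_from_choices(graph, sets, order, choices, anchor_tol),
                    error = function(e) NULL)
  if (is.null(model)) return(list(ok = FALSE))
  sc <- total_score(model, table, restraints, exp_curve)
  list(ok = TRUE, model = model, score = sc)
}

#' Refine a model by replica-exchange Monte Carlo
#'
#' Runs `n_replicas` coupled Metropolis chains on a geometric temperature
#' ladder. A move re-picks the fragment of one random motif node (among
#' nodes with at least two candidates) and rebuilds the model; it is
#' accepted when the total score does not increase, otherwise with
#' probability `exp(-delta/T)`. Every `swap_interval` steps
#' nearest-neighbour replica swaps are attempted, alternating between
#' even and odd pairs, with the standard exchange probability
#' `min(1, exp((1/T_i - 1/T_j)(S_i - S_j)))`. Each replica consumes an
#' independent reproducible random stream derived from `seed`. The
#' best-scoring model ever visited by any replica is returned, with its
#' score recomputed from scratch.
#'
#' @param graph an `rna_motifgraph`.
#' @param sets per-node candidate fragment sets (see [match_fragments()]).
#' @param table an `rna_potential`.
#' @param restraints restraint data frame or `NULL`.
#' @param exp_curve optional experimental SAXS curve; when given, chi^2 is
#'   recomputed for every proposal and folded into the score.
#' @param start an `rna_model` with `$choices` (e.g. from
#'   [assemble_starting_model()]) used to initialize every replica;
#'   `NULL` starts all replicas from the first candidate of each node.
#' @param n_replicas,t_min,t_max temperature ladder (defaults 8 replicas,
#'   0.5 to 16).
#' @param n_steps Monte Carlo steps per replica (default 5000).
#' @param swap_interval steps between swap attempts (default 50).
#' @param seed master seed for all randomness.
#' @param anchor_tol assembly anchor tolerance in Angstrom.
#' @param trace_interval steps between trace records (default
#'   `swap_interval`).
#' @return list with `model` (best model), `score` (its recomputed
#'   `rna_score`), `best_total`, `trace` (data frame: step, replica,
#'   temperature, total, e_potential, chi2), `acceptance` and `swap_rate`.
#' @export
run_refinement <- function(graph, sets, table, restraints = NULL,
                           exp_curve = NULL, start = NULL,
                           n_replicas = 8, t_min = 0.5, t_max = 16,
                           n_steps = 5000, swap_interval = 50, seed = 1,
                           anchor_tol = 1.5, trace_interval = swap_interval) {
  order <- if (!is.null(start) && !is.null(attr(start, "assembly_order"))) {
    attr(start, "assembly_order")
  } else assembly_order(graph, sets)
  start_choices <- if (!is.null(start) && !is.null(start$choices)) {
    start$choices
  } else rep(1L, length(graph$nodes))
  movable <- movable_nodes(sets)
  if (!length(movable)) stop("no motif node has more than one candidate fragment")
  temps <- temperature_ladder(n_replicas, t_min, t_max)

  ## independent reproducible random streams: one per replica + one for swaps
  make_stream <- function(s) { set.seed(s); .Random.seed }
  streams <- lapply(seq_len(n_replicas + 1L), function(r) make_stream(seed + r))
  load_stream <- function(r) assign(".Random.seed", streams[[r]], envir = globalenv())
  save_stream <- function(r) streams[[r]] <<- get(".Random.seed", envir = globalenv())

  base <- evaluate_choices(graph, sets, order, start_choices, table,
                           restraints, exp_curve, anchor_tol)
  if (!base$ok) stop("starting choices cannot be assembled")
  reps <- lapply(seq_len(n_replicas), function(r) {
    list(choices = start_choices, total = base$score$total,
         e_potential = base$score$e_potential, chi2 = base$score$chi2)
  })
  best <- list(choices = start_choices, total = base$score$total)

  trace_steps <- unique(c(seq_len(n_steps)[seq_len(n_steps) %% trace_interval == 0L],
                          if (n_steps >= 1L) n_steps))
  n_trace <- length(trace_steps) * n_replicas
  trace <- list(step = integer(n_trace), replica = integer(n_trace),
                temperature = numeric(n_trace), total = numeric(n_trace),
                e_potential = numeric(n_trace), chi2 = numeric(n_trace))
  trace_at <- 0L
  n_prop <- 0L; n_acc <- 0L; n_swap_try <- 0L; n_swap_acc <- 0L
  swap_parity <- 0L

  for (step in seq_len(n_steps)) {
    for (r in seq_len(n_replicas)) {
      load_stream(r)
      prop_choices <- propose_move(reps[[r]]$choices, sets, movable)
      ev <- evaluate_choices(graph, sets, order, prop_choices, table,
                             restraints, exp_curve, anchor_tol)
      n_prop <- n_prop + 1L
      if (ev$ok && metropolis_accept(ev$score$total - reps[[r]]$total, temps[r])) {
        n_acc <- n_acc + 1L
        reps[[r]] <- list(choices = prop_choices, total = ev$score$total,
                          e_potential = ev$score$e_potential,
                          chi2 = ev$score$chi2)
        if (ev$score$total < best$total) {
          best <- list(choices = prop_choices, total = ev$score$total)
        }
      }
      save_stream(r)
    }
    if (n_replicas > 1L && step %% swap_interval == 0L) {
      load_stream(n_replicas + 1L)
      lo <- if (1L + swap_parity > n_replicas - 1L) integer(0) else {
        seq.int(1L + swap_parity, n_replicas - 1L, by = 2L)
      }
      for (a in lo) {
        b <- a + 1L
        n_swap_try <- n_swap_try + 1L
        p <- exp((1 / temps[a] - 1 / temps[b]) * (reps[[a]]$total - reps[[b]]$total))
        if (p >= 1 || runif(1) < p) {
          n_swap_acc <- n_swap_acc + 1L
          tmp <- reps[[a]]; reps[[a]] <- reps[[b]]; reps[[b]] <- tmp
        }
      }
      save_stream(n_replicas + 1L)
      swap_parity <- 1L - swap_parity
    }
    if (step %% trace_interval == 0L || step == n_steps) {
      for (r in seq_len(n_replicas)) {
        trace_at <- trace_at + 1L
        trace$step[trace_at] <- step
        trace$replica[trace_at] <- r
        trace$temperature[trace_at] <- temps[r]
        trace$total[trace_at] <- reps[[r]]$total
        trace$e_potential[trace_at] <- reps[[r]]$e_potential
        trace$chi2[trace_at] <- reps[[r]]$chi2
      }
    }
  }

  final <- evaluate_choices(graph, sets, order, best$choices, table,
                            restraints, exp_curve, anchor_tol)
  list(model = final$model, score = final$score, best_total = final$score$total,
       trace = as.data.frame(trace[lapply(trace, length) > 0]),
       acceptance = if (n_prop) n_acc / n_prop else NA_real_,
       swap_rate = if (n_swap_try) n_swap_acc / n_swap_try else NA_real_)
}
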