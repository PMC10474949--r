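## Starting-model assembly: leaf-first traversal of the motif graph,
## joining rigid fragments by superposition on the six coarse atoms of the
## shared closing pair, searching fragment choices by deterministic beam
## search on the clash count.

new_model <- function(seq, P, C4p, N, pairs, provenance = character(0),
                      choices = NULL) {
  structure(list(seq = seq, P = P, C4p = C4p, N = N,
                 pairs = as_pair_matrix(pairs),
                 provenance = provenance, choices = choices),
            class = "rna_model")
}

#' @export
print.rna_model <- function(x, ...) {
  cat(sprintf("Coarse-grained RNA model: %d residues, %d nested pairs\n",
              length(x$seq), nrow(x$pairs)))
  invisible(x)
}

model_size <- function(model) length(model$seq)

#' Count glycosidic-nitrogen clashes
#'
#' A clash is a pair of residues whose glycosidic nitrogens (N1 for
#' pyrimidines, N9 for purines) are strictly closer than `cutoff` (6 A by
#' default). Residue pairs adjacent in sequence and pairs forming a nested
#' base pair are excluded. Implemented with a spatial grid (cell lists),
#' which equals the quadratic double loop exactly.
#'
#' @param model an `rna_model` or partial model (rows with `NA` N
#'   coordinates are ignored).
#' @param cutoff clash distance in Angstrom (strict `<`).
#' @param exclude_pairs optional two-column matrix of residue pairs to
#'   exclude in addition to sequence neighbours; defaults to the model's
#'   nested pairs.
#' @return integer clash count.
#' @export
count_clashes <- function(model, cutoff = 6.0, exclude_pairs = NULL) {
  if (is.null(exclude_pairs)) exclude_pairs <- model$pairs
  exclude_pairs <- as_pair_matrix(exclude_pairs)
  ok <- !is.na(model$N[, 1])
  if (sum(ok) < 2) return(0L)
  .count_clashes_grid(model$N[ok, , drop = FALSE], which(ok),
                      as.integer(exclude_pairs[, 1]),
                      as.integer(exclude_pairs[, 2]), cutoff)
}

new_partial <- function(n, seq, pairs) {
  na <- matrix(NA_real_, n, 3)
  structure(list(seq = seq, P = na, C4p = na, N = na,
                 pairs = as_pair_matrix(pairs),
                 placed = logical(n), placed_nodes = integer(0),
                 clash_count = 0L, rmsd_sum = 0,
                 provenance = character(0)),
            class = "rna_partial_model")
}

## core placement; returns list(ok, partial, rmsd, reason)
place_fragment_core <- function(partial, node, frag, anchor_tol = 1.5,
                                track_clashes = TRUE) {
  layout <- node$layout
  if (length(layout) != fragment_size(frag)) {
    return(list(ok = FALSE, reason = "fragment size does not match node"))
  }
  P <- frag$P; C4p <- frag$C4p; N <- frag$N
  rmsd <- 0
  if (length(partial$placed_nodes)) {
    anchor <- NULL
    if (nrow(node$pairs)) {
      for (r in seq_len(nrow(node$pairs))) {
        if (all(partial$placed[node$pairs[r, ]])) { anchor <- node$pairs[r, ]; break }
      }
    }
    if (is.null(anchor)) {
      return(list(ok = FALSE, reason = "node shares no placed closing pair"))
    }
    la <- match(anchor, layout)
    moving <- rbind(P[la[1], ], C4p[la[1], ], N[la[1], ],
                    P[la[2], ], C4p[la[2], ], N[la[2], ])
    reference <- rbind(partial$P[anchor[1], ], partial$C4p[anchor[1], ], partial$N[anchor[1], ],
                       partial$P[anchor[2], ], partial$C4p[anchor[2], ], partial$N[anchor[2], ])
    tf <- superpose_core(moving, reference)
    if (is.null(tf)) return(list(ok = FALSE, reason = "degenerate anchor geometry"))
    if (tf$rmsd > anchor_tol) {
      return(list(ok = FALSE, rmsd = tf$rmsd,
                  reason = sprintf("anchor rmsd %.2f exceeds tolerance %.2f",
                                   tf$rmsd, anchor_tol)))
    }
    rmsd <- tf$rmsd
    P <- apply_transform(P, tf); C4p <- apply_transform(C4p, tf); N <- apply_transform(N, tf)
  }
  new_res <- layout[!partial$placed[layout]]
  rows <- match(new_res, layout)
  partial$P[new_res, ] <- P[rows, , drop = FALSE]
  partial$C4p[new_res, ] <- C4p[rows, , drop = FALSE]
  partial$N[new_res, ] <- N[rows, , drop = FALSE]
  partial$placed[new_res] <- TRUE
  partial$placed_nodes <- c(partial$placed_nodes, node$id)
  partial$rmsd_sum <- partial$rmsd_sum + rmsd
  partial$provenance[as.character(node$id)] <- frag$source_id
  if (track_clashes) partial$clash_count <- count_clashes(partial)
  list(ok = TRUE, partial = partial, rmsd = rmsd)
}

#' Place a fragment onto a partial model
#'
#' Rigidly transforms a fragment so the P, C4' and glycosidic N atoms of
#' its shared closing pair superpose onto the already-placed copy, then
#' copies the fragment's remaining residues into the model (placed
#' residues win). The first node of an empty partial model is placed in
#' the fragment's own frame.
#'
#' @param partial a partial model (from [new_partial_model()] or previous
#'   placements).
#' @param node the motif node being placed.
#' @param frag the chosen fragment (aligned to the node's layout).
#' @param anchor_tol maximum anchor RMSD in Angstrom (default 1.5).
#' @return the updated partial model; placement failure is an error
#'   naming the reason.
#' @export
place_fragment <- function(partial, node, frag, anchor_tol = 1.5) {
  res <- place_fragment_core(partial, node, frag, anchor_tol)
  if (!res$ok) stop("placement rejected: ", res$reason)
  res$partial
}

#' Create an empty partial model for a motif graph
#' @param graph an `rna_motifgraph`.
#' @return an empty partial model covering the graph's sequence.
#' @export
new_partial_model <- function(graph) {
  new_partial(length(graph$seq), graph$seq, graph$ss$nested)
}

## leaf-first node ordering: start at the leaf with fewest candidates,
## then breadth-first toward the interior
assembly_order <- function(graph, sets) {
  nn <- length(graph$nodes)
  if (nn == 1L) return(1L)
  deg <- integer(nn)
  adj <- lapply(seq_len(nn), function(i) integer(0))
  for (r in seq_len(nrow(graph$edges))) {
    a <- graph$edges$a[r]; b <- graph$edges$b[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
  }
  leaves <- which(deg <= 1L)
  ncand <- vapply(seq_len(nn), function(i) length(sets[[i]]$candidates), 0L)
  start <- leaves[order(ncand[leaves], leaves)][1]
  order <- start; seen <- logical(nn); seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- sort(adj[[v]])
    for (w in nb) if (!seen[w]) {
      seen[w] <- TRUE; order <- c(order, w); queue <- c(queue, w)
    }
  }
  order
}

## deterministic rebuild of a full model from per-node fragment choices
build_from_choices <- function(graph, sets, order, choices, anchor_tol = 1.5) {
  partial <- new_partial_model(graph)
  for (nid in order) {
    frag <- sets[[nid]]$candidates[[choices[nid]]]
    res <- place_fragment_core(partial, graph$nodes[[nid]], frag, anchor_tol,
                               track_clashes = FALSE)
    if (!res$ok) {
      stop(sprintf("assembly failed at node %d (%s): %s", nid,
                   graph$nodes[[nid]]$signature, res$reason))
    }
    partial <- res$partial
  }
  model <- new_model(graph$seq, partial$P, partial$C4p, partial$N,
                     graph$ss$nested, partial$provenance, choices)
  model
}

#' Assemble a starting model by beam search
#'
#' Builds a complete clash-minimized model: starting from the motif-graph
#' leaf with the fewest candidate fragments, nodes are added one at a time
#' (breadth-first); at each step every beam member is expanded with every
#' candidate fragment of the next node and the `beam_width` partial models
#' with the fewest glycosidic-N clashes are kept (ties broken by smaller
#' accumulated anchor RMSD, then candidate order). The completed model
#' with the fewest clashes is returned.
#'
#' @param graph an `rna_motifgraph`.
#' @param sets list of `rna_fragment_set`, indexed by node id (see
#'   [match_fragments()]).
#' @param beam_width beam size (default 100; `Inf` for exhaustive search).
#' @param seed unused unless random subsampling of expansions is enabled
#'   via `max_expansions`.
#' @param anchor_tol anchor RMSD tolerance in Angstrom.
#' @param max_expansions optional cap on expansions per step; when
#'   exceeded, a seeded random subsample is used.
#' @return an `rna_model` with per-node fragment provenance and the
#'   chosen candidate indices in `$choices`.
#' @export
assemble_starting_model <- function(graph, sets, beam_width = 100, seed = NULL,
                                    anchor_tol = 1.5, max_expansions = NULL) {
  order <- assembly_order(graph, sets)
  for (nid in order) {
    if (!length(sets[[nid]]$candidates)) {
      stop("node ", nid, " has no candidate fragments")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  beam <- list(list(partial = new_partial_model(graph),
                    choices = rep(NA_integer_, length(graph$nodes))))
  for (nid in order) {
    node <- graph$nodes[[nid]]
    cands <- sets[[nid]]$candidates
    expansions <- list()
    for (st in beam) {
      for (ci in seq_along(cands)) {
        res <- place_fragment_core(st$partial, node, cands[[ci]], anchor_tol)
        if (!res$ok) next
        ch <- st$choices; ch[nid] <- ci
        expansions[[length(expansions) + 1L]] <- list(partial = res$partial,
                                                      choices = ch)
      }
    }
    if (!length(expansions)) {
      stop(sprintf("assembly failed: all placements rejected at node %d (%s)",
                   nid, node$signature))
    }
    if (!is.null(max_expansions) && length(expansions) > max_expansions) {
      expansions <- expansions[sort(sample.int(length(expansions), max_expansions))]
    }
    key <- order(vapply(expansions, function(e) e$partial$clash_count, 0L),
                 vapply(expansions, function(e) e$partial$rmsd_sum, 0))
    keep <- head(key, if (is.finite(beam_width)) beam_width else length(key))
    beam <- expansions[keep]
  }
  best <- beam[[1]]
  model <- new_model(graph$seq, best$partial$P, best$partial$C4p, best$partial$N,
                     graph$ss$nested, best$partial$provenance, best$choices)
  attr(model, "clash_count") <- best$partial$clash_count
  attr(model, "assembly_order") <- order
  model
}
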