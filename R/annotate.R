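## Geometric base-pair annotation of coarse-grained 3D models.

#' Annotate the secondary structure of a 3D model
#'
#' Detects base pairs from coarse-grained geometry: two residues at least
#' 3 apart in sequence are candidate partners when they form a canonical
#' Watson-Crick or GU wobble combination, their glycosidic nitrogens are
#' 7.5--10.5 A apart and their C4' atoms 9.0--11.5 A apart. Candidates
#' are accepted greedily, each residue pairing at most once: candidates
#' supported by a neighbouring candidate (`(i-1, j+1)` or `(i+1, j-1)`,
#' i.e. helix stacking continuity) are taken before isolated ones, and
#' within each group by closeness of the N--N distance to the ideal
#' 8.9 A. The accepted pairs are then split into a maximal nested set and
#' pseudoknot pairs.
#'
#' @param model an `rna_model`.
#' @param nn_range,c4_range acceptance windows in Angstrom.
#' @param ideal_nn ideal glycosidic N--N distance (8.9 A).
#' @return a resolved `rna_secstruct` (fields `nested` and `pseudoknot`).
#' @export
annotate_secondary_structure <- function(model, nn_range = c(7.5, 10.5),
                                         c4_range = c(9.0, 11.5),
                                         ideal_nn = 8.9) {
  n <- length(model$seq)
  cand <- list()
  for (i in seq_len(max(0L, n - 3L))) {
    for (j in (i + 3L):n) {
      if (!paste0(model$seq[i], model$seq[j]) %in%
            paste0(CANONICAL_PAIRS[, 1], CANONICAL_PAIRS[, 2])) next
      dnn <- sqrt(sum((model$N[i, ] - model$N[j, ])^2))
      if (is.na(dnn) || dnn < nn_range[1] || dnn > nn_range[2]) next
      dcc <- sqrt(sum((model$C4p[i, ] - model$C4p[j, ])^2))
      if (is.na(dcc) || dcc < c4_range[1] || dcc > c4_range[2]) next
      cand[[length(cand) + 1L]] <- c(i, j, abs(dnn - ideal_nn))
    }
  }
  taken <- logical(n)
  pairs <- NULL
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    ## helix support: a candidate flanked by another candidate along a
    ## would-be helix outranks isolated (often spurious diagonal) contacts
    keyset <- paste(cm[, 1], cm[, 2])
    support <- (paste(cm[, 1] - 1L, cm[, 2] + 1L) %in% keyset) +
               (paste(cm[, 1] + 1L, cm[, 2] - 1L) %in% keyset)
    cm <- cm[order(-support, cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, 1]; j <- cm[r, 2]
      if (taken[i] || taken[j]) next
      taken[i] <- taken[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  ss <- new_secstruct(model$seq, as_pair_matrix(pairs))
  remove_pseudoknots(ss)$ss
}

#' Fraction of reference nested pairs recovered by annotation
#'
#' @param annotated,reference resolved `rna_secstruct` objects over the
#'   same sequence.
#' @return list with `recovered` (count), `reference` (count) and
#'   `fraction`.
#' @export
pair_recovery <- function(annotated, reference) {
  ref <- reference$nested
  if (!nrow(ref)) return(list(recovered = 0L, reference = 0L, fraction = NA_real_))
  found <- union(paste(annotated$nested[, 1], annotated$nested[, 2]),
                 paste(annotated$pseudoknot[, 1], annotated$pseudoknot[, 2]))
  hit <- sum(paste(ref[, 1], ref[, 2]) %in% found)
  list(recovered = hit, reference = nrow(ref), fraction = hit / nrow(ref))
}
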