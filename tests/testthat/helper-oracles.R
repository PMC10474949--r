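## Independent reference implementations ("oracles") used by the tests.
## Each deliberately uses a different algorithm than the package code.

## --- maximum crossing-free subset of a pair matching, by exhaustive
## subset enumeration (pairs already residue-disjoint)
oracle_max_nested <- function(pairs) {
  m <- nrow(pairs)
  if (m == 0L) return(0L)
  cross <- matrix(FALSE, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a != b) cross[a, b] <- rnamason:::pairs_cross(pairs[a, ], pairs[b, ])
  }
  best <- 0L
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    for (a in sel) for (b in sel) if (cross[a, b]) { ok <- FALSE; break }
    if (ok) best <- length(sel)
  }
  best
}

## --- enumerate all matchings of 1..n into disjoint pairs (i, j) with
## j - i >= 3 (including partial matchings and the empty one)
oracle_enumerate_matchings <- function(n) {
  out <- list()
  recurse <- function(pos, used, acc) {
    if (pos > n) {
      out[[length(out) + 1L]] <<- if (length(acc)) {
        do.call(rbind, acc)
      } else matrix(integer(0), ncol = 2)
      return(invisible())
    }
    if (used[pos]) return(recurse(pos + 1L, used, acc))
    ## leave pos unpaired
    recurse(pos + 1L, used, acc)
    ## pair pos with any later free j
    js <- seq_len(n)
    js <- js[js >= pos + 3L & !used[js]]
    for (j in js) {
      used2 <- used; used2[c(pos, j)] <- TRUE
      recurse(pos + 1L, used2, c(acc, list(c(pos, j))))
    }
  }
  recurse(1L, logical(n), list())
  out
}

## --- rigid superposition via Horn's quaternion method
oracle_quaternion_rmsd <- function(moving, reference) {
  P <- sweep(moving, 2, colMeans(moving))
  Q <- sweep(reference, 2, colMeans(reference))
  S <- t(P) %*% Q
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

## --- quadratic-time clash count (dense distance matrix) with the same
## exclusion rules as the grid implementation
oracle_clash_count <- function(model, cutoff = 6.0) {
  D <- as.matrix(dist(model$N))
  sel <- upper.tri(D) & (col(D) - row(D) > 1L) & D < cutoff
  if (!is.null(model$pairs) && nrow(model$pairs)) {
    sel[model$pairs[, 1:2, drop = FALSE]] <- FALSE
  }
  sum(sel, na.rm = TRUE)
}

## --- brute-force pairwise statistical-potential energy
oracle_potential <- function(model, table) {
  at <- rnamason:::stack_atoms(model)
  e <- 0
  m <- nrow(at$coords)
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      if (abs(at$resid[a] - at$resid[b]) < 2) next
      d <- sqrt(sum((at$coords[a, ] - at$coords[b, ])^2))
      if (d >= table$max_dist) next
      t1 <- min(at$atype[a], at$atype[b]); t2 <- max(at$atype[a], at$atype[b])
      row <- (t1 - 1) * 3 - ((t1 - 1) * (t1 - 2)) %/% 2 + (t2 - t1) + 1
      e <- e + unname(table$table[row, floor(d / table$bin_width) + 1])
    }
  }
  e
}

## --- two-bead Debye closed form with Gaussian form factors
oracle_two_bead_I <- function(f1, f2, dist, q, rbead = 2.5) {
  g <- exp(-q^2 * rbead^2 / 2)
  sinc <- ifelse(q * dist < 1e-9, 1, sin(q * dist) / (q * dist))
  g^2 * (f1^2 + f2^2 + 2 * f1 * f2 * sinc)
}

## --- random coarse model over n residues (uniform in a box)
random_model <- function(n, box = 40, seed = 1, pairs = NULL) {
  rnamason:::with_seed(seed, {
    seqs <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    mk <- function() matrix(runif(3 * n, 0, box), n, 3)
    rnamason:::new_model(seqs, mk(), mk(), mk(), pairs)
  })
}

## --- a small assembled system shared by several tests
toy_system <- function(n_frag = 8, seed = 5, sequence = "GGGGAAAACCCC",
                       structure = "((((....))))") {
  res <- remove_pseudoknots(parse_dotbracket(sequence, structure))
  graph <- decompose_motifs(res$ss)
  counts <- setNames(rep(n_frag, 2),
                     c(paste0("stem:", graph$nodes[[1]]$L), "hairpin:4"))
  lib <- generate_synthetic_library(counts, seed = seed)
  sets <- lapply(graph$nodes, match_fragments, lib = lib, min_count = 2,
                 target_seq = res$ss$seq)
  list(res = res, graph = graph, lib = lib, sets = sets,
       order = rnamason:::assembly_order(graph, sets))
}
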