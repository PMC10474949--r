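## Scoring: knowledge-based distance potential, flat-bottom restraints,
## Debye-formula SAXS curves, chi-square fitting and the SAXS correction
## factor that couples the goodness of fit into the total score.

ATOM_TYPES <- c(P = 1L, C4p = 2L, N = 3L)
TYPE_PAIR_NAMES <- c("P-P", "P-C4'", "P-N", "C4'-C4'", "C4'-N", "N-N")

## stacked atom matrix of a model/fragment: coords, type, residue id
stack_atoms <- function(obj, resid = NULL) {
  m <- nrow(obj$P)
  if (is.null(resid)) resid <- seq_len(m)
  coords <- rbind(obj$P, obj$C4p, obj$N)
  atype <- rep(ATOM_TYPES, each = m)
  rid <- rep(resid, 3)
  ok <- !is.na(coords[, 1])
  list(coords = coords[ok, , drop = FALSE], atype = atype[ok], resid = rid[ok])
}

#' Derive a knowledge-based distance potential from a fragment library
#'
#' For each coarse atom-type pair (P, C4', glycosidic N) the
#' inter-residue distance distribution observed in the library (residue
#' separation >= 2) is converted into a pseudo-energy
#' `-ln((observed + 1) / (reference + 1))` per distance bin, where the
#' reference is the uniform-in-volume shell density at the same sample
#' size. Energies are clamped to [-5, 5]; distances beyond `max_dist`
#' score 0.
#'
#' @param lib an `rna_fragment_library`.
#' @param bin_width bin width in Angstrom (default 0.5).
#' @param max_dist range of the potential in Angstrom (default 20).
#' @return an `rna_potential`: list with `table` (6 x nbins matrix),
#'   `bin_width`, `max_dist`.
#' @export
derive_potential <- function(lib, bin_width = 0.5, max_dist = 20) {
  frags <- unlist(lib$fragments, recursive = FALSE)
  if (!length(frags)) stop("empty fragment library")
  nb <- ceiling(max_dist / bin_width)
  obs <- matrix(0, 6, nb)
  for (frag in frags) {
    at <- stack_atoms(frag)
    m <- nrow(at$coords)
    if (m < 2) next
    d <- as.matrix(dist(at$coords))
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        if (abs(at$resid[a] - at$resid[b]) < 2) next
        if (d[a, b] >= max_dist) next
        t1 <- min(at$atype[a], at$atype[b]); t2 <- max(at$atype[a], at$atype[b])
        row <- (t1 - 1L) * 3L - ((t1 - 1L) * (t1 - 2L)) %/% 2L + (t2 - t1) + 1L
        bin <- floor(d[a, b] / bin_width) + 1L
        obs[row, bin] <- obs[row, bin] + 1
      }
    }
  }
  ## reference: same number of samples distributed uniformly in the sphere
  edges <- seq(0, max_dist, by = bin_width)
  shell <- diff(edges^3) / max_dist^3
  table <- matrix(0, 6, nb)
  for (row in 1:6) {
    tot <- sum(obs[row, ])
    ref <- tot * shell
    e <- -log((obs[row, ] + 1) / (ref + 1))
    table[row, ] <- pmin(5, pmax(-5, e))
  }
  rownames(table) <- TYPE_PAIR_NAMES
  structure(list(table = table, bin_width = bin_width, max_dist = max_dist),
            class = "rna_potential")
}

#' Score a model with the statistical potential
#'
#' Sums the potential-table lookups over all atom pairs of non-adjacent
#' residues (residue separation >= 2) within the potential range. Lower
#' is better.
#'
#' @param model an `rna_model` (or fragment).
#' @param table an `rna_potential` from [derive_potential()].
#' @return pseudo-energy (numeric).
#' @export
score_potential <- function(model, table) {
  at <- stack_atoms(model)
  if (nrow(at$coords) < 2) return(0)
  .pair_potential_energy(at$coords, at$atype, at$resid,
                         table$table, table$bin_width, table$max_dist)
}

#' Score flat-bottom distance restraints
#'
#' Each restraint contributes
#' `weight * max(0, |d_ij - target| - flat_width)^2`, where `d_ij` is the
#' glycosidic N--N distance. Pseudoknot pairs are converted to restraints
#' with target 9 A (canonical-pair N--N distance), flat width 1 A and
#' weight 1.
#'
#' @param model an `rna_model`.
#' @param restraints data frame with columns `i`, `j`, `target`,
#'   `flat_width`, `weight`.
#' @return restraint pseudo-energy.
#' @export
score_restraints <- function(model, restraints) {
  if (is.null(restraints) || !nrow(restraints)) return(0)
  d <- sqrt(rowSums((model$N[restraints$i, , drop = FALSE] -
                     model$N[restraints$j, , drop = FALSE])^2))
  sum(restraints$weight * pmax(0, abs(d - restraints$target) - restraints$flat_width)^2)
}

#' Simulate a SAXS curve with the Debye formula
#'
#' One scattering bead per residue at the C4' position, with an effective
#' Gaussian form factor `f(q) = F0 exp(-q^2 Rb^2 / 2)` (`F0` = 165
#' electrons for purines, 140 for pyrimidines; bead radius `Rb` = 2.5 A).
#' `I(q) = sum_ab f_a f_b sin(q r_ab)/(q r_ab)`, with the `sin(x)/x -> 1`
#' limit at small arguments, so `I(0)` equals `(sum F0)^2` exactly.
#'
#' @param model an `rna_model`.
#' @param q_grid increasing non-negative scattering vector grid (1/A).
#' @return an `rna_saxs_curve`: data frame with columns `q`, `I`, `sigma`
#'   (sigma `NA` for simulated curves).
#' @export
compute_saxs_curve <- function(model, q_grid) {
  if (any(diff(q_grid) <= 0) || any(q_grid < 0)) {
    stop("q grid must be non-negative and strictly increasing")
  }
  f0 <- FORM_FACTOR[model$seq]
  I <- .debye_intensity(model$C4p, as.numeric(f0), as.numeric(q_grid), 2.5)
  new_saxs_curve(q_grid, I, rep(NA_real_, length(q_grid)))
}

new_saxs_curve <- function(q, I, sigma) {
  structure(data.frame(q = q, I = I, sigma = sigma),
            class = c("rna_saxs_curve", "data.frame"))
}

#' Read a SAXS curve from a 3-column text file
#'
#' Whitespace-separated columns `q`, `I`, `sigma`; `#` comments and
#' non-numeric header lines are skipped (GNOM-style `.dat` files are
#' accepted).
#'
#' @param path file path.
#' @return an `rna_saxs_curve`.
#' @export
read_saxs_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  rows <- lapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 2) return(NULL)
    v <- suppressWarnings(as.numeric(f[1:min(3, length(f))]))
    if (anyNA(v[1:2])) return(NULL)
    c(v, NA_real_)[1:3]
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows) || nrow(rows) < 2) stop("no data rows in SAXS file ", path)
  ord <- order(rows[, 1])
  rows <- rows[ord, , drop = FALSE]
  new_saxs_curve(rows[, 1], rows[, 2], rows[, 3])
}

#' Write a SAXS curve to a 3-column text file
#' @param curve an `rna_saxs_curve`.
#' @param path output path.
#' @export
write_saxs_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q\tI\tsigma", con)
  write.table(format(curve, digits = 8), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Chi-square agreement between a model and an experimental SAXS curve
#'
#' The model curve is resampled onto the experimental grid by linear
#' interpolation, then `chi^2 = 1/(N-1) sum ((c I_m - I_e)/sigma)^2` with
#' the scale factor `c` minimizing the sum in closed form.
#'
#' @param model_curve,exp_curve `rna_saxs_curve` objects; `exp_curve`
#'   must carry positive `sigma`.
#' @return list with `chi2` and `scale`.
#' @export
chi_square <- function(model_curve, exp_curve) {
  N <- nrow(exp_curve)
  if (N < 2) stop("need at least 2 experimental points")
  if (any(!is.finite(exp_curve$sigma)) || any(exp_curve$sigma <= 0)) {
    stop("experimental curve must have positive sigma")
  }
  chi2_core(model_curve$q, model_curve$I, exp_curve$q, exp_curve$I,
            exp_curve$sigma)
}

chi2_core <- function(qm, Im, qe, Ie, sigma) {
  Im <- if (identical(qm, qe)) Im else approx(qm, Im, xout = qe, rule = 2)$y
  s2 <- sigma^2
  c_scale <- sum(Im * Ie / s2) / sum(Im^2 / s2)
  chi2 <- sum(((c_scale * Im - Ie)^2) / s2) / (length(qe) - 1)
  list(chi2 = chi2, scale = c_scale)
}

#' SAXS correction factor
#'
#' Quantifies the deviation of chi^2 from 1 with a mixture of two
#' Gaussians with variances 1 and 10:
#' `f(x) = exp(-(x-1)^2/2) + 0.5 exp(-(x-1)^2/20)`, so a perfect fit
#' (chi^2 = 1) gives 1.5 and the factor decays monotonically in
#' `|chi^2 - 1|`.
#'
#' @param chi2 chi-square value(s).
#' @return correction factor(s) in (0, 1.5].
#' @export
saxs_correction_factor <- function(chi2) {
  exp(-(chi2 - 1)^2 / 2) + 0.5 * exp(-(chi2 - 1)^2 / 20)
}

#' Total model score
#'
#' Base score `S = e_potential + w_restraint * e_restraint +
#' w_clash * clash_count`. Without a SAXS curve the total is `S`. With
#' one, the score is multiplied by the correction factor
#' `f(chi^2)`: `total = S * f` when `S < 0`, and
#' `S * (2 - min(f, 1.5)/1.5)` otherwise, so a poorer fit always raises
#' the total regardless of the sign of `S`.
#'
#' @param model an `rna_model`.
#' @param table an `rna_potential`.
#' @param restraints restraint data frame (or `NULL`).
#' @param exp_curve optional experimental `rna_saxs_curve`.
#' @param w_restraint,w_clash weights (defaults 10 and 5).
#' @param q_points number of model-curve points spanning the experimental
#'   q range (default 256).
#' @return an `rna_score`: list with `e_potential`, `e_restraint`,
#'   `e_clash`, `chi2`, `saxs_factor`, `total`.
#' @export
total_score <- function(model, table, restraints = NULL, exp_curve = NULL,
                        w_restraint = 10, w_clash = 5, q_points = 256) {
  e_pot <- score_potential(model, table)
  e_res <- score_restraints(model, restraints)
  e_clash <- count_clashes(model)
  S <- e_pot + w_restraint * e_res + w_clash * e_clash
  chi2 <- NA_real_; fac <- NA_real_
  total <- S
  if (!is.null(exp_curve)) {
    qg <- seq(min(exp_curve$q), max(exp_curve$q), length.out = q_points)
    Im <- .debye_intensity(model$C4p, as.numeric(FORM_FACTOR[model$seq]), qg, 2.5)
    chi2 <- chi2_core(qg, Im, exp_curve$q, exp_curve$I, exp_curve$sigma)$chi2
    fac <- saxs_correction_factor(chi2)
    total <- if (S < 0) S * fac else S * (2 - min(fac, 1.5) / 1.5)
  }
  structure(list(e_potential = e_pot, e_restraint = e_res, e_clash = e_clash,
                 chi2 = chi2, saxs_factor = fac, total = total),
            class = "rna_score")
}

#' @export
print.rna_score <- function(x, ...) {
  cat(sprintf("total %.3f (potential %.3f, restraints %.3f, clashes %d%s)\n",
              x$total, x$e_potential, x$e_restraint, x$e_clash,
              if (is.finite(x$chi2)) sprintf(", chi2 %.3f, factor %.3f",
                                             x$chi2, x$saxs_factor) else ""))
  invisible(x)
}

#' Read a tertiary-contact restraints file
#'
#' TSV with columns `i`, `j` and optional `target`, `flat_width`,
#' `weight`; omitted trailing columns get the pseudoknot defaults
#' (9 A, 1 A, 1).
#'
#' @param path file path.
#' @return restraint data frame.
#' @export
read_restraints <- function(path) {
  tb <- read.table(path, header = FALSE, comment.char = "#", fill = TRUE)
  if (!ncol(tb) || !nrow(tb)) return(empty_restraints())
  ## drop a header row if present
  if (!is.numeric(tb[[1]]) && suppressWarnings(is.na(as.numeric(tb[1, 1])))) {
    tb <- tb[-1, , drop = FALSE]
  }
  out <- data.frame(i = as.integer(as.numeric(tb[[1]])),
                    j = as.integer(as.numeric(tb[[2]])),
                    target = if (ncol(tb) >= 3) as.numeric(tb[[3]]) else 9.0,
                    flat_width = if (ncol(tb) >= 4) as.numeric(tb[[4]]) else 1.0,
                    weight = if (ncol(tb) >= 5) as.numeric(tb[[5]]) else 1.0)
  out$target[is.na(out$target)] <- 9.0
  out$flat_width[is.na(out$flat_width)] <- 1.0
  out$weight[is.na(out$weight)] <- 1.0
  out
}
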