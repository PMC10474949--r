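## Coarse-grained nucleotide geometry: 3 points per residue (P, C4',
## glycosidic N = N1 pyrimidine / N9 purine). An idealized A-form base-pair
## template (helix axis = z through the origin, pair plane z = 0) is the
## common anchor unit of all fragment builders.

A_RISE <- 2.81          # A A-form helical rise per bp
A_TWIST <- 32.7 * pi / 180  # A-form twist per bp
C4_STEP <- 5.9          # target consecutive C4'-C4' spacing in loops, A
PAIR_C4_SPAN <- 10.3    # C4'-C4' distance across a canonical pair, A

GLYCO_DIST <- c(A = 4.3, G = 4.3, C = 3.4, U = 3.4)  # C4'-N by base class
FORM_FACTOR <- c(A = 165, G = 165, C = 140, U = 140) # electrons per base class
is_purine <- function(nt) nt %in% c("A", "G")

## pair template (side1 = 5' partner, side2 = 3' partner); C2 pseudo-dyad
## about the y axis maps side1 onto side2.
PAIR_C4 <- rbind(c(-5.15, 7.86, 0), c(5.15, 7.86, 0))
PAIR_NDIR <- rbind(c(0.185, -0.983, 0) / sqrt(0.185^2 + 0.983^2),
                   c(-0.185, -0.983, 0) / sqrt(0.185^2 + 0.983^2))
PAIR_P <- rbind(c(-2.58, 8.52, -1.405), c(2.58, 8.52, 1.405))

CANONICAL_PAIRS <- rbind(c("A", "U"), c("U", "A"), c("G", "C"),
                         c("C", "G"), c("G", "U"), c("U", "G"))

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1))
}

## rotation about an arbitrary unit axis (Rodrigues)
rot_axis <- function(axis, a) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

unit <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

## atoms of one template pair given the two nucleotide codes, transformed by
## rotation R and translation t. Returns list of 2x3 matrices P, C4p, N.
pair_atoms <- function(nt, R = diag(3), t = c(0, 0, 0)) {
  N <- PAIR_C4 + PAIR_NDIR * GLYCO_DIST[nt]
  tr <- function(m) t(R %*% t(m)) + rep(t, each = 2)
  list(P = tr(PAIR_P), C4p = tr(PAIR_C4), N = tr(N))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of one point set onto another.
#'
#' @param moving,reference numeric matrices (n x 3), n >= 3, corresponding
#'   rows; the point sets must not be collinear.
#' @return list with `R` (3x3 rotation, det +1), `t` (translation so that
#'   `x %*% t(R) + t` maps moving onto reference) and `rmsd`.
#' @export
superpose <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (nrow(moving) != nrow(reference)) stop("point counts differ")
  if (nrow(moving) < 3) stop("need at least 3 points")
  out <- superpose_core(moving, reference)
  if (is.null(out)) stop("points are collinear")
  out
}

## non-throwing kernel; NULL when the rotation is underdetermined
superpose_core <- function(moving, reference) {
  n <- nrow(moving)
  cm <- colMeans(moving); cr <- colMeans(reference)
  P <- moving - matrix(cm, n, 3, byrow = TRUE)
  Q <- reference - matrix(cr, n, 3, byrow = TRUE)
  H <- crossprod(P, Q)
  s <- svd(H)
  ## a (near-)collinear point set leaves the rotation underdetermined
  if (s$d[2] <= 1e-8 * max(s$d[1], 1e-12)) return(NULL)
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% (c(1, 1, d) * t(s$u))
  t <- cr - as.vector(R %*% cm)
  moved <- tcrossprod(P, R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

apply_transform <- function(m, tf) {
  tcrossprod(m, tf$R) + matrix(tf$t, nrow(m), 3, byrow = TRUE)
}

## Solve the loop-cycle circle radius: k closing-pair chords (10.3 A) and
## n_step single-residue chords (C4_STEP) must close a circle.
loop_circle_radius <- function(k, n_step) {
  f <- function(R) {
    k * 2 * asin(pmin(1, PAIR_C4_SPAN / 2 / R)) +
      n_step * 2 * asin(pmin(1, C4_STEP / 2 / R)) - 2 * pi
  }
  lo <- PAIR_C4_SPAN / 2 + 1e-6
  if (f(lo) < 0) stop("loop too small to close")
  uniroot(f, c(lo, 2000), tol = 1e-10)$root
}

## Solve arc opening angle for interpolation: n_seg chords of length s
## spanning a chord of length c (s * n_seg > c).
arc_angle <- function(c, s, n_seg) {
  g <- function(a) c * sin(a / (2 * n_seg)) - s * sin(a / 2)
  ## g < 0 near 0 (arc shorter than needed), > 0 near 2*pi
  uniroot(g, c(1e-8, 2 * pi - 1e-6), tol = 1e-10)$root
}

## n points interpolated on a circular arc from A to B bulging toward dirn
## (a vector, not necessarily orthogonal to AB), with n+1 equal chords.
arc_points <- function(A, B, n, dirn, step = 5.7) {
  if (n < 1) return(matrix(numeric(0), ncol = 3))
  c <- sqrt(sum((B - A)^2))
  n_seg <- n + 1
  if (c / n_seg >= 4.6) {
    ## straight interpolation already gives acceptable spacing
    tt <- seq_len(n) / n_seg
    return(t(sapply(tt, function(f) A + f * (B - A))))
  }
  e1 <- unit(B - A)
  w <- dirn - sum(dirn * e1) * e1
  if (sqrt(sum(w^2)) < 1e-8) w <- if (abs(e1[3]) < 0.9) cross3(e1, c(0, 0, 1)) else cross3(e1, c(1, 0, 0))
  e2 <- unit(w)
  alpha <- arc_angle(c, step, n_seg)
  R <- c / (2 * sin(alpha / 2))
  M <- (A + B) / 2
  centre <- M - e2 * (R * cos(alpha / 2))
  vA <- A - centre
  axis <- cross3(e1, e2)  # rotating vA by +alpha about axis reaches vB
  test <- centre + as.vector(rot_axis(axis, alpha) %*% vA)
  if (sum((test - B)^2) > 1e-6) axis <- -axis
  t(sapply(seq_len(n), function(i) {
    centre + as.vector(rot_axis(axis, alpha * i / n_seg) %*% vA)
  }))
}

## radius of gyration of weighted beads (SAXS oracle helper)
coord_rg <- function(coords, w) {
  w <- w / sum(w)
  mu <- colSums(coords * w)
  sqrt(sum(w * rowSums(sweep(coords, 2, mu)^2)))
}
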