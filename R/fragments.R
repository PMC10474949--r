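## Fragments: rigid coarse-grained 3D building blocks keyed by motif
## topology. Residues are stored in "motif order" -- the order in which the
## motif's residues appear in the parent sequence when the motif is
## instantiated with its entry closing pair first. Closing pairs are local
## (i, j) index pairs into that order, entry pair first.

new_fragment <- function(kind, spacers, seq, P, C4p, N, pairs,
                         source_id = "synthetic", attach = NA_character_,
                         L = NA_integer_) {
  frag <- structure(list(
    kind = kind, spacers = as.integer(spacers), L = L,
    seq = seq, P = P, C4p = C4p, N = N,
    pairs = as_pair_matrix(pairs),
    attach = attach, source_id = source_id
  ), class = "rna_fragment")
  frag$signature <- fragment_signature(frag)
  frag
}

fragment_signature <- function(frag) {
  switch(frag$kind,
    stem = paste0("stem:", frag$L),
    single_strand = paste0("ss:", frag$spacers[1]),
    loop_signature(frag$kind, frag$spacers))
}

#' Topology signature of a motif or fragment
#'
#' Serializes the secondary-structure topology of a motif-graph node or of
#' a fragment: `stem:L`, `hairpin:L`, `internal:L1-L2`,
#' `junction:k:L1-...-Lk` (rotation-normalized to the lexicographically
#' minimal rotation of the spacer lengths) or `ss:L`. Fragment-to-node
#' matching considers only this signature; sequence is ignored.
#'
#' @param x a motif node (from [decompose_motifs()]) or an `rna_fragment`.
#' @return character signature.
#' @export
topology_signature <- function(x) {
  if (inherits(x, "rna_fragment")) return(fragment_signature(x))
  switch(x$kind,
    stem = paste0("stem:", x$L),
    single_strand = paste0("ss:", x$spacers[1]),
    loop_signature(x$kind, x$spacers))
}

fragment_size <- function(frag) length(frag$seq)

## local layout bookkeeping for a closed loop with spacer vector s:
## order = entry.i, s1, c1.i, c1.j, s2, c2.i, c2.j, ..., sk, entry.j
loop_local_layout <- function(spacers) {
  k <- length(spacers)
  pos <- 1L
  pair_pos <- matrix(NA_integer_, k, 2)
  pair_pos[1, 1] <- 1L
  strand_pos <- vector("list", k)
  cursor <- 1L
  for (t in seq_len(k)) {
    seg <- if (spacers[t] > 0) (cursor + 1L):(cursor + spacers[t]) else integer(0)
    strand_pos[[t]] <- seg
    cursor <- cursor + spacers[t]
    if (t < k) {
      pair_pos[t + 1L, ] <- c(cursor + 1L, cursor + 2L)
      cursor <- cursor + 2L
    } else {
      pair_pos[1, 2] <- cursor + 1L
      cursor <- cursor + 1L
    }
  }
  list(pairs = pair_pos, strands = strand_pos, m = cursor)
}

random_canonical_pair <- function() CANONICAL_PAIRS[sample.int(6, 1), ]

jitter_coords <- function(m, sigma) {
  if (sigma <= 0) return(m)
  m + matrix(rnorm(length(m), sd = sigma), nrow(m), 3)
}

## ---- builders ------------------------------------------------------------

## ideal A-form stem of L base pairs (plus seeded jitter)
build_stem_fragment <- function(L, jitter = 0, source_id = "synthetic") {
  m <- 2L * L
  seq <- character(m)
  P <- C4p <- N <- matrix(NA_real_, m, 3)
  for (t in 0:(L - 1L)) {
    nt <- random_canonical_pair()
    R <- rot_z(t * A_TWIST); tr <- c(0, 0, t * A_RISE)
    at <- pair_atoms(nt, R, tr)
    i1 <- t + 1L; i2 <- m - t
    seq[i1] <- nt[1]; seq[i2] <- nt[2]
    P[i1, ] <- at$P[1, ]; C4p[i1, ] <- at$C4p[1, ]; N[i1, ] <- at$N[1, ]
    P[i2, ] <- at$P[2, ]; C4p[i2, ] <- at$C4p[2, ]; N[i2, ] <- at$N[2, ]
  }
  pairs <- rbind(c(1L, m))
  if (L > 1L) pairs <- rbind(pairs, c(L, L + 1L))
  new_fragment("stem", integer(0), seq,
               jitter_coords(P, jitter), jitter_coords(C4p, jitter),
               jitter_coords(N, jitter), pairs, source_id, L = L)
}

## closed loop (hairpin / internal / junction): closing pairs placed as
## rigid template-pair units around a circle, unpaired residues on the
## connecting arcs. Child pairs get a random tilt (about their chord) and
## twist (about their helix axis) so fragments of one signature differ in
## the relative orientation of the helices they join.
build_loop_fragment <- function(kind, spacers, jitter = 0.3,
                                max_tilt = 45 * pi / 180,
                                max_twist = 25 * pi / 180,
                                source_id = "synthetic") {
  k <- length(spacers)
  lay <- loop_local_layout(spacers)
  m <- lay$m
  Rcirc <- loop_circle_radius(k, k + sum(spacers))
  a_pair <- 2 * asin(PAIR_C4_SPAN / 2 / Rcirc)
  a_step <- 2 * asin(C4_STEP / 2 / Rcirc)
  ## angles of every C4' position around the cycle
  ang <- numeric(m)
  ang[lay$pairs[1, 1]] <- 0
  cursor <- 0
  for (t in seq_len(k)) {
    for (p in lay$strands[[t]]) { cursor <- cursor + a_step; ang[p] <- cursor }
    if (t < k) {
      cursor <- cursor + a_step; ang[lay$pairs[t + 1L, 1]] <- cursor
      cursor <- cursor + a_pair; ang[lay$pairs[t + 1L, 2]] <- cursor
    } else {
      cursor <- cursor + a_step; ang[lay$pairs[1, 2]] <- cursor
    }
  }
  circ <- function(a) Rcirc * c(cos(a), sin(a), 0)
  seq <- character(m)
  P <- C4p <- N <- matrix(NA_real_, m, 3)
  ## closing-pair units
  for (t in seq_len(k)) {
    ia <- lay$pairs[t, 1]; ib <- lay$pairs[t, 2]
    nt <- random_canonical_pair()
    seq[ia] <- nt[1]; seq[ib] <- nt[2]
    pa <- circ(ang[ia]); pb <- circ(ang[ib])
    x_img <- unit(pb - pa)
    mid <- (pa + pb) / 2
    radial <- unit(c(mid[1], mid[2], 0))
    zdir <- if (t == 1L) -radial else radial   # helix axis; entry points inward
    z_img <- unit(zdir - sum(zdir * x_img) * x_img)
    if (t > 1L) {
      tilt <- runif(1, -max_tilt, max_tilt)
      z_img <- as.vector(rot_axis(x_img, tilt) %*% z_img)
    }
    y_img <- cross3(z_img, x_img)
    Rm <- cbind(x_img, y_img, z_img)
    at <- pair_atoms(nt)
    if (t > 1L) {
      twist <- runif(1, -max_twist, max_twist)
      ctr <- c(0, 7.86, 0)
      Tw <- rot_z(twist)
      for (nm in names(at)) at[[nm]] <- t(Tw %*% (t(at[[nm]]) - ctr)) + rep(ctr, each = 2)
    }
    tr <- pa - as.vector(Rm %*% at$C4p[1, ])
    for (nm in names(at)) at[[nm]] <- t(Rm %*% t(at[[nm]])) + rep(tr, each = 2)
    P[c(ia, ib), ] <- at$P; C4p[c(ia, ib), ] <- at$C4p; N[c(ia, ib), ] <- at$N
  }
  ## unpaired residues on the circle, N lifted out of plane, P midway back
  for (t in seq_len(k)) {
    prev <- if (t == 1L) lay$pairs[1, 1] else lay$pairs[t, 2]
    for (p in lay$strands[[t]]) {
      seq[p] <- sample(RNA_ALPHABET, 1)
      C4p[p, ] <- circ(ang[p])
      u <- unit(c(-0.25 * cos(ang[p]), -0.25 * sin(ang[p]), 1))
      N[p, ] <- C4p[p, ] + GLYCO_DIST[seq[p]] * u
      P[p, ] <- (C4p[prev, ] + C4p[p, ]) / 2 + c(0, 0, -0.8)
      prev <- p
    }
  }
  frag <- new_fragment(kind, spacers, seq,
                       jitter_coords(P, jitter), jitter_coords(C4p, jitter),
                       jitter_coords(N, jitter), lay$pairs, source_id)
  frag
}

## single strand: either a tail anchored on one closing pair (attach "5p"
## or "3p") or a free strand (attach "none"). Tails continue the helical
## backbone path away from the stem side of the pair.
build_ss_fragment <- function(L, attach = c("3p", "5p", "none"),
                              jitter = 0.3, source_id = "synthetic") {
  attach <- match.arg(attach)
  if (attach == "none") {
    m <- L
    seq <- sample(RNA_ALPHABET, L, replace = TRUE)
    P <- C4p <- N <- matrix(NA_real_, m, 3)
    for (t in seq_len(L)) {
      R <- rot_z(t * A_TWIST); tr <- c(0, 0, t * A_RISE)
      C4p[t, ] <- as.vector(R %*% PAIR_C4[1, ]) + tr
      N[t, ] <- C4p[t, ] + GLYCO_DIST[seq[t]] * as.vector(R %*% PAIR_NDIR[1, ])
      P[t, ] <- as.vector(R %*% PAIR_P[1, ]) + tr
    }
    return(new_fragment("single_strand", L, seq,
                        jitter_coords(P, jitter), jitter_coords(C4p, jitter),
                        jitter_coords(N, jitter), NULL, source_id,
                        attach = attach))
  }
  m <- L + 2L
  nt <- random_canonical_pair()
  seq <- character(m)
  P <- C4p <- N <- matrix(NA_real_, m, 3)
  at <- pair_atoms(nt)
  side <- if (attach == "3p") 2L else 1L
  if (attach == "3p") {
    ip <- 1L; jp <- 2L; strand <- 2L + seq_len(L)
    tpar <- seq_len(L)           # strand residue r sits at t = -r
  } else {
    ip <- L + 1L; jp <- L + 2L; strand <- seq_len(L)
    tpar <- rev(seq_len(L))      # last strand residue adjacent to the pair
  }
  seq[ip] <- nt[1]; seq[jp] <- nt[2]
  P[c(ip, jp), ] <- at$P; C4p[c(ip, jp), ] <- at$C4p; N[c(ip, jp), ] <- at$N
  for (r in seq_len(L)) {
    t <- tpar[r]
    pos <- strand[r]
    seq[pos] <- sample(RNA_ALPHABET, 1)
    R <- rot_z(-t * A_TWIST); tr <- c(0, 0, -t * A_RISE)
    C4p[pos, ] <- as.vector(R %*% PAIR_C4[side, ]) + tr
    N[pos, ] <- C4p[pos, ] + GLYCO_DIST[seq[pos]] * as.vector(R %*% PAIR_NDIR[side, ])
    P[pos, ] <- as.vector(R %*% PAIR_P[side, ]) + tr
  }
  new_fragment("single_strand", L, seq,
               jitter_coords(P, jitter), jitter_coords(C4p, jitter),
               jitter_coords(N, jitter), rbind(c(ip, jp)), source_id,
               attach = attach)
}

## ---- bookkeeping operations ----------------------------------------------

#' Circular permutations of a loop fragment
#'
#' Re-roots which closing pair of an internal loop or junction is the
#' "entry" pair. Coordinates are untouched; only the residue bookkeeping is
#' remapped (rotating the strand order). Only permutations whose canonical
#' topology signature equals the original's are returned, so a symmetric
#' internal loop yields one extra candidate while an asymmetric one yields
#' none.
#'
#' @param frag an `rna_fragment`.
#' @return list of permuted fragments (possibly empty).
#' @export
circular_permutations <- function(frag) {
  if (!frag$kind %in% c("internal_loop", "junction")) return(list())
  k <- length(frag$spacers)
  out <- list()
  for (r in seq_len(k - 1L)) {
    rot <- rotate_loop_fragment(frag, r)
    if (rot$signature == frag$signature) out[[length(out) + 1L]] <- rot
  }
  out
}

## rotate entry role by r closing pairs (bookkeeping only). The cycle
## order is P1.i, strand1, P2.i, P2.j, strand2, ..., Pk.i, Pk.j, strandk,
## P1.j; re-rooting at pair p = r+1 starts the traversal at Pp.j. The old
## entry pair reappears as a child traversed (j, i); the coarse pair unit
## has a C2 pseudo-dyad, so the side swap is still a proper rigid anchor.
rotate_loop_fragment <- function(frag, r) {
  k <- length(frag$spacers)
  r <- r %% k
  if (r == 0L) return(frag)
  p <- r + 1L
  lay <- loop_local_layout(frag$spacers)
  pair_seq <- c(p:k, seq_len(p - 1L))  # old pair indices in new cycle order
  ord <- integer(0)
  for (idx in seq_len(k)) {
    q <- pair_seq[idx]
    if (idx == 1L) ord <- c(ord, lay$pairs[q, 2])
    else if (q == 1L) ord <- c(ord, lay$pairs[1L, c(2, 1)])
    else ord <- c(ord, lay$pairs[q, ])
    ord <- c(ord, lay$strands[[q]])
  }
  ord <- c(ord, lay$pairs[p, 1])
  new_spacers <- frag$spacers[pair_seq]
  new_fragment(frag$kind, new_spacers, frag$seq[ord],
               frag$P[ord, , drop = FALSE], frag$C4p[ord, , drop = FALSE],
               frag$N[ord, , drop = FALSE],
               loop_local_layout(new_spacers)$pairs,
               paste0(frag$source_id, "|rot", r), attach = frag$attach)
}

#' Insert residues into an unpaired strand of a fragment
#'
#' Builds a larger fragment from a smaller one by placing `count` new
#' residues on a circular-arc interpolation between the flanking C4'
#' positions (backbone spacing kept within 4.5--7 A); glycosidic N atoms
#' are set at the canonical class distance along the local outward
#' direction. The signature is updated to the longer strand.
#'
#' @param frag an `rna_fragment`.
#' @param strand index of the unpaired strand (spacer) to grow.
#' @param position insert after this many existing strand residues (0 =
#'   at the strand start).
#' @param count number of residues to insert (>= 1).
#' @param codes optional nucleotide codes for the new residues.
#' @return the grown `rna_fragment`.
#' @export
insert_residues <- function(frag, strand, position, count, codes = NULL) {
  if (count < 1) stop("count must be >= 1")
  if (strand < 1 || strand > max(1L, length(frag$spacers))) stop("no such strand")
  if (is.null(codes)) codes <- sample(RNA_ALPHABET, count, replace = TRUE)
  if (length(codes) != count) stop("codes length must equal count")
  m <- fragment_size(frag)
  if (frag$kind == "stem") stop("cannot insert into a paired region")
  if (frag$kind == "single_strand") {
    lay_str <- list(which(!seq_len(m) %in% as.vector(frag$pairs)))
  } else {
    lay <- loop_local_layout(frag$spacers)
    lay_str <- lay$strands
  }
  spos <- lay_str[[strand]]
  if (position < 0 || position > length(spos)) stop("insertion position outside the strand")
  ## insertion point: between local index `ins_prev` and `ins_prev + 1`
  ins_prev <- if (position > 0L) {
    spos[position]
  } else if (length(spos)) {
    spos[1] - 1L
  } else if (frag$kind == "single_strand") {
    stop("empty strand needs flanking anchors")
  } else if (strand == 1L) {
    lay$pairs[1, 1]
  } else {
    lay$pairs[strand, 2]
  }
  if (ins_prev < 1L || ins_prev >= m) stop("insertion site has no flanking residues")
  A <- frag$C4p[ins_prev, ]; B <- frag$C4p[ins_prev + 1L, ]
  centroid <- colMeans(frag$C4p)
  dirn <- (A + B) / 2 - centroid
  if (sqrt(sum(dirn^2)) < 1e-6) dirn <- c(0, 0, 1)
  pts <- arc_points(A, B, count, dirn)
  newP <- newC <- newN <- matrix(NA_real_, count, 3)
  prev <- A
  for (t in seq_len(count)) {
    newC[t, ] <- pts[t, ]
    u <- unit(pts[t, ] - centroid)
    newN[t, ] <- pts[t, ] + GLYCO_DIST[codes[t]] * u
    newP[t, ] <- (prev + pts[t, ]) / 2 + 0.6 * unit(dirn)
    prev <- pts[t, ]
  }
  ins <- function(old, new) rbind(old[seq_len(ins_prev), , drop = FALSE], new,
                                  old[(ins_prev + 1L):m, , drop = FALSE])
  seq2 <- c(frag$seq[seq_len(ins_prev)], codes, frag$seq[(ins_prev + 1L):m])
  shift <- function(idx) ifelse(idx > ins_prev, idx + count, idx)
  pairs2 <- frag$pairs
  if (nrow(pairs2)) pairs2 <- matrix(shift(pairs2), ncol = 2)
  spacers2 <- frag$spacers
  spacers2[strand] <- spacers2[strand] + count
  new_fragment(frag$kind, spacers2, seq2,
               ins(frag$P, newP), ins(frag$C4p, newC), ins(frag$N, newN),
               pairs2, paste0(frag$source_id, "|ins", count),
               attach = frag$attach, L = frag$L)
}

#' Mutate a fragment to a target sequence
#'
#' Replaces the nucleotide codes of a fragment. When a residue changes
#' base class (purine <-> pyrimidine) its glycosidic N is repositioned
#' along the C4'->N axis to the canonical glycosidic distance of the new
#' class (purine 4.3 A, pyrimidine 3.4 A); all other coordinates are
#' untouched.
#'
#' @param frag an `rna_fragment`.
#' @param target character vector of nucleotide codes, one per residue in
#'   motif order.
#' @return the mutated `rna_fragment`.
#' @export
mutate_to_sequence <- function(frag, target) {
  target <- toupper(target)
  if (length(target) == 1L && nchar(target) > 1L) target <- strsplit(target, "")[[1]]
  if (length(target) != fragment_size(frag)) {
    stop(sprintf("target length %d does not match fragment size %d",
                 length(target), fragment_size(frag)))
  }
  if (any(!target %in% RNA_ALPHABET)) stop("invalid nucleotide code in target")
  N <- frag$N
  for (t in seq_len(length(target))) {
    d_old <- GLYCO_DIST[frag$seq[t]]
    d_new <- GLYCO_DIST[target[t]]
    if (d_old != d_new) {
      u <- unit(N[t, ] - frag$C4p[t, ])
      N[t, ] <- frag$C4p[t, ] + d_new * u
    }
  }
  out <- frag
  out$seq <- unname(target)
  out$N <- N
  out
}
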