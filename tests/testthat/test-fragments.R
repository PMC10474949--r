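stem_sig <- function(frag) topology_signature(frag)

test_that("stem fragments reproduce ideal A-form geometry", {
  frag <- rnamason:::with_seed(1, rnamason:::build_stem_fragment(4, jitter = 0))
  expect_equal(stem_sig(frag), "stem:4")
  expect_length(frag$seq, 8L)
  ## paired C4'-C4' span
  for (t in 1:4) {
    d <- sqrt(sum((frag$C4p[t, ] - frag$C4p[9 - t, ])^2))
    expect_equal(d, 10.3, tolerance = 1e-6)
  }
  ## helical rise between consecutive pairs
  mid1 <- (frag$C4p[1, ] + frag$C4p[8, ]) / 2
  mid2 <- (frag$C4p[2, ] + frag$C4p[7, ]) / 2
  expect_equal(abs(mid2[3] - mid1[3]), 2.81, tolerance = 1e-6)
  ## glycosidic N of every canonical pair at the pairing distance
  for (t in 1:4) {
    dnn <- sqrt(sum((frag$N[t, ] - frag$N[9 - t, ])^2))
    expect_equal(dnn, 8.92, tolerance = 0.02)
  }
  ## chain continuity along each strand
  for (t in 1:3) {
    expect_lt(abs(sqrt(sum((frag$C4p[t + 1, ] - frag$C4p[t, ])^2)) - 5.99), 0.1)
  }
})

test_that("loop fragments close their cycle with template-sized pairs", {
  frag <- rnamason:::with_seed(2, rnamason:::build_loop_fragment(
    "junction", c(2L, 2L, 2L), jitter = 0))
  expect_equal(topology_signature(frag), "junction:3:2-2-2")
  expect_length(frag$seq, 12L)  # 3 pairs + 6 spacers
  for (r in seq_len(nrow(frag$pairs))) {
    d <- sqrt(sum((frag$C4p[frag$pairs[r, 1], ] - frag$C4p[frag$pairs[r, 2], ])^2))
    expect_equal(d, 10.3, tolerance = 1e-6)
  }
  ## consecutive residues along the cycle sit at spacer chords (~5.9 A)
  ## or cross a closing pair (10.3 A)
  steps <- sqrt(rowSums(diff(frag$C4p)^2))
  expect_true(all(steps > 3 & steps < 10.5))
})

test_that("circular permutations preserve the canonical signature", {
  frag <- rnamason:::with_seed(3, rnamason:::build_loop_fragment(
    "junction", c(1L, 2L, 3L), jitter = 0))
  ## the identity is not re-issued, leaving k - 1 = 2 rotations
  perms <- circular_permutations(frag)
  expect_length(perms, 2L)
  sigs <- vapply(perms, topology_signature, "")
  expect_true(all(sigs == sigs[1]))
  ## the rotated fragment exposes the rotated spacer order
  rot <- rnamason:::rotate_loop_fragment(frag, 1L)
  expect_equal(rot$spacers, c(2L, 3L, 1L))
  ## rotation is a relabeling: the multiset of pair distances is unchanged
  d0 <- sort(sqrt(rowSums((frag$C4p[frag$pairs[, 1], ] -
                           frag$C4p[frag$pairs[, 2], ])^2)))
  d1 <- sort(sqrt(rowSums((rot$C4p[rot$pairs[, 1], ] -
                           rot$C4p[rot$pairs[, 2], ])^2)))
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("residue insertion grows a strand while keeping continuity", {
  frag <- rnamason:::with_seed(4, rnamason:::build_loop_fragment(
    "internal_loop", c(2L, 2L), jitter = 0))
  grown <- insert_residues(frag, strand = 1L, position = 1L, count = 2L,
                           codes = c("A", "A"))
  expect_equal(grown$spacers, c(4L, 2L))
  expect_equal(topology_signature(grown), "internal:4-2")
  expect_length(grown$seq, length(frag$seq) + 2L)
  steps <- sqrt(rowSums(diff(grown$C4p)^2))
  expect_true(all(steps > 2.5 & steps < 11))
})

test_that("sequence mutation rescales the glycosidic distance by class", {
  frag <- rnamason:::with_seed(5, rnamason:::build_stem_fragment(2, jitter = 0))
  target <- c("A", "U", "A", "U")
  mut <- mutate_to_sequence(frag, target)
  expect_equal(mut$seq, target)
  for (t in seq_along(target)) {
    d <- sqrt(sum((mut$N[t, ] - mut$C4p[t, ])^2))
    expected <- if (target[t] %in% c("A", "G")) 4.3 else 3.4
    expect_equal(d, expected, tolerance = 1e-6)
  }
  expect_equal(mut$C4p, frag$C4p)  # backbone untouched
})

test_that("single-strand fragments come in all attachment variants", {
  for (at in c("5p", "3p", "none")) {
    frag <- rnamason:::with_seed(6, rnamason:::build_ss_fragment(3, at, jitter = 0))
    expect_equal(frag$attach, at)
    expect_equal(topology_signature(frag), "ss:3")
    expect_length(frag$seq, if (at == "none") 3L else 5L)
  }
})
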