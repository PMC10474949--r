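test_that("annotation recovers the pairs of an assembled model", {
  sys <- toy_system()
  m <- assemble_starting_model(sys$graph, sys$sets, beam_width = 10)
  ann <- annotate_secondary_structure(m)
  rec <- pair_recovery(ann, sys$res$ss)
  expect_equal(rec$fraction, 1)
  ## no spurious extra pairs on this clean model
  expect_equal(nrow(ann$pairs), nrow(sys$res$ss$nested))
})

test_that("annotation ignores non-canonical combinations and far pairs", {
  ## two A residues at perfect pairing geometry: not canonical, no pair
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0), c(9, 0, 0), c(30, 0, 0))
  N <- rbind(c(0, 0, 0), c(30, 0, 0), c(60, 0, 0), c(8.9, 0, 0), c(90, 0, 0))
  C4 <- rbind(c(0, 2, 0), c(30, 2, 0), c(60, 2, 0), c(10.2, 2, 0), c(90, 2, 0))
  m_aa <- rnamason:::new_model(c("A", "C", "G", "A", "G"), xyz, C4, N, NULL)
  ann <- annotate_secondary_structure(m_aa)
  expect_equal(nrow(ann$pairs), 0L)
  ## same geometry with G/C partners is detected
  m_gc <- rnamason:::new_model(c("G", "A", "A", "C", "G"), xyz, C4, N, NULL)
  ann2 <- annotate_secondary_structure(m_gc)
  expect_equal(unname(ann2$pairs), rbind(c(1L, 4L)))
})

test_that("annotated crossing pairs are split out as pseudoknots", {
  ## build two perfect pair geometries that cross: (1,5) and (3,8)
  place_pair <- function(m, i, j, origin) {
    tpl <- rnamason:::pair_atoms(c("G", "C"), diag(3), origin)
    for (w in 1:2) {
      idx <- c(i, j)[w]
      m$P[idx, ] <- tpl$P[w, ]; m$C4p[idx, ] <- tpl$C4p[w, ]; m$N[idx, ] <- tpl$N[w, ]
    }
    m
  }
  far <- matrix(rep(seq(100, 800, by = 100), 3), 8, 3)
  m <- rnamason:::new_model(c("G", "A", "G", "A", "C", "A", "A", "C"),
                            far, far, far, NULL)
  m <- place_pair(m, 1, 5, c(0, 0, 0))
  m <- place_pair(m, 3, 8, c(50, 0, 0))
  ann <- annotate_secondary_structure(m)
  expect_equal(nrow(ann$nested), 1L)
  expect_equal(nrow(ann$pseudoknot), 1L)
})

test_that("pair recovery reports fractions correctly", {
  ref <- remove_pseudoknots(parse_dotbracket("GGGGAAAACCCC", "((((....))))"))$ss
  partial <- rnamason:::new_secstruct(ref$seq, ref$nested[1:2, ],
                                      nested = ref$nested[1:2, ], resolved = TRUE)
  rec <- pair_recovery(partial, ref)
  expect_equal(rec$recovered, 2L)
  expect_equal(rec$reference, 4L)
  expect_equal(rec$fraction, 0.5)
})
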