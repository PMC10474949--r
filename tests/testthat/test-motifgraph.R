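test_that("hairpin decomposition yields stem + hairpin loop", {
  ss <- remove_pseudoknots(parse_dotbracket("GGGGAAAACCCC", "((((....))))"))$ss
  g <- decompose_motifs(ss)
  kinds <- vapply(g$nodes, `[[`, "", "kind")
  sigs <- vapply(g$nodes, `[[`, "", "signature")
  expect_setequal(kinds, c("stem", "hairpin_loop"))
  expect_setequal(sigs, c("stem:4", "hairpin:4"))
  expect_equal(nrow(g$edges), 1L)
  expect_true(rnamason:::graph_is_tree(g))
  ## every residue is covered and shared residues are exactly closing pairs
  expect_equal(rnamason:::graph_residues(g), 1:12)
})

test_that("three-way junction and tails decompose correctly", {
  seqs <- "AAGGGGAAGGGGAAAACCCCAAGGGGAAAACCCCAACCCCAA"
  db   <- "..((((..((((....))))..((((....))))..)))).."
  ss <- remove_pseudoknots(parse_dotbracket(seqs, db))$ss
  g <- decompose_motifs(ss)
  kinds <- vapply(g$nodes, `[[`, "", "kind")
  sigs <- vapply(g$nodes, `[[`, "", "signature")
  expect_equal(sum(kinds == "stem"), 3L)
  expect_equal(sum(kinds == "junction"), 1L)
  expect_equal(sum(kinds == "hairpin_loop"), 2L)
  expect_equal(sum(kinds == "single_strand"), 2L)  # 5' and 3' tails
  expect_true("junction:3:2-2-2" %in% sigs)
  jn <- g$nodes[[which(sigs == "junction:3:2-2-2")]]
  expect_equal(nrow(jn$pairs), 3L)
  expect_equal(jn$spacers, c(2L, 2L, 2L))
  ## the junction layout starts and ends on the entry pair
  expect_equal(jn$layout[1], unname(jn$pairs[1, 1]))
  expect_equal(jn$layout[length(jn$layout)], unname(jn$pairs[1, 2]))
  expect_true(rnamason:::graph_is_tree(g))
})

test_that("internal loop signature keeps strand order", {
  ss <- remove_pseudoknots(parse_dotbracket(
    "GGGAGGGAAAACCCAAACCC", "(((.(((....)))...)))"))$ss
  g <- decompose_motifs(ss)
  sigs <- vapply(g$nodes, `[[`, "", "signature")
  expect_true("internal:1-3" %in% sigs)
})

test_that("junction signature uses the minimal rotation", {
  expect_equal(rnamason:::min_rotation(c(3L, 1L, 2L)), c(1L, 2L, 3L))
  expect_equal(rnamason:::loop_signature("junction", c(3L, 1L, 2L)),
               "junction:3:1-2-3")
})

test_that("exterior with several helices becomes an open junction", {
  seqs <- "GGGGAAAACCCCAAGGGGAAAACCCC"
  db   <- "((((....))))..((((....))))"
  ss <- remove_pseudoknots(parse_dotbracket(seqs, db))$ss
  g <- decompose_motifs(ss)
  open <- Filter(function(nd) isTRUE(nd$open), g$nodes)
  expect_length(open, 1L)
  expect_equal(open[[1]]$kind, "junction")
  expect_equal(open[[1]]$spacers, c(0L, 2L, 0L))
  expect_true(rnamason:::graph_is_tree(g))
})

test_that("fully unpaired input is a single strand node", {
  ss <- remove_pseudoknots(parse_dotbracket("AAAAA", "....."))$ss
  g <- decompose_motifs(ss)
  expect_length(g$nodes, 1L)
  expect_equal(g$nodes[[1]]$kind, "single_strand")
  expect_equal(g$nodes[[1]]$attach, "none")
})
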