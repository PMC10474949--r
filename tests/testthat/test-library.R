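test_that("synthetic library generation honours the composition", {
  cfg <- c("stem:3" = 4L, "hairpin:4" = 5L, "internal:1-2" = 2L, "ss:2" = 2L)
  lib <- generate_synthetic_library(cfg, seed = 11)
  counts <- library_counts(lib)
  expect_equal(unname(counts["stem:3"]), 4L)
  expect_equal(unname(counts["hairpin:4"]), 5L)
  expect_equal(unname(counts["internal:1-2"]), 2L)
  ## single strands are emitted in all three attachment variants
  expect_equal(unname(counts["ss:2"]), 6L)
  ## same seed, same library
  lib2 <- generate_synthetic_library(cfg, seed = 11)
  expect_equal(lib$fragments[["stem:3"]][[1]]$C4p,
               lib2$fragments[["stem:3"]][[1]]$C4p)
})

test_that("library write/read round-trips fragments through PDB", {
  cfg <- c("stem:2" = 2L, "hairpin:3" = 2L)
  lib <- generate_synthetic_library(cfg, seed = 3)
  dir <- file.path(tempdir(), "libtest")
  write_fragment_library(lib, dir)
  expect_true(file.exists(file.path(dir, "index.tsv")))
  back <- read_fragment_library(dir)
  expect_equal(sort(names(back$fragments)), sort(names(lib$fragments)))
  a <- lib$fragments[["hairpin:3"]][[1]]
  b <- back$fragments[["hairpin:3"]][[1]]
  expect_equal(a$seq, b$seq)
  expect_equal(a$C4p, b$C4p, tolerance = 1e-3)
  expect_equal(a$spacers, b$spacers)
})

test_that("reading a library with a missing coordinate file errors", {
  cfg <- c("stem:2" = 1L)
  lib <- generate_synthetic_library(cfg, seed = 3)
  dir <- file.path(tempdir(), "libtest2")
  write_fragment_library(lib, dir)
  idx <- read.table(file.path(dir, "index.tsv"), header = TRUE, sep = "\t",
                    comment.char = "")
  file.remove(file.path(dir, idx$file[1]))
  expect_error(read_fragment_library(dir), "missing")
})

test_that("fragment matching finds exact and rotated candidates", {
  sys <- toy_system(n_frag = 6)
  expect_length(sys$sets, 2L)
  for (s in sys$sets) expect_gte(length(s$candidates), 6L)
  ## every candidate matches the node signature
  for (i in seq_along(sys$sets)) {
    sig <- sys$graph$nodes[[i]]$signature
    expect_true(all(vapply(sys$sets[[i]]$candidates, topology_signature, "") == sig))
  }
  ## candidates carry the target sequence of their node
  node <- sys$graph$nodes[[2]]
  for (fr in sys$sets[[2]]$candidates) {
    expect_equal(fr$seq, sys$res$ss$seq[node$layout])
  }
})

test_that("junction rotations are offered as extra candidates", {
  ss <- remove_pseudoknots(parse_dotbracket(
    "GGGGAAGGGGAAAACCCCAAGGGGAAAACCCCACCCC",
    "((((..((((....))))..((((....)))).))))"))$ss
  g <- decompose_motifs(ss)
  jn <- which(vapply(g$nodes, `[[`, "", "kind") == "junction")
  ## the node's spacer order (2,2,1) is a rotation of the stored 1-2-2
  lib <- generate_synthetic_library(c("junction:3:1-2-2" = 3L,
                                      "stem:4" = 3L, "hairpin:4" = 3L), seed = 9)
  set <- match_fragments(g$nodes[[jn]], lib, min_count = 1)
  expect_gte(length(set$candidates), 3L)
  for (fr in set$candidates) expect_equal(fr$spacers, g$nodes[[jn]]$spacers)
})

test_that("missing signatures are grown from smaller donors", {
  ss <- remove_pseudoknots(parse_dotbracket("GGGGAAAAAACCCC", "((((......))))"))$ss
  g <- decompose_motifs(ss)
  hp <- which(vapply(g$nodes, `[[`, "", "kind") == "hairpin_loop")
  lib <- generate_synthetic_library(c("hairpin:4" = 3L, "stem:4" = 3L), seed = 2)
  set <- match_fragments(g$nodes[[hp]], lib, min_count = 1)
  expect_gte(length(set$candidates), 1L)
  for (fr in set$candidates) expect_equal(topology_signature(fr), "hairpin:6")
})

test_that("a node with no obtainable candidates raises a named error", {
  ss <- remove_pseudoknots(parse_dotbracket("GGGGAAAACCCC", "((((....))))"))$ss
  g <- decompose_motifs(ss)
  lib <- generate_synthetic_library(c("stem:4" = 2L), seed = 2)
  hp <- which(vapply(g$nodes, `[[`, "", "kind") == "hairpin_loop")
  expect_error(match_fragments(g$nodes[[hp]], lib, min_count = 1), "hairpin:4")
})
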