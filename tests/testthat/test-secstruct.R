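test_that("dot-bracket parsing handles families, errors and constraints", {
  ss <- parse_dotbracket("GGAAUC", "((..))")
  expect_equal(ss$pairs, cbind(i = c(1L, 2L), j = c(6L, 5L)), ignore_attr = FALSE)
  expect_false(ss$resolved)

  ## multiple bracket families encode a pseudoknot
  pk <- parse_dotbracket("GGGAAAACCCUUUCCC", "(((..[[.)))..]].")
  expect_equal(nrow(pk$pairs), 5L)

  expect_error(parse_dotbracket("GG", "((.."), "length")
  expect_error(parse_dotbracket("GXGA", "...."), "invalid nucleotide code 'X' at position 2")
  expect_error(parse_dotbracket("GGAA", "(..."), "unbalanced")
  expect_error(parse_dotbracket("GGAA", "...)"), "unbalanced")
  expect_error(parse_dotbracket("GGCC", "(())"), "minimum hairpin")
  expect_error(parse_dotbracket("GGAA", "(.!)"), "unknown structure character")
})

test_that("pseudoknot removal maximizes nested pairs and emits restraints", {
  ## nested-only input is untouched
  ss <- parse_dotbracket("GGGGAAAACCCC", "((((....))))")
  out <- remove_pseudoknots(ss)
  expect_true(out$ss$resolved)
  expect_equal(nrow(out$ss$nested), 4L)
  expect_equal(nrow(out$ss$pseudoknot), 0L)
  expect_equal(nrow(out$restraints), 0L)

  ## 3 + 2 crossing pairs: the larger group must be kept
  pk <- parse_dotbracket("GGGAAAACCCUUUCCC", "(((..[[.)))..]].")
  out <- remove_pseudoknots(pk)
  expect_equal(nrow(out$ss$nested), 3L)
  expect_equal(nrow(out$ss$pseudoknot), 2L)
  ## removed pairs become flat-bottom restraints with canonical defaults
  expect_equal(out$restraints$target, c(9, 9))
  expect_equal(out$restraints$flat_width, c(1, 1))
  expect_equal(out$restraints$weight, c(1, 1))
  expect_equal(out$restraints$i, out$ss$pseudoknot[, 1])
})

test_that("pseudoknot removal tie-break is deterministic and lexicographic", {
  ## two crossing pairs of equal weight: keeping the lexicographically
  ## smaller pair makes the smallest removed pair as large as possible
  seqs <- paste(rep("G", 8), collapse = "")
  ss <- rnamason:::new_secstruct(strsplit(seqs, "")[[1]], rbind(c(1, 5), c(3, 8)))
  out <- remove_pseudoknots(ss)
  expect_equal(unname(out$ss$nested[1, ]), c(1L, 5L))
  expect_equal(unname(out$ss$pseudoknot[1, ]), c(3L, 8L))
})

test_that("dot-bracket writing round-trips and layers pseudoknots", {
  db <- "(((..[[.)))..]]."
  ss <- remove_pseudoknots(parse_dotbracket("GGGAAAACCCUUUCCC", db))$ss
  written <- write_dotbracket(ss)
  reparsed <- remove_pseudoknots(parse_dotbracket("GGGAAAACCCUUUCCC", written))$ss
  expect_equal(reparsed$pairs, ss$pairs)

  path <- file.path(tempdir(), "ss_report")
  files <- write_secstruct_report(ss, path)
  expect_true(all(file.exists(paste0(path, c(".dbn", ".tsv")))))
  tab <- read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 5L)
  expect_setequal(unique(tab$class), c("nested", "pseudoknot"))
})
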