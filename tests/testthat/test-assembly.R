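test_that("a hairpin assembles without clashes and with tight anchors", {
  sys <- toy_system()
  m <- assemble_starting_model(sys$graph, sys$sets, beam_width = 10)
  expect_s3_class(m, "rna_model")
  expect_length(m$seq, 12L)
  expect_false(anyNA(m$P))
  expect_equal(count_clashes(m), 0L)
  expect_identical(attr(m, "clash_count"), 0L)
  ## chain continuity of the assembled model
  steps <- sqrt(rowSums(diff(m$C4p)^2))
  expect_true(all(steps > 3 & steps < 9))
})

test_that("grid clash counting equals the quadratic oracle", {
  set.seed(31)
  for (k in 1:10) {
    n <- 80
    pairs <- cbind(seq(1, 20, by = 2), seq(61, 80, by = 2))
    m <- random_model(n, box = 25, seed = k, pairs = pairs)
    expect_identical(count_clashes(m), oracle_clash_count(m))
  }
})

test_that("clash counting excludes neighbours and paired residues", {
  ## three residues on top of each other: (1,2) adjacent, (1,3) paired
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- rnamason:::new_model(c("G", "A", "C"), xyz, xyz, xyz, rbind(c(1L, 3L)))
  expect_identical(count_clashes(m), 0L)  # (1,2),(2,3) adjacent; (1,3) paired
  m2 <- rnamason:::new_model(c("G", "A", "C"), xyz, xyz, xyz, NULL)
  expect_identical(count_clashes(m2), 1L)  # only (1,3) is not adjacent
})

test_that("deterministic rebuild reproduces the assembled model", {
  sys <- toy_system()
  m <- assemble_starting_model(sys$graph, sys$sets, beam_width = 10)
  rebuilt <- rnamason:::build_from_choices(sys$graph, sys$sets, sys$order,
                                           m$choices)
  expect_equal(rebuilt$C4p, m$C4p, tolerance = 1e-12)
  expect_equal(rebuilt$provenance, m$provenance)
})

test_that("fragment placement anchors on the shared pair", {
  sys <- toy_system()
  partial <- new_partial_model(sys$graph)
  partial <- place_fragment(partial, sys$graph$nodes[[1]],
                            sys$sets[[1]]$candidates[[1]])
  expect_true(all(partial$placed[sys$graph$nodes[[1]]$layout]))
  partial2 <- place_fragment(partial, sys$graph$nodes[[2]],
                             sys$sets[[2]]$candidates[[1]])
  expect_true(all(partial2$placed))
  ## placed stem residues were not overwritten by the loop fragment
  expect_equal(partial2$C4p[sys$graph$nodes[[1]]$layout, ],
               partial$C4p[sys$graph$nodes[[1]]$layout, ])
  ## a fragment with no placed shared pair is rejected
  empty <- new_partial_model(sys$graph)
  empty <- place_fragment(empty, sys$graph$nodes[[2]],
                          sys$sets[[2]]$candidates[[1]])
  expect_error(place_fragment(empty, sys$graph$nodes[[2]],
                              sys$sets[[2]]$candidates[[2]], anchor_tol = 0),
               "rejected")
})

test_that("assembly starts from the leaf with fewest candidates", {
  sys <- toy_system()
  ## hairpin node has its candidates truncated to make it the rarest leaf
  sets <- sys$sets
  hp <- which(vapply(sys$graph$nodes, `[[`, "", "kind") == "hairpin_loop")
  sets[[hp]]$candidates <- sets[[hp]]$candidates[1:2]
  ord <- rnamason:::assembly_order(sys$graph, sets)
  expect_equal(ord[1], hp)
})
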