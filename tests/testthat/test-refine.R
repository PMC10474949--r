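test_that("temperature ladder is geometric", {
  expect_equal(temperature_ladder(2, 0.5, 16), c(0.5, 16))
  expect_equal(temperature_ladder(4, 1, 8), c(1, 2, 4, 8))
  expect_equal(temperature_ladder(1, 0.7, 16), 0.7)
  ladder <- temperature_ladder(8, 0.5, 16)
  ratios <- ladder[-1] / ladder[-8]
  expect_lt(max(ratios) - min(ratios), 1e-12)
})

test_that("Metropolis acceptance follows the canonical law", {
  expect_true(metropolis_accept(-1, 0.5))
  expect_true(metropolis_accept(0, 0.5))
  ## delta = T ln 2 accepts with probability 1/2
  set.seed(123)
  Tt <- 2
  acc <- mean(replicate(10000, metropolis_accept(Tt * log(2), Tt)))
  expect_lt(abs(acc - 0.5), 0.02)
  ## essentially infinite temperature accepts everything
  set.seed(5)
  expect_true(all(replicate(200, metropolis_accept(50, 1e12))))
})

test_that("refinement is reproducible and never worse than the start", {
  sys <- toy_system()
  pot <- derive_potential(sys$lib)
  start <- assemble_starting_model(sys$graph, sys$sets, beam_width = 5)
  sc0 <- total_score(start, pot)
  run <- function() {
    run_refinement(sys$graph, sys$sets, pot, start = start, n_replicas = 3,
                   n_steps = 40, swap_interval = 10, seed = 99)
  }
  a <- run(); b <- run()
  expect_equal(a$trace, b$trace)
  expect_equal(a$best_total, b$best_total)
  expect_lte(a$best_total, sc0$total)
  ## best score is a lower bound on everything traced
  expect_true(all(a$trace$total >= a$best_total - 1e-9))
  ## reported score equals a from-scratch recomputation
  expect_equal(a$score$total, total_score(a$model, pot)$total, tolerance = 1e-9)
})

test_that("zero steps returns the starting model unchanged", {
  sys <- toy_system()
  pot <- derive_potential(sys$lib)
  start <- assemble_starting_model(sys$graph, sys$sets, beam_width = 5)
  r <- run_refinement(sys$graph, sys$sets, pot, start = start, n_replicas = 2,
                      n_steps = 0, seed = 1)
  expect_equal(r$model$C4p, start$C4p, tolerance = 1e-12)
})

test_that("a terminal hairpin move leaves all other residues fixed", {
  sys <- toy_system()
  hp <- which(vapply(sys$graph$nodes, `[[`, "", "kind") == "hairpin_loop")
  ch1 <- rep(1L, 2); ch2 <- ch1; ch2[hp] <- 2L
  m1 <- rnamason:::build_from_choices(sys$graph, sys$sets, sys$order, ch1)
  m2 <- rnamason:::build_from_choices(sys$graph, sys$sets, sys$order, ch2)
  stem_res <- sys$graph$nodes[[which(vapply(sys$graph$nodes, `[[`, "", "kind") == "stem")]]$layout
  expect_equal(m1$C4p[stem_res, ], m2$C4p[stem_res, ], tolerance = 1e-9)
  loop_only <- setdiff(sys$graph$nodes[[hp]]$layout, stem_res)
  expect_gt(max(abs(m1$C4p[loop_only, ] - m2$C4p[loop_only, ])), 1e-6)
})

test_that("an interior move transports the distal subtree rigidly", {
  tg <- benchmark_target("three_stem", n_fragments = 4)
  res <- remove_pseudoknots(parse_dotbracket(tg$sequence, tg$structure))
  g <- decompose_motifs(res$ss)
  lib <- generate_synthetic_library(tg$library_config, seed = 21)
  sets <- lapply(g$nodes, match_fragments, lib = lib, min_count = 2,
                 target_seq = res$ss$seq)
  ord <- rnamason:::assembly_order(g, sets)
  jn <- which(vapply(g$nodes, `[[`, "", "kind") == "junction")
  ch1 <- rep(1L, length(g$nodes)); ch2 <- ch1; ch2[jn] <- 2L
  m1 <- rnamason:::build_from_choices(g, sets, ord, ch1)
  m2 <- rnamason:::build_from_choices(g, sets, ord, ch2)
  ## pairwise distances within each distal hairpin stem are preserved
  hairpins <- which(vapply(g$nodes, `[[`, "", "kind") == "hairpin_loop")
  for (hp in hairpins) {
    res_ids <- g$nodes[[hp]]$layout
    d1 <- dist(m1$C4p[res_ids, ])
    d2 <- dist(m2$C4p[res_ids, ])
    expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-8)
  }
})

test_that("replica swaps respect the exchange probability in edge cases", {
  ## a better model at higher temperature must always swap downward:
  ## exponent (1/T_lo - 1/T_hi)(S_lo - S_hi) > 0 when S_hi < S_lo
  p <- exp((1 / 0.5 - 1 / 4) * (10 - 2))
  expect_gte(p, 1)
  ## equal scores always swap
  expect_equal(exp((1 / 0.5 - 1 / 4) * 0), 1)
})
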