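lib_small <- generate_synthetic_library(c("stem:4" = 4L, "hairpin:4" = 4L),
                                        seed = 17)
pot <- derive_potential(lib_small)

test_that("the statistical potential table is well-formed", {
  expect_equal(dim(pot$table), c(6L, 40L))
  expect_true(all(pot$table >= -5 & pot$table <= 5))
  ## observed helix distances score below the clamp ceiling
  expect_lt(min(pot$table), 0)
})

test_that("potential scoring matches the quadratic oracle and edge cases", {
  ## two adjacent residues: no eligible pair
  m2 <- random_model(2, seed = 1)
  expect_equal(score_potential(m2, pot), 0)
  ## 50-residue random model vs brute-force double loop
  m50 <- random_model(50, box = 30, seed = 2)
  expect_equal(score_potential(m50, pot), oracle_potential(m50, pot),
               tolerance = 1e-9)
})

test_that("flat-bottom restraints score piecewise correctly", {
  ## place two N atoms at a controlled distance
  mk <- function(d) {
    xyz <- rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0), c(d, 0, 0))
    rnamason:::new_model(c("G", "A", "A", "C"), xyz, xyz,
                         rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0), c(d, 0, 0)),
                         NULL)
  }
  rs <- data.frame(i = 1L, j = 4L, target = 9, flat_width = 1, weight = 2)
  expect_equal(score_restraints(mk(9.5), rs), 0)     # inside the flat bottom
  expect_equal(score_restraints(mk(12), rs), 2 * 4)  # (12-9-1)^2 * w
  expect_equal(score_restraints(mk(6), rs), 2 * 4)   # symmetric side
  expect_equal(score_restraints(mk(9.5), NULL), 0)
})

test_that("Debye curve matches the two-bead closed form to 1e-10", {
  xyz <- rbind(c(0, 0, 0), c(7.3, 0, 0))
  m <- rnamason:::new_model(c("G", "U"), xyz, xyz, xyz, NULL)
  q <- seq(0.01, 0.5, by = 0.01)
  curve <- compute_saxs_curve(m, q)
  expect_equal(curve$I, oracle_two_bead_I(165, 140, 7.3, q),
               tolerance = 1e-10)
  ## forward scattering is the squared total electron count
  c0 <- compute_saxs_curve(m, c(1e-12, 0.1))
  expect_equal(c0$I[1], (165 + 140)^2, tolerance = 1e-6)
})

test_that("Guinier Rg of simulated curves matches coordinate Rg", {
  for (s in 1:5) {
    m <- random_model(30, box = 30, seed = s)
    w <- rnamason:::FORM_FACTOR[m$seq]
    rg <- rnamason:::coord_rg(m$C4p, w)
    q <- seq(0.002, 1 / rg, length.out = 60)
    curve <- compute_saxs_curve(m, q)
    fit <- lm(log(curve$I) ~ I(curve$q^2))
    rg_guinier <- sqrt(-3 * coef(fit)[[2]])
    ## a Gaussian bead of width r contributes 3 r^2 to the apparent Rg^2
    rg_expected <- sqrt(rg^2 + 3 * 2.5^2)
    expect_lt(abs(rg_guinier - rg_expected) / rg_expected, 0.02)
  }
})

test_that("chi-square scale invariance and closed-form optimality", {
  m <- random_model(20, box = 30, seed = 4)
  q <- seq(0.01, 0.4, length.out = 80)
  base <- compute_saxs_curve(m, q)
  exp_same <- rnamason:::new_saxs_curve(q, base$I, 0.05 * base$I)
  r <- chi_square(base, exp_same)
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$scale, 1, tolerance = 1e-12)
  exp_double <- rnamason:::new_saxs_curve(q, 2 * base$I, 0.05 * base$I)
  r2 <- chi_square(base, exp_double)
  expect_equal(r2$chi2, 0, tolerance = 1e-12)
  expect_equal(r2$scale, 2, tolerance = 1e-12)
  ## perturbed data: the closed-form scale beats any scanned scale
  set.seed(9)
  exp_noisy <- rnamason:::new_saxs_curve(q, base$I * (1 + rnorm(80, 0, 0.05)),
                                         0.05 * base$I)
  ropt <- chi_square(base, exp_noisy)
  chi_at <- function(cc) {
    sum(((cc * base$I - exp_noisy$I) / exp_noisy$sigma)^2) / (80 - 1)
  }
  for (cc in seq(0.8, 1.2, by = 0.01)) {
    expect_gte(chi_at(cc) + 1e-12, ropt$chi2)
  }
  ## chi-square is invariant under scaling the model curve
  scaled <- rnamason:::new_saxs_curve(q, 3.7 * base$I, rep(NA_real_, 80))
  expect_equal(chi_square(scaled, exp_noisy)$chi2, ropt$chi2, tolerance = 1e-9)
})

test_that("SAXS correction factor has the documented shape", {
  expect_equal(saxs_correction_factor(2), exp(-0.5) + 0.5 * exp(-0.05),
               tolerance = 1e-12)
  ## decays monotonically away from 1 on both sides
  xs <- seq(1, 6, by = 0.25)
  expect_true(all(diff(saxs_correction_factor(xs)) < 0))
  expect_equal(saxs_correction_factor(0.5), saxs_correction_factor(1.5))
})

test_that("total score folds the SAXS factor in sign-aware fashion", {
  sys <- toy_system()
  m <- assemble_starting_model(sys$graph, sys$sets, beam_width = 5)
  q <- seq(0.01, 0.3, length.out = 64)
  base <- compute_saxs_curve(m, q)
  sc0 <- total_score(m, pot, NULL, NULL)
  expect_equal(sc0$total, sc0$e_potential + 10 * sc0$e_restraint + 5 * sc0$e_clash)
  ## two experimental curves, both worse than chi2 = 1: larger chi2 must
  ## always give the larger (worse) total
  mk_exp <- function(fac) rnamason:::new_saxs_curve(q, base$I * fac, 0.02 * base$I)
  sc_a <- total_score(m, pot, NULL, mk_exp(1 + 0.4 * q))
  sc_b <- total_score(m, pot, NULL, mk_exp(1 + 1.2 * q))
  expect_true(sc_a$chi2 > 1 && sc_b$chi2 > sc_a$chi2)
  expect_lt(sc_a$total, sc_b$total)
})
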