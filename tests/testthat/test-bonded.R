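# Internal-coordinate measurement and Boltzmann-inversion fitting.

test_that("measure_internals handles the geometric base cases", {
  m <- parse_mapping("
[molecule] TRI 0
[atoms]
A1 C 14 8
A2 C 14 8
A3 C 14 8
[bead] B1 TC3 0.00 : A1
[bead] B2 TC3 0.00 : A2
[bead] B3 TC3 0.00 : A3
[bonds]
B1 B2
B2 B3
[angles]
B1 B2 B3
")
  # collinear beads -> angle mean 180, sd 0
  fr <- cg_frame(rbind(c(0, 0, 0), c(0, 0, 0.3), c(0, 0, 0.6)))
  su <- measure_internals(m, cg_ensemble(list(fr, fr)))
  ang <- su[[3]]
  expect_equal(ang$kind, "angle")
  expect_equal(ang$mean, 180)
  expect_equal(ang$sd, 0)
  expect_equal(su[[1]]$mean, 0.3)

  # zero-length bond -> degenerate
  bad <- cg_frame(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0.6)))
  expect_error(measure_internals(m, cg_ensemble(list(bad, bad))),
               "degenerate internal coordinate")
})

test_that("a planar 4-bead frame has improper 0", {
  m <- parse_mapping("
[molecule] PL 0
[atoms]
A1 C 14 8
A2 C 14 8
A3 C 14 8
A4 C 14 8
[bead] B1 TC3 0.00 : A1
[bead] B2 TC3 0.00 : A2
[bead] B3 TC3 0.00 : A3
[bead] B4 TC3 0.00 : A4
[bonds]
B1 B2
B2 B3
B3 B4
[impropers]
B1 B2 B3 B4
")
  fr <- cg_frame(rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.3, 0.3, 0),
                       c(0, 0.4, 0)))
  su <- measure_internals(m, cg_ensemble(list(fr, fr)))
  expect_equal(su[[4]]$kind, "improper")
  expect_equal(su[[4]]$mean, 0, tolerance = 1e-9)
})

test_that("fit_bond inverts moments and respects its preconditions", {
  # frozen example: mean 0.35 nm, sd 0.0222725 nm at 298 K
  d <- distribution_summary("bond", c(1, 2),
                            c(0.35 - 0.0222725, 0.35 + 0.0222725))
  d$mean <- 0.35; d$sd <- 0.0222725
  t <- fit_bond(d, T = 298)
  expect_equal(t$equilibrium, 0.35)
  expect_equal(t$force_constant, 0.0083145 * 298 / 0.0222725^2)
  expect_lt(abs(t$force_constant - 5000) / 5000, 0.005)

  # sd -> large => k -> 0
  d$sd <- 1000
  expect_lt(fit_bond(d, T = 298)$force_constant, 1e-4)

  d$sd <- 0
  expect_error(fit_bond(d), "classify_constraint")
})

test_that("bond and angle round-trips recover programmed parameters", {
  # (0.1% equilibrium, 5% force constant) at 1e5 samples, 3 seeds
  for (seed in 1:3) {
    d <- gen_internal_samples("bond", 0.35, 5000, 1e5, T = 298, seed = seed)
    t <- fit_bond(d, T = 298)
    expect_lt(abs(t$equilibrium - 0.35) / 0.35, 0.001)
    expect_lt(abs(t$force_constant - 5000) / 5000, 0.05)

    a <- gen_internal_samples("angle", 150, 100, 1e5, T = 298, seed = seed)
    ta <- fit_angle(a, T = 298)
    expect_lt(abs(ta$equilibrium - 150) / 150, 0.001)
    expect_lt(abs(ta$force_constant - 100) / 100, 0.05)

    im <- gen_internal_samples("improper", 0, 50, 1e5, T = 298, seed = seed)
    ti <- fit_improper(im, T = 298)
    expect_lt(abs(ti$equilibrium), 0.2)
    expect_lt(abs(ti$force_constant - 50) / 50, 0.05)
  }
})

test_that("degenerate angle distributions cap k and warn near linearity", {
  d <- distribution_summary("angle", c(1, 2, 3), rep(120, 10) + 0)
  expect_warning(t <- fit_angle(d), "capped")
  expect_equal(t$equilibrium, 120, tolerance = 1e-6)
  expect_equal(t$force_constant, 1000)
})

test_that("classify_constraint applies the width threshold", {
  d <- distribution_summary("bond", c(1, 2), rnorm(100, 0.25, 1))
  d$sd <- 0.001
  expect_equal(classify_constraint(d), "constraint")
  d$sd <- 0.02
  expect_equal(classify_constraint(d), "bond")
  d$sd <- 0.004
  expect_equal(classify_constraint(d, threshold_nm = 0.003), "bond")
})

test_that("bimodal distributions are flagged and fitted at the pooled mean", {
  set.seed(9)
  th <- c(rnorm(5000, 100, 1.5), rnorm(5000, 140, 1.5))
  d <- distribution_summary("angle", c(1, 2, 3), th)
  expect_true(d$bimodal)
  t <- suppressWarnings(fit_angle(d))
  pooled <- 180 / pi * acos(mean(cos(th * pi / 180)))
  expect_equal(t$equilibrium, pooled, tolerance = 1e-6)

  uni <- distribution_summary("angle", c(1, 2, 3), rnorm(5000, 120, 5))
  expect_false(uni$bimodal)
})

test_that("compare_distributions is a bounded symmetric overlap", {
  set.seed(3)
  a <- distribution_summary("bond", c(1, 2), rnorm(5e4, 0.35, 0.02))
  b <- distribution_summary("bond", c(1, 2), rnorm(5e4, 0.37, 0.02))
  ov <- compare_distributions(a, b)
  # two equal-sd Gaussians 1 sd apart: overlap = 2*pnorm(-1/2) = 0.617
  expect_equal(ov, 2 * pnorm(-0.5), tolerance = 0.02)
  expect_equal(ov, compare_distributions(b, a), tolerance = 1e-12)

  expect_equal(compare_distributions(a, a), 1, tolerance = 1e-9)

  c <- distribution_summary("bond", c(1, 2), rnorm(1000, 2.0, 0.01))
  expect_warning(ov0 <- compare_distributions(a, c), "disjoint")
  expect_equal(ov0, 0)
})

test_that("refine_term is a fixed point on match and a contraction otherwise", {
  term <- cgparam:::harmonic_term("bond", c(1, 2), 0.35, 5000, 1L)
  tgt <- gen_internal_samples("bond", 0.35, 5000, 2e4, seed = 5)
  same <- refine_term(term, tgt, tgt)
  expect_equal(same$force_constant, term$force_constant)
  expect_equal(same$equilibrium, term$equilibrium)

  # observed twice as wide -> k quadrupled
  obs <- tgt; obs$sd <- 2 * tgt$sd
  expect_equal(refine_term(term, tgt, obs)$force_constant / 5000, 4,
               tolerance = 1e-9)

  zero <- tgt; zero$sd <- 0
  expect_error(refine_term(term, zero, obs), "refinement undefined")
})

test_that("the refinement loop converges for a 50% mis-initialized bond", {
  set.seed(17)
  target <- gen_internal_samples("bond", 0.35, 5000, 2e4)
  term <- cgparam:::harmonic_term("bond", c(1, 2), 0.36, 2500, 1L)
  ov <- 0
  for (it in 1:5) {
    observed <- gen_internal_samples("bond", term$equilibrium,
                                     term$force_constant, 2e4)
    ov <- compare_distributions(target, observed)
    if (ov > 0.95) break
    term <- refine_term(term, target, observed)
  }
  expect_gt(ov, 0.95)
  expect_lte(it, 5)
})

test_that("distribution_report tabulates summaries with overlap", {
  a <- gen_internal_samples("bond", 0.35, 5000, 1000, seed = 1)
  b <- gen_internal_samples("angle", 120, 100, 1000, seed = 1)
  rep <- distribution_report(list(a, b), targets = list(a, b))
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$overlap > 0.99))
})
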