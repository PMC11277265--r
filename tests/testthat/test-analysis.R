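# Electron density profiles, superposition/RMSF, SASA.

test_that("density profile base cases: spike, flat slab, conservation", {
  box <- c(4, 4, 6)
  # all beads at one z -> single-bin spike
  fr <- cg_frame(cbind(runif(50, 0, 4), runif(50, 0, 4), rep(3, 50)),
                 box = box)
  prof <- electron_density_profile(cg_ensemble(list(fr, fr)), 1,
                                   list(all = 1:50), nbins = 60)
  expect_equal(sum(prof$raw[, 1] > 0), 1L)
  expect_equal(max(prof$normalized[, 1]), 1)

  # uniform slab, unweighted -> flat within noise
  set.seed(6)
  frames <- lapply(1:200, function(i)
    cg_frame(cbind(runif(200, 0, 4), runif(200, 0, 4), runif(200, 0, 6)),
             box = box))
  flat <- electron_density_profile(cg_ensemble(frames), 1,
                                   list(all = 1:200), nbins = 20)
  expect_lt(sd(flat$raw[, 1]) / mean(flat$raw[, 1]), 0.12)

  # area conservation: integral of the raw profile = selection electrons
  el <- rep(c(10, 20), 100)
  cons <- electron_density_profile(cg_ensemble(frames), el,
                                   list(all = 1:200), nbins = 25)
  expect_equal(sum(cons$raw[, 1]) * cons$bin_width, sum(el),
               tolerance = 1e-9)
})

test_that("density profile validates boxes and selections", {
  fr <- cg_frame(matrix(0.5, 10, 3))
  expect_error(electron_density_profile(cg_ensemble(list(fr, fr)), 1,
                                        list(a = 1:10)), "missing box")
  frb <- cg_frame(matrix(0.5, 10, 3), box = c(2, 2, 2))
  expect_error(electron_density_profile(cg_ensemble(list(frb)), 1,
                                        list(a = integer(0))),
               "empty selection")
})

test_that("a symmetric toy bilayer yields a symmetric profile", {
  bl <- gen_toy_bilayer(n_lipids = 64, n_cofactor = 8,
                        scenario = "midplane", n_frames = 150, seed = 21)
  prof <- electron_density_profile(bl$ensemble, bl$electrons,
                                   bl$selections, center = "lipid_tails",
                                   nbins = 60)
  h <- prof$raw[, "lipid_heads"]
  n <- length(h)
  left <- sum(h[1:(n / 2)])
  right <- sum(h[(n / 2 + 1):n])
  expect_lt(abs(left - right) / (left + right), 0.02)
})

test_that("kabsch superposition is exact on identical and rotated frames", {
  set.seed(8)
  X <- matrix(rnorm(60), ncol = 3)
  expect_equal(kabsch_superpose(X, X)$rmsd, 0, tolerance = 1e-10)

  R <- random_rotation()
  fit <- kabsch_superpose(X %*% R + 0.5, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)

  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(seq_len(5), 0, 0)
  expect_error(kabsch_superpose(line, line + rnorm(15)), "collinear")
})

test_that("kabsch RMSD is minimal and matches a brute-force search", {
  set.seed(12)
  for (rep in 1:3) {
    X <- matrix(rnorm(18), ncol = 3)          # 6-point system
    Y <- X %*% random_rotation() + matrix(rnorm(18, 0, 0.05), ncol = 3)
    k <- kabsch_superpose(Y, X)
    expect_lt(abs(k$rmsd - brute_force_rmsd(Y, X)), 1e-6)
  }
  # RMSD after fitting never exceeds the perturbation RMS
  X <- matrix(rnorm(60), ncol = 3)
  pert <- matrix(rnorm(60, 0, 0.1), ncol = 3)
  expect_lte(kabsch_superpose(X + pert, X)$rmsd,
             sqrt(mean(rowSums(pert^2))) * 10 + 1e-9)
})

test_that("rmsf recovers the closed form for isotropic jitter", {
  # 100 sites so the 6 rigid-body DOF absorbed by superposition are
  # negligible next to the 5% tolerance
  set.seed(13)
  base <- matrix(rnorm(300, 0, 1), ncol = 3)
  sigma <- 0.05   # nm = 0.5 A per coordinate
  frames <- lapply(1:800, function(i)
    cg_frame(base + matrix(rnorm(300, 0, sigma), ncol = 3)))
  rep <- rmsf(cg_ensemble(frames))
  expect_equal(mean(rep$rmsf), sqrt(3) * sigma * 10, tolerance = 0.05)
  expect_true(all(rep$rmsf >= 0))
})

test_that("rmsf is zero for static or rigidly wobbling ensembles", {
  base <- matrix(rnorm(45), ncol = 3)
  static <- cg_ensemble(lapply(1:5, function(i) cg_frame(base)))
  expect_equal(max(rmsf(static)$rmsf), 0, tolerance = 1e-10)

  set.seed(14)
  wobble <- cg_ensemble(lapply(1:20, function(i)
    cg_frame(base %*% random_rotation() +
             matrix(rep(rnorm(3), each = nrow(base)), ncol = 3))))
  expect_lt(max(rmsf(wobble)$rmsf), 1e-8)
})

test_that("rmsf is invariant under global rigid transforms of every frame", {
  set.seed(15)
  frames <- lapply(1:50, function(i)
    cg_frame(matrix(rnorm(30, 0, 1), ncol = 3) * 0.3 +
             matrix(rep(rnorm(3), each = 10), ncol = 3)))
  ens <- cg_ensemble(frames)
  r1 <- rmsf(ens)$rmsf
  R <- random_rotation()
  ens2 <- cg_ensemble(lapply(frames, function(f)
    cg_frame(f$coords %*% R + 2)))
  expect_equal(rmsf(ens2)$rmsf, r1, tolerance = 1e-6)
})

test_that("sasa matches the analytic sphere and merges overlapping beads", {
  s1 <- sasa(matrix(0, 1, 3), radii = 0.235, probe = 0.14, n_points = 960)
  expect_lt(abs(s1$total - 4 * pi * 0.375^2) / (4 * pi * 0.375^2), 0.01)

  s2 <- sasa(matrix(0, 2, 3), radii = 0.235, probe = 0.14, n_points = 960)
  expect_lt(abs(s2$total - s1$total) / s1$total, 0.02)

  expect_error(sasa(matrix(0, 1, 3), radii = NA_real_), "missing radius")
})

test_that("sasa decreases monotonically as two beads merge", {
  r <- 0.235; p <- 0.14
  seps <- seq(2 * (r + p), 0, length.out = 10)
  tot <- vapply(seps, function(d)
    sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = r, probe = p,
         n_points = 960)$total, numeric(1))
  expect_true(all(diff(tot) <= 1e-9))
})

test_that("CG SASA is below pseudo-atomistic SASA for every cofactor", {
  for (nm in cofactor_mappings()) {
    m <- cofactor_mapping(nm)
    co <- idealized_coordinates(m)
    cg <- sasa(co, cg_bead_radii(vapply(m$beads, `[[`, character(1),
                                        "martini_type")))
    aa_fr <- place_atoms(m, cg_frame(co))   # same conformer, atom detail
    aa <- sasa(aa_fr, aa_atom_radii(m$atoms$element))
    expect_lt(cg$total, aa$total)
  }
})
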