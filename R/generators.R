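# Seed-deterministic synthetic generators: Boltzmann samplers for single
# internal coordinates and whole bonded networks, pseudo-atomistic
# trajectories with exact projection closure, Crooks-consistent work
# samples, and toy bilayers.

#' Boltzmann samples of a single internal coordinate
#'
#' Direct sampling from the marginal each harmonic form implies, in the
#' coordinate where it is exactly Gaussian: bond lengths `r ~ N(b0,
#' sqrt(RT/k))`; angle cosines `cos(theta) ~ N(cos(theta0), sqrt(RT/k))`
#' (raw cosines are attached to the summary, so the fit round-trip is
#' exact); improper angles `xi ~ N(xi0, sqrt(RT/k))` in radians. This is
#' the conjugate-model oracle for the Boltzmann-inversion fits.
#'
#' @param kind "bond", "angle" or "improper".
#' @param equilibrium b0 (nm) or theta0/xi0 (degrees).
#' @param k force constant in the units of [fit_bond()]/[fit_angle()]/
#'   [fit_improper()].
#' @param n number of samples.
#' @param T temperature in kelvin.
#' @param seed optional RNG seed.
#' @param indices bead tuple stamped on the summary.
#' @return a `distribution_summary`.
#' @export
gen_internal_samples <- function(kind = c("bond", "angle", "improper"),
                                 equilibrium, k, n, T = 298, seed = NULL,
                                 indices = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(R_GAS * T / k)
  if (kind == "bond") {
    x <- stats::rnorm(n, equilibrium, s)
    distribution_summary("bond", indices %||% c(1L, 2L), x)
  } else if (kind == "angle") {
    cth <- stats::rnorm(n, cos(deg2rad(equilibrium)), s)
    th <- rad2deg(acos(pmin(1, pmax(-1, cth))))
    distribution_summary("angle", indices %||% c(1L, 2L, 3L), th,
                         cos_samples = cth)
  } else {
    xi <- equilibrium + rad2deg(stats::rnorm(n, 0, s))
    distribution_summary("improper", indices %||% c(1L, 2L, 3L, 4L), xi)
  }
}

# rowwise cross product for W x 3 matrices
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Bonded energy of the terms in `terms` (subset rows of targets), for all
# walkers. X: W x nb x 3 array. Returns numeric length W.
local_energy <- function(X, tg, bond_rows, angle_rows, improper_rows) {
  W <- dim(X)[1]
  E <- numeric(W)
  if (length(bond_rows)) {
    for (r in bond_rows) {
      i <- tg$bonds$i[r]; j <- tg$bonds$j[r]
      d <- sqrt(rowSums((X[, i, , drop = FALSE] - X[, j, , drop = FALSE])^2,
                        dims = 1))
      E <- E + 0.5 * tg$bonds$k[r] * (d - tg$bonds$b0[r])^2
    }
  }
  if (length(angle_rows)) {
    for (r in angle_rows) {
      a <- c(tg$angles$i[r], tg$angles$j[r], tg$angles$k_[r])
      v1 <- matrix(X[, a[1], ] - X[, a[2], ], ncol = 3)
      v2 <- matrix(X[, a[3], ] - X[, a[2], ], ncol = 3)
      cth <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      E <- E + 0.5 * tg$angles$k[r] * (cth - cos(deg2rad(tg$angles$theta0[r])))^2
    }
  }
  if (length(improper_rows)) {
    for (r in improper_rows) {
      im <- c(tg$impropers$i[r], tg$impropers$j[r], tg$impropers$k_[r],
              tg$impropers$l[r])
      b1 <- matrix(X[, im[2], ] - X[, im[1], ], ncol = 3)
      b2 <- matrix(X[, im[3], ] - X[, im[2], ], ncol = 3)
      b3 <- matrix(X[, im[4], ] - X[, im[3], ], ncol = 3)
      n1 <- cross_rows(b1, b2)
      n2 <- cross_rows(b2, b3)
      m1 <- cross_rows(n1, b2 / sqrt(rowSums(b2^2)))
      xi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
      dxi <- xi - deg2rad(tg$impropers$xi0[r])
      dxi <- atan2(sin(dxi), cos(dxi))
      E <- E + 0.5 * tg$impropers$k[r] * dxi^2
    }
  }
  E
}

#' Metropolis sampler over a bonded potential (bead resolution)
#'
#' Samples the Boltzmann distribution of the full bonded potential (bonds
#' harmonic in r, angles cosine-harmonic, impropers harmonic in xi) with a
#' sweep Metropolis scheme run over many independent walkers started at
#' the idealized geometry. Per-bead proposal scales are initialized from
#' the local stiffness and auto-tuned during burn-in toward 30-50%
#' acceptance; samples are collected every `stride` sweeps after burn-in,
#' a spacing chosen well past the sweep-level autocorrelation of the
#' stiffest-to-softest mode mix (see the package vignette).
#'
#' @param targets a [bonded_targets()] list (an unconnected graph is an
#'   error).
#' @param n_samples total samples (frames) to return.
#' @param T temperature in kelvin.
#' @param seed RNG seed.
#' @param n_walkers number of independent walkers.
#' @param burn burn-in sweeps.
#' @param stride sweeps between collected samples.
#' @return a `cg_ensemble` of bead frames.
#' @export
gen_harmonic_ensemble <- function(targets, n_samples = 5000, T = 298,
                                  seed = 1, n_walkers = 250, burn = 300,
                                  stride = 10) {
  set.seed(seed)
  tg <- targets
  nb <- nrow(tg$coords)
  if (is.null(tg$bonds) || nrow(tg$bonds) < nb - 1L)
    stop("unconnected graph: bonded network must span all beads")
  # connectivity check on the bond list
  adj <- vector("list", nb)
  for (r in seq_len(nrow(tg$bonds))) {
    i <- tg$bonds$i[r]; j <- tg$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(nb); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  if (!all(seen)) stop("unconnected graph: bead ", which(!seen)[1], " unreachable")

  beta <- 1 / (R_GAS * T)
  # per-bead term lists
  brows <- lapply(seq_len(nb), function(b)
    which(tg$bonds$i == b | tg$bonds$j == b))
  arows <- lapply(seq_len(nb), function(b)
    if (is.null(tg$angles)) integer(0)
    else which(tg$angles$i == b | tg$angles$j == b | tg$angles$k_ == b))
  irows <- lapply(seq_len(nb), function(b)
    if (is.null(tg$impropers)) integer(0)
    else which(tg$impropers$i == b | tg$impropers$j == b |
               tg$impropers$k_ == b | tg$impropers$l == b))

  keff <- vapply(seq_len(nb), function(b)
    sum(tg$bonds$k[brows[[b]]]) + 1e-9, numeric(1))
  scale <- pmin(0.12, pmax(0.0015, 0.4 * sqrt(R_GAS * T / keff)))

  W <- n_walkers
  X <- array(rep(as.vector(tg$coords), each = W), c(W, nb, 3))
  X <- X + array(stats::rnorm(W * nb * 3, 0, 0.002), c(W, nb, 3))

  acc_ct <- prop_ct <- numeric(nb)
  n_collect <- ceiling(n_samples / W)
  frames <- vector("list", n_collect * W)
  got <- 0L
  total_sweeps <- burn + n_collect * stride

  for (sw in seq_len(total_sweeps)) {
    for (b in seq_len(nb)) {
      e0 <- local_energy(X, tg, brows[[b]], arows[[b]], irows[[b]])
      Xp <- X
      Xp[, b, ] <- Xp[, b, ] + matrix(stats::rnorm(W * 3, 0, scale[b]), W, 3)
      e1 <- local_energy(Xp, tg, brows[[b]], arows[[b]], irows[[b]])
      accept <- stats::runif(W) < exp(pmin(0, -beta * (e1 - e0)))
      if (any(accept)) X[accept, b, ] <- Xp[accept, b, ]
      acc_ct[b] <- acc_ct[b] + sum(accept)
      prop_ct[b] <- prop_ct[b] + W
    }
    if (sw <= burn && sw %% 20L == 0L) {
      rate <- acc_ct / prop_ct
      scale <- pmin(0.2, pmax(5e-4,
        scale * ifelse(rate > 0.5, 1.15, ifelse(rate < 0.3, 0.85, 1))))
      acc_ct[] <- 0; prop_ct[] <- 0
    }
    if (sw > burn && (sw - burn) %% stride == 0L) {
      for (w in seq_len(W)) {
        got <- got + 1L
        frames[[got]] <- cg_frame(matrix(X[w, , ], ncol = 3))
      }
    }
  }
  cg_ensemble(frames[seq_len(min(got, n_samples))])
}

#' Place pseudo-atoms around a bead frame
#'
#' Atoms sit at rigid offsets around their host bead (offset radius set by
#' the bead size class) plus optional isotropic jitter; each bead's
#' uniquely-mapped atoms are then shifted so the bead's mass-weighted atom
#' center reproduces the bead position exactly. Doubly-mapped atoms sit at
#' the midpoint of their two hosts and carry no jitter. Projecting the
#' result through [project_frame()] therefore returns the input bead frame
#' to machine precision.
#'
#' @param mapping a `molecule_mapping`.
#' @param frame a `cg_frame` of bead coordinates (mapping bead order).
#' @param jitter per-coordinate atomic jitter sd (nm).
#' @return a `cg_frame` of atom coordinates (mapping atom order).
#' @export
place_atoms <- function(mapping, frame, jitter = 0) {
  na <- nrow(mapping$atoms)
  W <- bead_membership(mapping)
  hosts <- apply(W, 1, function(r) which(r > 0), simplify = FALSE)
  shared <- vapply(hosts, length, integer(1)) == 2L
  types <- vapply(mapping$beads, `[[`, character(1), "martini_type")
  off_scale <- c(T = 0.06, S = 0.09, R = 0.12)[bead_size_class(types)]

  offs <- matrix(0, na, 3)
  for (b in seq_along(mapping$beads)) {
    members <- which(W[, b] > 0)
    uniq <- members[!shared[members]]
    if (!length(uniq)) next
    dirs <- fibonacci_sphere(max(2L, length(uniq)))[seq_along(uniq), ,
                                                    drop = FALSE]
    offs[uniq, ] <- dirs * off_scale[b]
  }
  shared_dir <- fibonacci_sphere(max(2L, sum(shared)))
  masses <- mapping$atoms$mass

  B <- frame$coords
  A <- matrix(0, na, 3)
  si <- 0L
  for (a in which(shared)) {
    si <- si + 1L
    h <- hosts[[a]]
    A[a, ] <- (B[h[1], ] + B[h[2], ]) / 2 + shared_dir[si, ] * 0.02
  }
  for (b in seq_along(mapping$beads)) {
    members <- which(W[, b] > 0)
    uniq <- members[!shared[members]]
    if (!length(uniq)) next
    A[uniq, ] <- B[rep(b, length(uniq)), , drop = FALSE] +
      offs[uniq, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(uniq), 0, jitter), ncol = 3)
    D <- colSums(matrix(masses[members], length(members), 3) *
                 (A[members, , drop = FALSE] -
                  matrix(B[b, ], length(members), 3, byrow = TRUE)))
    A[uniq, ] <- A[uniq, , drop = FALSE] -
      matrix(D / sum(masses[uniq]), length(uniq), 3, byrow = TRUE)
  }
  rownames(A) <- mapping$atoms$name
  cg_frame(A, box = frame$box)
}

#' Pseudo-atomistic trajectory with exact projection closure
#'
#' Emulates a mapped atomistic reference trajectory statistically: bead
#' centers follow the Metropolis sampler over the programmed bonded
#' statistics; atoms are placed around each sampled bead frame with
#' [place_atoms()], whose mass-center correction guarantees the projection
#' closure (project -> measure recovers the bead statistics exactly).
#'
#' @param mapping a `molecule_mapping`.
#' @param n_samples frames to generate.
#' @param T temperature (K).
#' @param seed RNG seed.
#' @param jitter per-coordinate atomic jitter sd (nm).
#' @param targets optional [bonded_targets()] override.
#' @param ... passed to [gen_harmonic_ensemble()].
#' @return list with `atoms` (atomistic `cg_ensemble`), `beads` (the
#'   underlying bead ensemble) and `targets`.
#' @export
gen_pseudo_aa_trajectory <- function(mapping, n_samples = 2000, T = 298,
                                     seed = 1, jitter = 0.005,
                                     targets = NULL, ...) {
  tg <- targets %||% bonded_targets(mapping, T = T)
  beads <- gen_harmonic_ensemble(tg, n_samples = n_samples, T = T,
                                 seed = seed, ...)
  frames <- lapply(beads, place_atoms, mapping = mapping, jitter = jitter)
  list(atoms = cg_ensemble(frames), beads = beads, targets = tg)
}

#' Crooks-consistent Gaussian work samples
#'
#' Generates forward and reverse energy-difference samples (both in the
#' `U_next - U_this` convention) that satisfy the Crooks fluctuation
#' relation exactly: forward `~ N(dF + beta*sigma^2/2, sigma^2)` and
#' reverse `~ N(dF - beta*sigma^2/2, sigma^2)`. BAR's estimand on these
#' samples equals `dF` by construction, making this the exact-estimand
#' oracle for [bar_pair()].
#'
#' @param deltaF programmed free-energy difference, kJ mol^-1.
#' @param sigma work-distribution width, kJ mol^-1 (> 0).
#' @param n samples per side.
#' @param T temperature in kelvin.
#' @param seed RNG seed.
#' @return list with `forward`, `reverse`, `deltaF`, `temperature`.
#' @export
gen_crooks_work <- function(deltaF, sigma, n, T = 300, seed = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  beta <- 1 / (R_GAS * T)
  list(forward = stats::rnorm(n, deltaF + beta * sigma^2 / 2, sigma),
       reverse = stats::rnorm(n, deltaF - beta * sigma^2 / 2, sigma),
       deltaF = deltaF, temperature = T)
}

#' Crooks-consistent multi-window series
#'
#' Chains [gen_crooks_work()] over adjacent window pairs so the programmed
#' total equals `sum(deltaFs)`.
#'
#' @param deltaFs per-pair free-energy differences (length nw-1).
#' @param sigma work width per pair (recycled).
#' @param n samples per side per pair.
#' @param T temperature (K).
#' @param seed RNG seed.
#' @return a `lambda_series`.
#' @export
gen_crooks_series <- function(deltaFs, sigma = 2, n = 1000, T = 300,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- rep_len(sigma, length(deltaFs))
  fw <- rv <- vector("list", length(deltaFs))
  for (i in seq_along(deltaFs)) {
    g <- gen_crooks_work(deltaFs[i], sigma[i], n, T)
    fw[[i]] <- g$forward
    rv[[i]] <- g$reverse
  }
  lambda_series(seq(0, 1, length.out = length(deltaFs) + 1L), fw, rv, T)
}

#' Toy bilayer ensemble for density-profile tests
#'
#' Gaussian leaflets of lipid head beads about +-`z_offset`, tail beads
#' about the midplane, and cofactor beads placed per scenario:
#' "head_anchored" co-localizes the cofactor heads with the lipid head
#' peaks, "midplane" concentrates them at the bilayer center. x/y are
#' uniform in the box; z is stored wrapped into the box.
#'
#' @param n_lipids lipid head beads per leaflet.
#' @param n_cofactor cofactor beads.
#' @param scenario "head_anchored" or "midplane".
#' @param n_frames number of frames.
#' @param box box edges (nm).
#' @param z_offset leaflet head offset from midplane (nm).
#' @param head_width,tail_width Gaussian widths (nm).
#' @param seed RNG seed.
#' @return list with `ensemble`, `selections` (lipid_heads, lipid_tails,
#'   cofactor), and `electrons` per site.
#' @export
gen_toy_bilayer <- function(n_lipids = 64, n_cofactor = 8,
                            scenario = c("head_anchored", "midplane"),
                            n_frames = 100, box = c(6.4, 6.4, 8),
                            z_offset = 1.8, head_width = 0.25,
                            tail_width = 0.55, seed = 1) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  n_heads <- 2L * n_lipids
  n_tails <- 2L * n_lipids
  ns <- n_heads + n_tails + n_cofactor
  sel <- list(lipid_heads = seq_len(n_heads),
              lipid_tails = n_heads + seq_len(n_tails),
              cofactor = n_heads + n_tails + seq_len(n_cofactor))
  zmid <- box[3] / 2
  frames <- vector("list", n_frames)
  leaflet <- rep(c(-1, 1), each = n_lipids)
  cof_leaflet <- rep_len(c(-1, 1), n_cofactor)
  for (f in seq_len(n_frames)) {
    zh <- zmid + leaflet * z_offset + stats::rnorm(n_heads, 0, head_width)
    zt <- zmid + stats::rnorm(n_tails, 0, tail_width)
    zc <- if (scenario == "midplane")
      zmid + stats::rnorm(n_cofactor, 0, 0.3)
    else
      zmid + cof_leaflet * z_offset + stats::rnorm(n_cofactor, 0, head_width)
    z <- c(zh, zt, zc) %% box[3]
    xy <- matrix(stats::runif(2 * ns, 0, box[1]), ncol = 2)
    frames[[f]] <- cg_frame(cbind(xy, z), box = box)
  }
  list(ensemble = cg_ensemble(frames), selections = sel,
       electrons = c(rep(40, n_heads), rep(20, n_tails), rep(30, n_cofactor)))
}
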