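# Internal-coordinate distributions and Boltzmann-inversion fitting of
# Martini-style harmonic bonded parameters.
#
# Conventions (GROMACS dialect):
#   bonds      funct 1, U = k/2 (r - b0)^2,          k in kJ mol^-1 nm^-2
#   constraints funct 1, fixed length b0 (no k)
#   angles     funct 2 (cosine-harmonic),
#              U = k/2 (cos th - cos th0)^2,         k in kJ mol^-1
#   impropers  funct 2, U = k/2 (xi - xi0)^2,        k in kJ mol^-1 rad^-2
#
# Moments are taken on raw samples with no Jacobian (r^2 or sin th)
# correction; for angles the inversion works in cosine space, where the
# cosine-harmonic potential is exactly Gaussian.

default_k_max <- function(kind) {
  switch(kind, bond = 25000, angle = 1000, improper = 500, 25000)
}

#' Summarize samples of one internal coordinate
#'
#' Builds a `distribution_summary`: sample moments, a Freedman-Diaconis
#' histogram (binning affects reporting and overlap scores only; fits use
#' the raw samples), and a bimodality flag from a dip test on the histogram
#' (two local maxima separated by a >= 20% dip).
#'
#' @param kind "bond", "angle" or "improper".
#' @param indices integer bead tuple the coordinate belongs to.
#' @param samples numeric samples: nm for bonds, degrees for angles and
#'   impropers.
#' @param cos_samples optional raw cosine samples for angles (used in
#'   preference to `cos(samples)` by [fit_angle()]).
#' @param breaks histogram bin specification passed to [graphics::hist()];
#'   default Freedman-Diaconis.
#' @return a `distribution_summary`.
#' @export
distribution_summary <- function(kind = c("bond", "angle", "improper"),
                                 indices, samples, cos_samples = NULL,
                                 breaks = "FD") {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("need at least 2 samples")
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  dens <- h$density
  m <- if (kind == "improper") circular_mean_deg(samples) else mean(samples)
  s <- stats::sd(samples)
  structure(list(
    kind = kind,
    indices = as.integer(indices),
    samples_n = length(samples),
    mean = m,
    sd = s,
    histogram = list(edges = h$breaks, density = dens),
    bimodal = detect_bimodal(dens),
    samples = samples,
    cos_samples = cos_samples), class = "distribution_summary")
}

# dip test on histogram densities: two local maxima with a >=20% dip between
detect_bimodal <- function(dens, dip = 0.2) {
  n <- length(dens)
  if (n < 5) return(FALSE)
  # light smoothing so single-bin noise does not count as a peak
  sm <- stats::filter(dens, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- dens[is.na(sm)]
  sm <- as.numeric(sm)
  peaks <- which(diff(sign(diff(sm))) == -2) + 1L
  if (length(peaks) < 2) return(FALSE)
  peaks <- peaks[order(sm[peaks], decreasing = TRUE)][1:2]
  p1 <- min(peaks); p2 <- max(peaks)
  valley <- min(sm[p1:p2])
  lower_peak <- min(sm[p1], sm[p2])
  lower_peak > 0 && valley <= (1 - dip) * lower_peak
}

#' @export
print.distribution_summary <- function(x, ...) {
  unit <- if (x$kind == "bond") "nm" else "deg"
  cat(sprintf("<distribution_summary %s (%s): n=%d, mean=%.4f %s, sd=%.4f %s%s>\n",
              x$kind, paste(x$indices, collapse = "-"), x$samples_n,
              x$mean, unit, x$sd, unit,
              if (isTRUE(x$bimodal)) ", bimodal" else ""))
  invisible(x)
}

#' @export
plot.distribution_summary <- function(x, ...) {
  unit <- if (x$kind == "bond") "nm" else "degrees"
  mids <- (utils::head(x$histogram$edges, -1) + utils::tail(x$histogram$edges, -1)) / 2
  graphics::plot(mids, x$histogram$density, type = "h",
                 xlab = unit, ylab = "density",
                 main = sprintf("%s %s", x$kind, paste(x$indices, collapse = "-")), ...)
  invisible(x)
}

#' Measure internal-coordinate distributions of a mapped ensemble
#'
#' For every bond, angle and improper in the mapping, collects the samples
#' over a bead-resolution ensemble. Angles are computed via the arccosine
#' of normalized dot products at the middle bead; impropers as the signed
#' angle between the (i,j,k) and (j,k,l) planes, in degrees.
#'
#' @param mapping a `molecule_mapping`.
#' @param ensemble a `cg_ensemble` of bead frames (bead count must match).
#' @return a list of `distribution_summary`, bonds first, then angles,
#'   then impropers.
#' @export
measure_internals <- function(mapping, ensemble) {
  arr <- ensemble_array(ensemble)
  if (dim(arr)[2] != length(mapping$beads))
    stop(sprintf("ensemble has %d sites but mapping has %d beads",
                 dim(arr)[2], length(mapping$beads)))
  out <- list()
  for (b in mapping$bonds) {
    d <- sqrt(rowSums((arr[, b[1], , drop = FALSE] - arr[, b[2], , drop = FALSE])^2))
    if (any(d < 1e-9)) stop("degenerate internal coordinate: zero-length bond ",
                            paste(b, collapse = "-"))
    out[[length(out) + 1L]] <- distribution_summary("bond", b, d)
  }
  for (a in mapping$angles) {
    v1 <- arr[, a[1], ] - arr[, a[2], ]
    v2 <- arr[, a[3], ] - arr[, a[2], ]
    if (length(dim(v1)) < 2) { v1 <- matrix(v1, ncol = 3); v2 <- matrix(v2, ncol = 3) }
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    if (any(n1 < 1e-9) || any(n2 < 1e-9))
      stop("degenerate internal coordinate: zero-length angle arm ",
           paste(a, collapse = "-"))
    cosang <- pmin(1, pmax(-1, rowSums(v1 * v2) / (n1 * n2)))
    out[[length(out) + 1L]] <-
      distribution_summary("angle", a, rad2deg(acos(cosang)), cos_samples = cosang)
  }
  for (im in mapping$impropers) {
    nfr <- dim(arr)[1]
    xi <- vapply(seq_len(nfr), function(f)
      dihedral_deg(arr[f, im[1], ], arr[f, im[2], ], arr[f, im[3], ], arr[f, im[4], ]),
      numeric(1))
    out[[length(out) + 1L]] <- distribution_summary("improper", im, xi)
  }
  out
}

harmonic_term <- function(kind, indices, equilibrium, force_constant, funct) {
  structure(list(kind = kind, indices = as.integer(indices),
                 equilibrium = equilibrium, force_constant = force_constant,
                 funct = as.integer(funct)), class = "harmonic_term")
}

#' @export
print.harmonic_term <- function(x, ...) {
  cat(sprintf("<%s %s: eq=%.4f%s, funct=%d>\n", x$kind,
              paste(x$indices, collapse = "-"), x$equilibrium,
              if (is.na(x$force_constant)) "" else sprintf(", k=%.1f", x$force_constant),
              x$funct))
  invisible(x)
}

#' Boltzmann-invert a bond distribution
#'
#' Single-pass inversion: `b0 = mean`, `k = R*T / sd^2`. The force constant
#' is capped at `k_max` (with a warning) so stiff distributions never emit
#' unstable parameters; for genuinely sharp distributions use
#' [classify_constraint()] first.
#'
#' @param d a `distribution_summary` of kind "bond".
#' @param T temperature in kelvin.
#' @param k_max force-constant cap, kJ mol^-1 nm^-2.
#' @return a `harmonic_term` (funct 1).
#' @export
fit_bond <- function(d, T = 298, k_max = default_k_max("bond")) {
  stopifnot(inherits(d, "distribution_summary"), d$kind == "bond")
  if (d$sd <= 0)
    stop("zero-width bond distribution; use classify_constraint and emit a constraint")
  k <- R_GAS * T / d$sd^2
  if (k > k_max) {
    warning(sprintf("bond %s force constant %.0f capped at k_max = %.0f",
                    paste(d$indices, collapse = "-"), k, k_max))
    k <- k_max
  }
  harmonic_term("bond", d$indices, d$mean, k, 1L)
}

#' Boltzmann-invert an angle distribution (cosine-harmonic)
#'
#' Works in cosine space, where the cosine-harmonic (GROMACS funct 2)
#' potential is exactly Gaussian: `theta0 = acos(mean(cos theta))`,
#' `k = R*T / var(cos theta)`. Raw cosine samples attached to the summary
#' are used when present (they may exceed \[-1,1\] for synthetic
#' conjugate-model samples); otherwise cosines of the angle samples.
#'
#' @param d a `distribution_summary` of kind "angle".
#' @param T temperature in kelvin.
#' @param k_max force-constant cap, kJ mol^-1.
#' @return a `harmonic_term` (funct 2, equilibrium in degrees).
#' @export
fit_angle <- function(d, T = 298, k_max = default_k_max("angle")) {
  stopifnot(inherits(d, "distribution_summary"), d$kind == "angle")
  cth <- d$cos_samples %||% cos(deg2rad(d$samples))
  v <- stats::var(cth)
  th0 <- rad2deg(acos(pmin(1, pmax(-1, mean(cth)))))
  k <- if (v <= 0) Inf else R_GAS * T / v
  if (k > k_max) {
    warning(sprintf("angle %s force constant capped at k_max = %.0f",
                    paste(d$indices, collapse = "-"), k_max))
    k <- k_max
  }
  if (abs(th0 - 180) < 1e-6 && d$sd > 0)
    warning("near-linear angle, consider restricted-bending form")
  harmonic_term("angle", d$indices, th0, k, 2L)
}

#' Boltzmann-invert an improper-dihedral distribution
#'
#' Harmonic in the plane angle xi: `xi0` is the circular mean (degrees),
#' `k = R*T / var(xi)` with the variance taken in radians (kJ mol^-1
#' rad^-2). Used to keep ring systems planar.
#'
#' @param d a `distribution_summary` of kind "improper".
#' @param T temperature in kelvin.
#' @param k_max force-constant cap, kJ mol^-1 rad^-2.
#' @return a `harmonic_term` (funct 2, equilibrium in degrees).
#' @export
fit_improper <- function(d, T = 298, k_max = default_k_max("improper")) {
  stopifnot(inherits(d, "distribution_summary"), d$kind == "improper")
  xi0 <- circular_mean_deg(d$samples)
  dev <- deg2rad(d$samples - xi0)
  dev <- atan2(sin(dev), cos(dev))     # wrap into (-pi, pi]
  v <- stats::var(dev)
  k <- if (v <= 0) Inf else R_GAS * T / v
  if (k > k_max) {
    warning(sprintf("improper %s force constant capped at k_max = %.0f",
                    paste(d$indices, collapse = "-"), k_max))
    k <- k_max
  }
  harmonic_term("improper", d$indices, xi0, k, 2L)
}

#' Decide between a bond and a constraint
#'
#' Very sharp bond distributions cannot be matched by a stable harmonic
#' bond; they are emitted as constraints of fixed length instead. The
#' default width threshold is 0.005 nm.
#'
#' @param d a `distribution_summary` of kind "bond".
#' @param threshold_nm classify as constraint when `sd < threshold_nm`.
#' @return "constraint" or "bond".
#' @export
classify_constraint <- function(d, threshold_nm = 0.005) {
  stopifnot(inherits(d, "distribution_summary"), d$kind == "bond")
  if (d$sd < threshold_nm) "constraint" else "bond"
}

#' Overlap coefficient between two distributions
#'
#' Rebins the raw samples of both summaries onto common equal-width bins and
#' returns `sum(min(p_i, q_i)) * dx`, which is 1 for identical histograms
#' and 0 for disjoint supports (with a warning).
#'
#' @param target,trial `distribution_summary` objects of the same kind.
#' @param nbins number of common bins.
#' @return overlap in \[0, 1\].
#' @export
compare_distributions <- function(target, trial, nbins = 100) {
  stopifnot(inherits(target, "distribution_summary"),
            inherits(trial, "distribution_summary"))
  if (target$kind != trial$kind)
    stop("cannot compare distributions of different kinds")
  rng <- range(target$samples, trial$samples)
  if (diff(rng) <= 0) return(1)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  dx <- diff(edges)[1]
  p <- graphics::hist(target$samples, breaks = edges, plot = FALSE)$density
  q <- graphics::hist(trial$samples, breaks = edges, plot = FALSE)$density
  ov <- sum(pmin(p, q)) * dx
  if (ov == 0) warning("distributions have disjoint supports")
  min(1, ov)
}

#' Refine a harmonic term against a target distribution
#'
#' One step of the distribution-matching loop: given the distribution
#' `observed` produced by simulating with `term`, the force constant is
#' scaled by `(sd_observed / sd_target)^2` and the equilibrium shifted by
#' the mean mismatch. The update is a contraction on the width mismatch
#' and leaves a matched term unchanged.
#'
#' @param term the `harmonic_term` that generated `observed`.
#' @param target the reference (mapped-atomistic) `distribution_summary`.
#' @param observed the `distribution_summary` simulated with `term`.
#' @param k_max force-constant cap.
#' @return an updated `harmonic_term`.
#' @export
refine_term <- function(term, target, observed, k_max = default_k_max(term$kind)) {
  stopifnot(inherits(term, "harmonic_term"))
  if (target$sd <= 0) stop("refinement undefined, use constraint")
  knew <- term$force_constant * (observed$sd / target$sd)^2
  knew <- min(max(knew, 0), k_max)
  harmonic_term(term$kind, term$indices,
                term$equilibrium + (target$mean - observed$mean),
                knew, term$funct)
}

#' Fit all bonded terms of a mapping from measured distributions
#'
#' Applies constraint classification to bonds, then Boltzmann inversion to
#' every term (`fit_bond`, `fit_angle`, `fit_improper`).
#'
#' @param summaries list of `distribution_summary` from [measure_internals()].
#' @param T temperature in kelvin.
#' @param constraint_threshold width threshold (nm) for
#'   [classify_constraint()].
#' @return list with elements `bonds`, `constraints`, `angles`, `impropers`,
#'   each a list of `harmonic_term`.
#' @export
fit_terms <- function(summaries, T = 298, constraint_threshold = 0.005) {
  out <- list(bonds = list(), constraints = list(), angles = list(),
              impropers = list())
  for (d in summaries) {
    if (d$kind == "bond") {
      if (classify_constraint(d, constraint_threshold) == "constraint") {
        out$constraints[[length(out$constraints) + 1L]] <-
          harmonic_term("constraint", d$indices, d$mean, NA_real_, 1L)
      } else {
        out$bonds[[length(out$bonds) + 1L]] <- fit_bond(d, T)
      }
    } else if (d$kind == "angle") {
      out$angles[[length(out$angles) + 1L]] <- fit_angle(d, T)
    } else {
      out$impropers[[length(out$impropers) + 1L]] <- fit_improper(d, T)
    }
  }
  out
}

#' Tabulate distribution summaries
#'
#' Compact report (one row per internal coordinate) suitable for writing as
#' a tab-separated table.
#'
#' @param summaries list of `distribution_summary`.
#' @param targets optional parallel list of reference summaries; when given
#'   an `overlap` column is added via [compare_distributions()].
#' @return a data.frame.
#' @export
distribution_report <- function(summaries, targets = NULL) {
  df <- data.frame(
    kind = vapply(summaries, `[[`, character(1), "kind"),
    indices = vapply(summaries, function(d) paste(d$indices, collapse = "-"),
                     character(1)),
    n = vapply(summaries, `[[`, numeric(1), "samples_n"),
    mean = vapply(summaries, `[[`, numeric(1), "mean"),
    sd = vapply(summaries, `[[`, numeric(1), "sd"),
    bimodal = vapply(summaries, function(d) isTRUE(d$bimodal), logical(1)),
    stringsAsFactors = FALSE)
  if (!is.null(targets))
    df$overlap <- mapply(function(t, s) compare_distributions(t, s),
                         targets, summaries)
  df
}
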