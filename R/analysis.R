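# Validation analyses: electron density profiles along the bilayer normal,
# optimal superposition (Kabsch) with RMSD/RMSF, and Shrake-Rupley solvent
# accessible surface area.

#' Electron density profile along the bilayer normal
#'
#' Histograms bead z positions weighted by per-bead electron counts,
#' averaged over frames. Each frame is re-centered on the bilayer midplane
#' (the mean wrapped z of the `center` selection) before binning, so the
#' profile is reported against distance from the midplane. Bead z values
#' are wrapped into the box; molecules are not made whole (bead-resolution
#' analysis does not need it). The default normalization scales every
#' selection's curve to unit maximum; the raw electron/nm profile is kept
#' alongside.
#'
#' @param ensemble a `cg_ensemble`; every frame must carry a box.
#' @param electrons numeric vector of electrons per site (e.g. from
#'   [electrons_per_bead()]), recycled to the site count.
#' @param selections named list of site-index vectors to profile.
#' @param center name (or index vector) of the selection defining the
#'   membrane midplane; defaults to the first selection.
#' @param nbins number of uniform bins across the box height.
#' @param symmetrize reflect-average the two leaflets (off by default; the
#'   asymmetric two-head profiles are physically meaningful).
#' @return a `density_profile` with `z` (bin centers, nm from midplane),
#'   `raw` (electrons/nm) and `normalized` matrices (bins x selections).
#' @export
electron_density_profile <- function(ensemble, electrons, selections,
                                     center = NULL, nbins = 100,
                                     symmetrize = FALSE) {
  if (!length(selections)) stop("empty selection")
  if (is.null(names(selections)) || any(!nzchar(names(selections))))
    stop("selections must be named")
  if (any(vapply(selections, length, integer(1)) == 0L))
    stop("empty selection")
  boxes <- lapply(ensemble, `[[`, "box")
  if (any(vapply(boxes, is.null, logical(1))))
    stop("missing box: every frame needs box dimensions for a z profile")
  ns <- nrow(ensemble[[1]]$coords)
  electrons <- rep_len(electrons, ns)
  if (is.null(center)) center <- names(selections)[1]
  csel <- if (is.character(center)) selections[[center]] else as.integer(center)
  if (is.null(csel) || !length(csel)) stop("empty selection for centering")

  Lz <- boxes[[1]][3]
  edges <- seq(-Lz / 2, Lz / 2, length.out = nbins + 1)
  dz <- diff(edges)[1]
  acc <- matrix(0, nbins, length(selections),
                dimnames = list(NULL, names(selections)))
  for (f in seq_along(ensemble)) {
    z <- ensemble[[f]]$coords[, 3] %% ensemble[[f]]$box[3]
    mid <- mean(z[csel])
    rel <- (z - mid + Lz / 2) %% Lz - Lz / 2
    for (s in seq_along(selections)) {
      idx <- selections[[s]]
      b <- findInterval(rel[idx], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
      acc[, s] <- acc[, s] + as.numeric(
        tapply(electrons[idx], factor(b, levels = seq_len(nbins)), sum,
               default = 0))
    }
  }
  raw <- acc / (length(ensemble) * dz)     # electrons per nm, frame-averaged
  if (symmetrize) raw <- (raw + raw[rev(seq_len(nbins)), , drop = FALSE]) / 2
  normalized <- sweep(raw, 2, apply(raw, 2, max), "/")
  structure(list(z = (utils::head(edges, -1) + utils::tail(edges, -1)) / 2,
                 raw = raw, normalized = normalized, bin_width = dz,
                 n_frames = length(ensemble)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile: %d bins x %d selections, %d frames, dz = %.3f nm>\n",
              length(x$z), ncol(x$raw), x$n_frames, x$bin_width))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, normalized = TRUE, ...) {
  m <- if (normalized) x$normalized else x$raw
  graphics::matplot(x$z, m, type = "l", lty = 1,
                    xlab = "z from midplane (nm)",
                    ylab = if (normalized) "normalized electron density"
                           else "electron density (e/nm)", ...)
  graphics::legend("topright", colnames(m), col = seq_len(ncol(m)), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body superposition of `mobile` onto `reference` over
#' the given selection, via SVD of the covariance with the usual reflection
#' guard. RMSD is minimal over all rigid transforms.
#'
#' @param mobile,reference `cg_frame`s (or coordinate matrices) with equal
#'   site counts.
#' @param selection site indices used for the fit (default: all).
#' @return list with `rotation` (3x3), `translation` (applied as
#'   `coords %*% R + t`), and `rmsd` in Angstrom over the selection.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  X <- if (inherits(mobile, "cg_frame")) mobile$coords else as.matrix(mobile)
  Y <- if (inherits(reference, "cg_frame")) reference$coords else as.matrix(reference)
  if (nrow(X) != nrow(Y)) stop("site count mismatch")
  sel <- selection %||% seq_len(nrow(X))
  if (length(sel) < 3) stop("need at least 3 sites for superposition")
  xs <- X[sel, , drop = FALSE]; ys <- Y[sel, , drop = FALSE]
  cx <- colMeans(xs); cy <- colMeans(ys)
  xc <- sweep(xs, 2, cx); yc <- sweep(ys, 2, cy)
  sv <- svd(crossprod(xc, yc))
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2)
    stop("degenerate (collinear) selection")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cy - as.numeric(cx %*% R)
  fit <- sweep(xc %*% R, 2, cy, "+")
  rmsd_nm <- sqrt(mean(rowSums((fit - ys)^2)))
  list(rotation = R, translation = t, rmsd = rmsd_nm * 10)
}

apply_superposition <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, fit$translation, "+")
}

#' Per-site RMSF and per-frame RMSD of an ensemble
#'
#' Each frame is optimally superposed (via the alignment selection) onto
#' the ensemble's time-average structure; the average is itself refined by
#' one realignment pass. RMSF_i = sqrt(<|r_i - <r_i>|^2>) in Angstrom; the
#' per-frame RMSD (Angstrom, over the report selection) is measured against
#' the average structure.
#'
#' @param ensemble a `cg_ensemble` with at least 2 frames.
#' @param align site indices used for superposition (default: all).
#' @param report site indices to report (default: all).
#' @return a `mobility_report` with `rmsf` (per report site, Angstrom) and
#'   `rmsd` (per frame, Angstrom).
#' @export
rmsf <- function(ensemble, align = NULL, report = NULL) {
  if (length(ensemble) < 2) stop("need at least 2 frames")
  arr <- ensemble_array(ensemble)
  ns <- dim(arr)[2]
  align <- align %||% seq_len(ns)
  report <- report %||% seq_len(ns)

  ref <- arr[1, , ]
  for (pass in 1:2) {
    aligned <- array(0, dim(arr))
    for (f in seq_len(dim(arr)[1])) {
      fit <- kabsch_superpose(arr[f, , ], ref, selection = align)
      aligned[f, , ] <- apply_superposition(arr[f, , ], fit)
    }
    ref <- apply(aligned, c(2, 3), mean)
  }
  mean_str <- ref
  dev2 <- sweep(aligned, c(2, 3), mean_str)^2
  # per-site: mean over frames of squared deviation summed over xyz
  rmsf_nm <- sqrt(apply(apply(dev2, c(1, 2), sum), 2, mean))
  rmsd_nm <- sqrt(apply(apply(dev2[, report, , drop = FALSE], c(1, 2), sum),
                        1, mean))
  structure(list(rmsf = rmsf_nm[report] * 10, rmsd = rmsd_nm * 10,
                 align = align, report = report, mean_structure = mean_str),
            class = "mobility_report")
}

#' @export
print.mobility_report <- function(x, ...) {
  cat(sprintf("<mobility_report: %d sites, mean RMSF %.2f A; %d frames, mean RMSD %.2f A>\n",
              length(x$rmsf), mean(x$rmsf), length(x$rmsd), mean(x$rmsd)))
  invisible(x)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Quasi-uniform test points on a Fibonacci (golden-spiral) lattice are
#' placed on each site's solvent-accessible sphere (radius `r_i + probe`);
#' the accessible fraction times the sphere area gives the per-site SASA.
#'
#' @param frame a `cg_frame` (or coordinate matrix), nm.
#' @param radii per-site radii in nm (see [cg_bead_radii()] /
#'   [aa_atom_radii()]), recycled.
#' @param probe probe radius, nm (default 0.14, a water-sized probe).
#' @param n_points lattice points per sphere (default 960).
#' @return list with `total` (nm^2) and `per_site` (nm^2).
#' @export
sasa <- function(frame, radii, probe = 0.14, n_points = 960) {
  X <- if (inherits(frame, "cg_frame")) frame$coords else as.matrix(frame)
  n <- nrow(X)
  radii <- rep_len(radii, n)
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("missing radius: every site needs a positive radius")
  pts <- fibonacci_sphere(n_points)
  rs <- radii + probe
  per <- numeric(n)
  for (i in seq_len(n)) {
    # neighbors whose accessible spheres can intersect site i's
    d2 <- rowSums(sweep(X, 2, X[i, ])^2)
    nb <- which(d2 < (rs[i] + rs)^2 & seq_len(n) != i)
    surf <- sweep(pts * rs[i], 2, X[i, ], "+")
    acc <- rep(TRUE, n_points)
    tol <- 1e-9
    for (j in nb) {
      dj2 <- rowSums(sweep(surf, 2, X[j, ])^2)
      # points exactly on a neighbor's accessible sphere (fully overlapping
      # sites) are owned by the lower index, so coincident beads contribute
      # one sphere's area, not two
      buried <- dj2 < rs[j]^2 - tol |
        (abs(dj2 - rs[j]^2) <= tol & j < i)
      acc <- acc & !buried
      if (!any(acc)) break
    }
    per[i] <- mean(acc) * 4 * pi * rs[i]^2
  }
  list(total = sum(per), per_site = per)
}
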