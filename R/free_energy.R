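# Bennett acceptance ratio free energies over lambda windows, transfer free
# energies and the water/octanol partition coefficient.
#
# Sample convention: for an adjacent window pair (i, i+1) both sample sets
# are the same energy difference dU = U_{i+1} - U_i, the "forward" set
# evaluated on configurations of ensemble i and the "reverse" set on
# configurations of ensemble i+1. bar_pair() then estimates
# dF = F_{i+1} - F_i.

#' Construct a free-energy result
#'
#' Container for a free-energy difference with uncertainty; produced by
#' [bar_pair()]/[bar_chain()] and consumed by [transfer_free_energy()] and
#' [log_p()].
#'
#' @param deltaG free-energy difference, kJ mol^-1.
#' @param stderr standard error, kJ mol^-1 (>= 0).
#' @param temperature kelvin.
#' @param windows optional per-window contribution table.
#' @return a `free_energy_result`.
#' @export
free_energy_result <- function(deltaG, stderr, temperature, windows = NULL) {
  if (!is.na(stderr) && stderr < 0) stop("stderr must be >= 0")
  structure(list(deltaG = deltaG, stderr = stderr, temperature = temperature,
                 windows = windows), class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("<free_energy_result: dG = %.4f +- %.4f kJ/mol at %g K%s>\n",
              x$deltaG, x$stderr, x$temperature,
              if (is.null(x$windows)) "" else sprintf(" (%d windows)",
                                                      nrow(x$windows))))
  invisible(x)
}

#' Bennett acceptance ratio for one window pair
#'
#' Solves the BAR self-consistency equation
#' `sum_f 1/(1+exp(M + beta*(dU_f - dF))) = sum_r 1/(1+exp(-M - beta*(dU_r - dF)))`
#' with `M = log(n_f/n_r)` by bracketing and Brent root finding (residual
#' below 1e-10), and reports the asymptotic-variance standard error.
#'
#' @param forward numeric samples of `U_next - U_this` in this window's
#'   ensemble (kJ mol^-1).
#' @param reverse numeric samples of the same energy difference in the next
#'   window's ensemble.
#' @param T temperature in kelvin.
#' @return a `free_energy_result` with `dF = F_next - F_this`.
#' @export
bar_pair <- function(forward, reverse, T = 300) {
  if (!length(forward) || !length(reverse)) stop("empty sample set")
  beta <- 1 / (R_GAS * T)
  nf <- length(forward); nr <- length(reverse)
  M <- log(nf / nr)
  fermi <- function(x) 1 / (1 + exp(x))
  resid <- function(dF)
    sum(fermi(M + beta * (forward - dF))) - sum(fermi(-M - beta * (reverse - dF)))

  lo <- min(forward, reverse) - 10 / beta
  hi <- max(forward, reverse) + 10 / beta
  rlo <- resid(lo); rhi <- resid(hi)
  if (!is.finite(rlo) || !is.finite(rhi) || rlo * rhi > 0)
    stop(sprintf("poor overlap: BAR self-consistency has no root in [%.3g, %.3g] (residuals %.3g, %.3g)",
                 lo, hi, rlo, rhi))
  sol <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)
  dF <- sol$root
  # Newton polish until the per-sample residual is below 1e-10
  dresid <- function(dF) {
    ff <- fermi(M + beta * (forward - dF))
    fr <- fermi(-M - beta * (reverse - dF))
    beta * (sum(ff * (1 - ff)) + sum(fr * (1 - fr)))
  }
  for (it in 1:50) {
    r <- resid(dF)
    if (abs(r) / (nf + nr) < 1e-12) break
    dp <- dresid(dF)
    if (dp <= 0) break
    dF <- dF - r / dp
  }

  # Bennett asymptotic variance via the Fermi weights at the solution
  af <- fermi(M + beta * (forward - dF))
  ar <- fermi(-M - beta * (reverse - dF))
  if (mean(af) < 1e-8 || mean(ar) < 1e-8)
    stop(sprintf("poor overlap: mean acceptance weights %.3g (forward) / %.3g (reverse) leave the estimate unconstrained",
                 mean(af), mean(ar)))
  v <- (mean(af^2) / mean(af)^2 - 1) / nf + (mean(ar^2) / mean(ar)^2 - 1) / nr
  free_energy_result(dF, sqrt(max(v, 0)) / beta, T)
}

#' Create a lambda-window series
#'
#' @param lambdas strictly increasing coupling-parameter values in \[0,1\].
#' @param forward list (length `length(lambdas)-1`) of forward sample
#'   vectors for each adjacent pair.
#' @param reverse matching list of reverse sample vectors.
#' @param temperature kelvin.
#' @return a `lambda_series`.
#' @export
lambda_series <- function(lambdas, forward, reverse, temperature = 300) {
  if (length(lambdas) < 2) stop("need at least 2 windows")
  if (any(diff(lambdas) <= 0)) stop("lambdas must be strictly increasing")
  np <- length(lambdas) - 1L
  if (length(forward) != np || length(reverse) != np)
    stop("need one forward and one reverse sample set per adjacent window pair")
  nmin <- min(vapply(forward, length, integer(1)),
              vapply(reverse, length, integer(1)))
  if (nmin < 10) stop("each window pair needs at least 10 samples per side")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(lambdas = lambdas, forward = forward, reverse = reverse,
                 temperature = temperature), class = "lambda_series")
}

#' Chain BAR over all adjacent window pairs
#'
#' `dG = sum of per-pair dF`; the standard error is the quadrature sum of
#' the per-pair errors.
#'
#' @param series a `lambda_series`.
#' @return a `free_energy_result` with a `windows` table of per-pair
#'   contributions.
#' @export
bar_chain <- function(series) {
  stopifnot(inherits(series, "lambda_series"))
  np <- length(series$lambdas) - 1L
  res <- vector("list", np)
  for (i in seq_len(np)) {
    res[[i]] <- tryCatch(
      bar_pair(series$forward[[i]], series$reverse[[i]], series$temperature),
      error = function(e) stop("window pair ", i, " (lambda ",
                               series$lambdas[i], " -> ", series$lambdas[i + 1L],
                               "): ", conditionMessage(e), call. = FALSE))
  }
  dFs <- vapply(res, `[[`, numeric(1), "deltaG")
  ses <- vapply(res, `[[`, numeric(1), "stderr")
  windows <- data.frame(lambda_from = utils::head(series$lambdas, -1),
                        lambda_to = utils::tail(series$lambdas, -1),
                        deltaF = dFs, stderr = ses)
  free_energy_result(sum(dFs), sqrt(sum(ses^2)), series$temperature, windows)
}

#' Water/octanol transfer free energy
#'
#' `dG_W/Oct = dG_W/vac - dG_Oct/vac`, both decoupling free energies
#' (interactions switched off in the named solvent); standard errors are
#' combined in quadrature. A molecule that prefers octanol has a negative
#' transfer free energy and hence a positive log P.
#'
#' @param dG_water_vac,dG_oct_vac `free_energy_result`s at the same
#'   temperature.
#' @return a `free_energy_result`.
#' @export
transfer_free_energy <- function(dG_water_vac, dG_oct_vac) {
  if (!isTRUE(all.equal(dG_water_vac$temperature, dG_oct_vac$temperature)))
    stop("temperature mismatch between solvent legs")
  free_energy_result(dG_water_vac$deltaG - dG_oct_vac$deltaG,
                     sqrt(dG_water_vac$stderr^2 + dG_oct_vac$stderr^2),
                     dG_water_vac$temperature)
}

#' Partition coefficient from a transfer free energy
#'
#' `log P = -dG_W/Oct / (R T ln 10)` with R = 0.0083145 kJ mol^-1 K^-1;
#' the standard error is scaled by the same factor.
#'
#' @param dG a `free_energy_result` holding dG_W/Oct.
#' @param T temperature in kelvin (default: the result's own temperature).
#' @return list with `logP` and `stderr`.
#' @export
log_p <- function(dG, T = NULL) {
  T <- T %||% dG$temperature
  if (T <= 0) stop("temperature must be positive")
  f <- 1 / (R_GAS * T * log(10))
  list(logP = -dG$deltaG * f, stderr = dG$stderr * f)
}

#' Trapezoidal thermodynamic integration (cross-check)
#'
#' Simple trapezoid quadrature of mean dU/dlambda over the windows; a
#' cross-check for BAR when derivative columns are available.
#'
#' @param lambdas window lambda values.
#' @param dudl mean dU/dlambda per window (kJ mol^-1).
#' @return dG in kJ mol^-1.
#' @export
ti_trapezoid <- function(lambdas, dudl) {
  if (length(lambdas) != length(dudl)) stop("length mismatch")
  sum(diff(lambdas) * (utils::head(dudl, -1) + utils::tail(dudl, -1)) / 2)
}

#' Read an XVG-style table
#'
#' Whitespace-delimited numeric columns; `#` and `@` lines are ignored, so
#' MD-engine output can be consumed directly.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_xvg <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@]", lines)]
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  ncol <- length(rows[[1]])
  if (any(vapply(rows, length, integer(1)) != ncol))
    stop("ragged XVG table in ", path)
  matrix(unlist(rows), ncol = ncol, byrow = TRUE)
}

#' Read a directory of per-window energy-difference tables
#'
#' Expects one file per window named `lambda_<i>.xvg` (0-based, sorted
#' numerically) with columns `time, dU_to_next, dU_to_prev` (the neighbor
#' columns may be NaN/absent at the chain ends). Forward samples for pair
#' (i, i+1) come from window i's `dU_to_next`; reverse samples from window
#' i+1's `dU_to_prev`, already in the `U_{i+1} - U_i` convention.
#'
#' @param dir directory of window files.
#' @param lambdas optional lambda values (default: equally spaced on
#'   \[0, 1\]).
#' @param temperature kelvin.
#' @return a `lambda_series`.
#' @export
read_lambda_dir <- function(dir, lambdas = NULL, temperature = 300) {
  files <- list.files(dir, pattern = "^lambda_\\d+\\.xvg$", full.names = TRUE)
  if (length(files) < 2) stop("need at least 2 window files in ", dir)
  ord <- order(as.integer(sub("^lambda_(\\d+)\\.xvg$", "\\1", basename(files))))
  files <- files[ord]
  nw <- length(files)
  tabs <- lapply(files, read_xvg)
  lambdas <- lambdas %||% seq(0, 1, length.out = nw)
  fw <- rv <- vector("list", nw - 1L)
  for (i in seq_len(nw - 1L)) {
    f <- tabs[[i]][, 2]
    r <- tabs[[i + 1L]][, 3]
    fw[[i]] <- f[is.finite(f)]
    rv[[i]] <- r[is.finite(r)]
  }
  lambda_series(lambdas, fw, rv, temperature)
}

#' Write a window directory from sample lists
#'
#' Inverse of [read_lambda_dir()]; used by the synthetic generators and the
#' command-line workflow.
#'
#' @param dir output directory (created if missing).
#' @param forward,reverse lists of per-pair sample vectors.
#' @return `dir`, invisibly.
#' @export
write_lambda_dir <- function(dir, forward, reverse) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nw <- length(forward) + 1L
  for (i in seq_len(nw)) {
    f <- if (i < nw) forward[[i]] else rep(NaN, length(reverse[[i - 1L]]))
    r <- if (i > 1L) reverse[[i - 1L]] else rep(NaN, length(forward[[i]]))
    n <- max(length(f), length(r))
    length(f) <- n; length(r) <- n
    lines <- c("# cgparam lambda window table",
               "@ columns: time dU_to_next dU_to_prev",
               sprintf("%g %.8g %.8g", seq_len(n) - 1, f, r))
    writeLines(lines, file.path(dir, sprintf("lambda_%d.xvg", i - 1L)))
  }
  invisible(dir)
}
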