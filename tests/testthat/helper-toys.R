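# Shared toy fixtures and independent oracles used across test files.

toy_mapping_text <- function(charge_a = 0.0, charge_b = 0.0, formal = NULL) {
  formal <- formal %||% (charge_a + charge_b)
  sprintf("
; two-bead toy molecule
[molecule] TOY %g
[atoms]
A1 C 15.035 9
A2 C 14.027 8
A3 C 14.027 8
A4 C 15.035 9
[bead] B1 SC2 %.2f : A1 A2
[bead] B2 SC2 %.2f : A3 A4
[bonds]
B1 B2
", formal, charge_a, charge_b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random rotation matrix from normalized quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Independent brute-force RMSD minimization over rotations (random
# quaternion search + Nelder-Mead polish on an axis-angle chart).
brute_force_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rot_aa <- function(p) {
    th <- sqrt(sum(p^2))
    if (th < 1e-12) return(diag(3))
    a <- p / th
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  obj_R <- function(R) sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
  best <- list(val = Inf, p = c(0, 0, 0))
  for (i in 1:4000) {
    R <- random_rotation()
    v <- obj_R(R)
    if (v < best$val) {
      th <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
      ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
      na <- sqrt(sum(ax^2))
      best <- list(val = v, p = if (na > 1e-9) th * ax / na else c(0, 0, 0))
    }
  }
  o <- stats::optim(best$p, function(p) obj_R(rot_aa(p)),
                    method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  o$value * 10   # Angstrom
}

# Independent grid + bisection solve of the BAR self-consistency equation.
bar_grid_solve <- function(forward, reverse, T) {
  beta <- 1 / (0.0083145 * T)
  M <- log(length(forward) / length(reverse))
  g <- function(dF)
    sum(1 / (1 + exp(M + beta * (forward - dF)))) -
    sum(1 / (1 + exp(-M - beta * (reverse - dF))))
  grid <- seq(min(forward, reverse) - 20, max(forward, reverse) + 20,
              length.out = 4001)
  vals <- vapply(grid, g, numeric(1))
  sg <- which(diff(sign(vals)) != 0)[1]
  lo <- grid[sg]; hi <- grid[sg + 1]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Bonds of a mapping that are bridges (in no cycle) of the bead-bond graph.
bridge_bonds <- function(mapping) {
  nb <- length(mapping$beads)
  bonds <- mapping$bonds
  vapply(seq_along(bonds), function(k) {
    adj <- vector("list", nb)
    for (kk in seq_along(bonds)) {
      if (kk == k) next
      b <- bonds[[kk]]
      adj[[b[1]]] <- c(adj[[b[1]]], b[2])
      adj[[b[2]]] <- c(adj[[b[2]]], b[1])
    }
    seen <- logical(nb)
    q <- bonds[[k]][1]
    seen[q] <- TRUE
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; q <- c(q, w) }
    }
    !seen[bonds[[k]][2]]
  }, logical(1))
}

# Section line counts of ITP text (data lines only).
itp_section_counts <- function(txt) {
  txt <- sub(";.*$", "", txt)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt)]
  sec <- ""
  counts <- c(atoms = 0, bonds = 0, constraints = 0, angles = 0,
              dihedrals = 0)
  for (ln in txt) {
    if (grepl("^\\[", ln)) {
      sec <- trimws(gsub("\\[|\\]", "", ln))
    } else if (sec %in% names(counts)) {
      counts[sec] <- counts[sec] + 1
    }
  }
  counts
}
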