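# Shipped cofactor mapping registry and idealized geometries.

#' List the shipped cofactor mappings
#'
#' Eight parametrized cofactors plus the two mapping variants: beta-carotene
#' (BCAR), violaxanthin (VIOL), neoxanthin (NEOX), lutein (LUT),
#' plastoquinone (PLQ) and its reduced plastoquinol form (PLQL, quinone
#' TN3a head beads replaced by TN6), chlorophyll A (CLA), chlorophyll B
#' (CLB, one ring substituent bead SN4a instead of TC5), and heme (HEME).
#'
#' @return character vector of mapping codes.
#' @export
cofactor_mappings <- function() {
  c("BCAR", "VIOL", "NEOX", "LUT", "PLQ", "PLQL", "CLA", "CLB", "HEME")
}

#' Load a shipped cofactor mapping
#'
#' @param name a code from [cofactor_mappings()] (case-insensitive).
#' @return a `molecule_mapping`.
#' @export
cofactor_mapping <- function(name) {
  name <- toupper(name)
  if (!name %in% cofactor_mappings())
    stop("unknown cofactor mapping: ", name, " (see cofactor_mappings())")
  path <- system.file("extdata", "mappings", paste0(tolower(name), ".map"),
                      package = "cgparam", mustWork = TRUE)
  read_mapping(path)
}

#' Deterministic idealized bead geometry for a mapping
#'
#' Embeds the bead-bond graph in 3D by stress minimization: bonded pairs
#' are pulled toward a target length set by their size classes, non-bonded
#' pairs are pushed apart below 0.3 nm. The optimization is pure arithmetic
#' driven by an internal linear-congruential generator, so the result is
#' byte-stable across platforms; coordinates are rounded to 1e-5 nm.
#'
#' @param mapping a `molecule_mapping`.
#' @param seed integer seed for the internal generator.
#' @param n_iter gradient-descent iterations.
#' @return nbeads x 3 matrix of coordinates (nm), rownames = bead names.
#' @export
idealized_coordinates <- function(mapping, seed = 1234, n_iter = 400) {
  nb <- length(mapping$beads)
  rng <- lcg_new(seed)
  X <- matrix(rng(3 * nb) - 0.5, nb, 3) * max(1, nb^(1 / 3) * 0.6)
  if (nb == 1L) X <- matrix(0, 1, 3)
  types <- vapply(mapping$beads, `[[`, character(1), "martini_type")
  rad <- c(T = 0.125, S = 0.155, R = 0.185)[bead_size_class(types)]

  bonds <- mapping$bonds
  L <- vapply(bonds, function(b) rad[b[1]] + rad[b[2]], numeric(1))
  bonded_key <- vapply(bonds, function(b) paste(sort(b), collapse = "-"),
                       character(1))
  rep_cut <- 0.30
  step <- 0.05
  for (it in seq_len(n_iter)) {
    G <- matrix(0, nb, 3)
    for (k in seq_along(bonds)) {
      i <- bonds[[k]][1]; j <- bonds[[k]][2]
      v <- X[i, ] - X[j, ]
      d <- sqrt(sum(v^2))
      if (d < 1e-8) { v <- c(1e-3, 0, 0); d <- 1e-3 }
      g <- (d - L[k]) * v / d
      G[i, ] <- G[i, ] - g
      G[j, ] <- G[j, ] + g
    }
    if (nb > 2) {
      for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
        if (paste(i, j, sep = "-") %in% bonded_key) next
        v <- X[i, ] - X[j, ]
        d <- sqrt(sum(v^2))
        if (d < rep_cut && d > 1e-8) {
          g <- 0.5 * (rep_cut - d) * v / d
          G[i, ] <- G[i, ] + g
          G[j, ] <- G[j, ] - g
        }
      }
    }
    X <- X + step * G
  }
  X <- sweep(X, 2, colMeans(X))
  X <- round(X, 5)
  rownames(X) <- vapply(mapping$beads, `[[`, character(1), "name")
  X
}

# Bonds emitted as sharp ("constraint-like") in the synthetic reference
# statistics: both endpoints tiny beads, or a metal bead (TQ3p/SQ3p)
# bonded to a tiny bead -- the closely packed aromatic ring networks.
stiff_bond_flags <- function(mapping) {
  types <- vapply(mapping$beads, `[[`, character(1), "martini_type")
  ringish <- bead_size_class(types) == "T" | types %in% c("TQ3p", "SQ3p")
  vapply(mapping$bonds, function(b) all(ringish[b]), logical(1))
}

#' Reference ("programmed") bonded statistics for a mapping
#'
#' The synthetic stand-in for a mapped atomistic reference ensemble:
#' equilibrium values are measured on the idealized geometry; chain bonds
#' get a harmonic width of sqrt(R*T/k_bond), while ring-network bonds (see
#' the constraint rule) are programmed sharp (default sigma 0.002 nm, below
#' the constraint threshold). Angles and impropers get uniform generic
#' force constants.
#'
#' @param mapping a `molecule_mapping`.
#' @param coords optional idealized coordinates.
#' @param T temperature (K) at which sigma and k are related.
#' @param k_bond,k_angle,k_improper force constants of the soft terms.
#' @param stiff_sigma width (nm) programmed for ring-network bonds.
#' @return list with `coords` and data.frames `bonds` (i, j, b0, k, sigma,
#'   stiff), `angles` (i, j, k_, theta0, k), `impropers` (i, j, k_, l, xi0,
#'   k).
#' @export
bonded_targets <- function(mapping, coords = NULL, T = 298,
                           k_bond = 5000, k_angle = 100, k_improper = 50,
                           stiff_sigma = 0.002) {
  coords <- coords %||% idealized_coordinates(mapping)
  stiff <- stiff_bond_flags(mapping)
  bonds <- NULL
  if (length(mapping$bonds)) {
    b0 <- vapply(mapping$bonds, function(b) vnorm(coords[b[1], ] - coords[b[2], ]),
                 numeric(1))
    sigma <- ifelse(stiff, stiff_sigma, sqrt(R_GAS * T / k_bond))
    bonds <- data.frame(
      i = vapply(mapping$bonds, `[`, integer(1), 1),
      j = vapply(mapping$bonds, `[`, integer(1), 2),
      b0 = b0, k = R_GAS * T / sigma^2, sigma = sigma, stiff = stiff)
  }
  angles <- NULL
  if (length(mapping$angles)) {
    th0 <- vapply(mapping$angles, function(a)
      angle_deg(coords[a[1], ], coords[a[2], ], coords[a[3], ]), numeric(1))
    angles <- data.frame(
      i = vapply(mapping$angles, `[`, integer(1), 1),
      j = vapply(mapping$angles, `[`, integer(1), 2),
      k_ = vapply(mapping$angles, `[`, integer(1), 3),
      theta0 = th0, k = k_angle)
  }
  impropers <- NULL
  if (length(mapping$impropers)) {
    xi0 <- vapply(mapping$impropers, function(im)
      dihedral_deg(coords[im[1], ], coords[im[2], ], coords[im[3], ], coords[im[4], ]),
      numeric(1))
    impropers <- data.frame(
      i = vapply(mapping$impropers, `[`, integer(1), 1),
      j = vapply(mapping$impropers, `[`, integer(1), 2),
      k_ = vapply(mapping$impropers, `[`, integer(1), 3),
      l = vapply(mapping$impropers, `[`, integer(1), 4),
      xi0 = xi0, k = k_improper)
  }
  list(coords = coords, bonds = bonds, angles = angles, impropers = impropers,
       temperature = T)
}
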