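# Shared constants and small numeric helpers.

#' Molar gas constant in kJ mol^-1 K^-1
#'
#' The value used throughout for Boltzmann inversion and free-energy
#' conversions.
#' @export
R_GAS <- 0.0083145

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @keywords internal
#' Deterministic linear congruential generator.
#'
#' Used where byte-stable output across platforms matters (idealized fixture
#' geometries); the statistical generators use R's RNG via `set.seed()`.
lcg_new <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 16807) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

# Quasi-uniform directions on the unit sphere (Fibonacci / golden-spiral
# lattice). Returns an n x 3 matrix.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

vnorm <- function(v) sqrt(sum(v^2))

# Angle (degrees) at vertex j for points i-j-k.
angle_deg <- function(ri, rj, rk) {
  a <- ri - rj
  b <- rk - rj
  na <- vnorm(a); nb <- vnorm(b)
  if (na < 1e-12 || nb < 1e-12) stop("degenerate internal coordinate", call. = FALSE)
  cosang <- sum(a * b) / (na * nb)
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

# Signed dihedral (degrees) between planes (i,j,k) and (j,k,l).
dihedral_deg <- function(ri, rj, rk, rl) {
  b1 <- rj - ri
  b2 <- rk - rj
  b3 <- rl - rk
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12)
    stop("degenerate internal coordinate", call. = FALSE)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / vnorm(b2)
  rad2deg(atan2(y, x))
}

# Mean of angular data in degrees, safe near +-180.
circular_mean_deg <- function(x) {
  r <- deg2rad(x)
  rad2deg(atan2(mean(sin(r)), mean(cos(r))))
}

# Element data used for atom records: atomic number (= electrons of the
# neutral atom) and atomic mass. Implicit hydrogens are added per atom.
.element_z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, MG = 12, FE = 26,
                MN = 25, CA = 20)
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                   S = 32.06, MG = 24.305, FE = 55.845, MN = 54.938, CA = 40.078)

element_electrons <- function(el) {
  z <- .element_z[toupper(el)]
  if (any(is.na(z))) stop("unknown element: ", paste(el[is.na(z)], collapse = ", "))
  unname(z)
}

element_mass <- function(el) {
  m <- .element_mass[toupper(el)]
  if (any(is.na(m))) stop("unknown element: ", paste(el[is.na(m)], collapse = ", "))
  unname(m)
}

# Martini 3 size class of a bead type string ("T...", "S...", regular).
bead_size_class <- function(type) {
  ifelse(grepl("^T", type), "T", ifelse(grepl("^S", type), "S", "R"))
}

#' Default Martini 3 bead masses by size class
#'
#' Regular beads weigh 72 amu, small (S) beads 54 amu and tiny (T) beads
#' 36 amu; emitted topologies use these force-field defaults rather than
#' summed atomic masses (the mapped-atom mass sums are kept on the mapping
#' for projection).
#'
#' @param type character vector of Martini bead type strings (e.g. "TQ3p").
#' @return numeric vector of masses in amu.
#' @export
martini_bead_mass <- function(type) {
  unname(c(T = 36, S = 54, R = 72)[bead_size_class(type)])
}

#' Default coarse-grained bead radii for SASA (nm)
#'
#' Half the Martini 3 size-class Lennard-Jones sigma: 0.264 nm (regular),
#' 0.230 nm (small), 0.191 nm (tiny). Override by passing an explicit radii
#' table to [sasa()].
#'
#' @param type character vector of bead type strings.
#' @return numeric vector of radii in nm.
#' @export
cg_bead_radii <- function(type) {
  unname(c(T = 0.191, S = 0.230, R = 0.264)[bead_size_class(type)])
}

#' Van der Waals radii for (united) atoms, nm
#'
#' Carbon carries the united-atom value (implicit hydrogens folded in);
#' heteroatoms use standard van der Waals radii.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in nm.
#' @export
aa_atom_radii <- function(element) {
  tab <- c(C = 0.200, N = 0.155, O = 0.152, H = 0.120, P = 0.180, S = 0.180,
           MG = 0.173, FE = 0.160, MN = 0.160, CA = 0.170)
  r <- tab[toupper(element)]
  if (any(is.na(r))) stop("missing radius for element: ",
                          paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}
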