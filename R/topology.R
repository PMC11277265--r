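# GROMACS-dialect ITP topologies: the emit-ready parameter container, the
# writer/parser pair, and the special-case builders (pheophytin A from
# chlorophyll A, the 4-bead oxygen-evolving cluster, harmonic cofactor
# restraints).

#' Construct a coarse-grained topology
#'
#' @param molecule_name molecule/moleculetype name.
#' @param beads data.frame with columns `index` (1-based contiguous),
#'   `type`, `residue`, `name`, `charge`, `mass`.
#' @param bonds,constraints,angles,impropers lists of `harmonic_term`.
#' @param nrexcl number of bonded-neighbor exclusions (Martini convention 1).
#' @param notes character vector of provenance comments carried into the
#'   emitted file.
#' @return a `cg_topology`.
#' @export
cg_topology <- function(molecule_name, beads, bonds = list(),
                        constraints = list(), angles = list(),
                        impropers = list(), nrexcl = 1L,
                        notes = character()) {
  beads <- as.data.frame(beads)
  need <- c("index", "type", "residue", "name", "charge", "mass")
  if (!all(need %in% names(beads)))
    stop("beads must have columns: ", paste(need, collapse = ", "))
  if (!identical(as.integer(beads$index), seq_len(nrow(beads))))
    stop("bead indices must be 1-based and contiguous")
  if (any(beads$mass <= 0)) stop("bead masses must be positive")
  top <- structure(list(molecule_name = molecule_name, nrexcl = as.integer(nrexcl),
                        beads = beads, bonds = bonds, constraints = constraints,
                        angles = angles, impropers = impropers, notes = notes),
                   class = "cg_topology")
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  n <- nrow(top$beads)
  key <- function(t) paste(sort(t$indices[1:2]), collapse = "-")
  for (sec in c("bonds", "constraints", "angles", "impropers")) {
    for (t in top[[sec]]) {
      if (any(t$indices < 1L) || any(t$indices > n))
        stop("term in [", sec, "] references bead outside 1..", n)
    }
  }
  bk <- vapply(top$bonds, key, character(1))
  ck <- vapply(top$constraints, key, character(1))
  dup <- intersect(bk, ck)
  if (length(dup))
    stop("bead pair(s) duplicated as both bond and constraint: ",
         paste(dup, collapse = ", "))
  invisible(top)
}

#' Net charge of a topology
#' @param top a `cg_topology`.
#' @return total bead charge in e.
#' @export
net_charge <- function(top) sum(top$beads$charge)

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("<cg_topology %s: %d beads; %d bonds, %d constraints, %d angles, %d impropers; net charge %+g e>\n",
              x$molecule_name, nrow(x$beads), length(x$bonds),
              length(x$constraints), length(x$angles), length(x$impropers),
              net_charge(x)))
  invisible(x)
}

#' Build a topology from a mapping
#'
#' Bead records come from the mapping (Martini 3 size-class default masses:
#' 72/54/36 amu). Bonded parameters come either from fitted terms
#' (`fit_terms()` output) or, when `terms` is `NULL`, from a preliminary
#' parameter set: equilibrium values measured on the idealized geometry
#' (supplied or built with [idealized_coordinates()]) and generic initial
#' force constants, the starting point the distribution-matching loop
#' refines. All mapped pairs are emitted as bonds in that preliminary set;
#' constraint substitution happens once measured distributions exist.
#'
#' @param mapping a `molecule_mapping`.
#' @param terms optional `fit_terms()` result.
#' @param coords optional idealized bead coordinates (nm) used when `terms`
#'   is `NULL`.
#' @param residue residue code (default: molecule name truncated to 4).
#' @param k_defaults initial force constants for the preliminary set.
#' @return a `cg_topology`.
#' @export
as_cg_topology <- function(mapping, terms = NULL, coords = NULL,
                           residue = NULL,
                           k_defaults = c(bond = 5000, angle = 100,
                                          improper = 50)) {
  residue <- residue %||% substr(mapping$molecule_name, 1, 4)
  types <- vapply(mapping$beads, `[[`, character(1), "martini_type")
  beads <- data.frame(
    index = seq_along(mapping$beads),
    type = types,
    residue = residue,
    name = vapply(mapping$beads, `[[`, character(1), "name"),
    charge = vapply(mapping$beads, `[[`, numeric(1), "charge"),
    mass = martini_bead_mass(types),
    stringsAsFactors = FALSE)

  if (is.null(terms)) {
    if (is.null(coords)) coords <- idealized_coordinates(mapping)
    bonds <- lapply(mapping$bonds, function(b) {
      r0 <- vnorm(coords[b[1], ] - coords[b[2], ])
      harmonic_term("bond", b, r0, unname(k_defaults["bond"]), 1L)
    })
    angles <- lapply(mapping$angles, function(a)
      harmonic_term("angle", a, angle_deg(coords[a[1], ], coords[a[2], ], coords[a[3], ]),
                    unname(k_defaults["angle"]), 2L))
    impropers <- lapply(mapping$impropers, function(im)
      harmonic_term("improper", im,
                    dihedral_deg(coords[im[1], ], coords[im[2], ], coords[im[3], ], coords[im[4], ]),
                    unname(k_defaults["improper"]), 2L))
    terms <- list(bonds = bonds, constraints = list(), angles = angles,
                  impropers = impropers)
    notes <- sprintf("%s: preliminary parameters (idealized geometry)",
                     mapping$molecule_name)
  } else {
    notes <- sprintf("%s: Boltzmann-inverted from mapped ensemble",
                     mapping$molecule_name)
  }
  cg_topology(mapping$molecule_name, beads,
              bonds = terms$bonds, constraints = terms$constraints,
              angles = terms$angles, impropers = terms$impropers,
              notes = notes)
}

fmt_term_line <- function(t) {
  idx <- paste(sprintf("%5d", t$indices), collapse = " ")
  if (t$kind == "constraint")
    sprintf("%s %5d %12.6f", idx, t$funct, t$equilibrium)
  else
    sprintf("%s %5d %12.6f %12.2f", idx, t$funct, t$equilibrium, t$force_constant)
}

#' Emit a topology as GROMACS ITP text
#'
#' Sections in fixed order (`[moleculetype]`, `[atoms]`, `[bonds]`,
#' `[constraints]`, `[angles]`, `[dihedrals]`), deterministic formatting
#' (6 decimals for equilibria, 2 for force constants); empty bonded
#' sections are omitted. Provenance notes are carried as `; ` comments.
#'
#' @param top a `cg_topology`.
#' @param path optional output path; when given the text is also written.
#' @return the ITP text as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
write_itp <- function(top, path = NULL) {
  validate_topology(top)
  out <- c(sprintf("; %s", top$notes),
           "[ moleculetype ]",
           "; name nrexcl",
           sprintf("%s %d", top$molecule_name, top$nrexcl),
           "",
           "[ atoms ]",
           "; nr type resnr residue atom cgnr charge mass",
           sprintf("%5d %6s %5d %6s %6s %5d %10.4f %8.2f",
                   top$beads$index, top$beads$type, 1L, top$beads$residue,
                   top$beads$name, top$beads$index, top$beads$charge,
                   top$beads$mass))
  secmap <- list(bonds = "bonds", constraints = "constraints",
                 angles = "angles", impropers = "dihedrals")
  for (sec in names(secmap)) {
    terms <- top[[sec]]
    if (!length(terms)) next
    out <- c(out, "", sprintf("[ %s ]", secmap[[sec]]),
             vapply(terms, fmt_term_line, character(1)))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Parse GROMACS ITP text into a topology
#'
#' Accepts the dialect emitted by [write_itp()] (plus arbitrary extra
#' whitespace and `;` comments): bonds and constraints funct 1, angles
#' funct 2 (cosine-harmonic), dihedrals funct 2 (improper). The writer and
#' parser form a round-trip identity. Unknown sections and unsupported
#' function codes are errors.
#'
#' @param text character scalar or vector of ITP lines.
#' @return a `cg_topology`.
#' @export
read_itp <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  raw <- sub(";.*$", "", text)
  raw <- trimws(gsub("\\s+", " ", raw))
  keep <- nzchar(raw)
  raw <- raw[keep]

  known <- c("moleculetype", "atoms", "bonds", "constraints", "angles",
             "dihedrals")
  section <- ""
  mol <- NULL; nrexcl <- 1L
  beads <- list()
  terms <- list(bonds = list(), constraints = list(), angles = list(),
                impropers = list())
  arity <- c(bonds = 2L, constraints = 2L, angles = 3L, impropers = 4L)
  ok_funct <- list(bonds = 1L, constraints = 1L, angles = 2L, impropers = 2L)

  for (ln in raw) {
    if (grepl("^\\[", ln)) {
      sec <- trimws(gsub("\\[|\\]", "", ln))
      if (!sec %in% known) stop("unknown section: [", sec, "]")
      section <- if (sec == "dihedrals") "impropers" else sec
      next
    }
    tok <- strsplit(ln, " ")[[1]]
    if (section == "moleculetype") {
      mol <- tok[1]; nrexcl <- as.integer(tok[2])
    } else if (section == "atoms") {
      beads[[length(beads) + 1L]] <- data.frame(
        index = as.integer(tok[1]), type = tok[2], residue = tok[4],
        name = tok[5], charge = as.numeric(tok[7]), mass = as.numeric(tok[8]),
        stringsAsFactors = FALSE)
    } else if (section %in% names(terms)) {
      na <- arity[[section]]
      idx <- as.integer(tok[seq_len(na)])
      funct <- as.integer(tok[na + 1L])
      if (!funct %in% ok_funct[[section]])
        stop("unsupported function code ", funct, " in [", section, "]")
      eq <- as.numeric(tok[na + 2L])
      k <- if (length(tok) >= na + 3L) as.numeric(tok[na + 3L]) else NA_real_
      kind <- sub("s$", "", section)
      terms[[section]][[length(terms[[section]]) + 1L]] <-
        harmonic_term(kind, idx, eq, k, funct)
    } else {
      stop("data line outside any section: ", ln)
    }
  }
  if (is.null(mol)) stop("missing [moleculetype] section")
  beads <- do.call(rbind, beads)
  if (!identical(as.integer(beads$index), seq_len(nrow(beads))))
    stop("non-contiguous bead indices in [atoms]")
  cg_topology(mol, beads, bonds = terms$bonds, constraints = terms$constraints,
              angles = terms$angles, impropers = terms$impropers,
              nrexcl = nrexcl, notes = character())
}

#' Derive pheophytin A from a chlorophyll A topology
#'
#' Pheophytin A is chlorophyll A without the central magnesium: the Mg bead
#' (type TQ3p) is removed with index re-packing, every bead charge is set
#' to zero, every constraint becomes a bond with a force constant of
#' 50,000 kJ mol^-1 nm^-2 (unchanged equilibrium, stabilizing the central
#' ring), and bonded terms that referenced the removed bead are dropped.
#'
#' @param chlA a chlorophyll-A-like `cg_topology` (must contain a TQ3p bead).
#' @param residue residue code for the derived molecule.
#' @return a `cg_topology` for pheophytin A.
#' @export
derive_pheophytin <- function(chlA, residue = "PHO") {
  mg <- which(chlA$beads$type == "TQ3p")
  if (length(mg) != 1L) stop("not a chlorophyll-like topology: need exactly one TQ3p bead")
  keep <- setdiff(seq_len(nrow(chlA$beads)), mg)
  remap <- integer(nrow(chlA$beads))
  remap[keep] <- seq_along(keep)

  beads <- chlA$beads[keep, , drop = FALSE]
  beads$index <- seq_len(nrow(beads))
  beads$charge <- 0
  beads$residue <- residue
  rownames(beads) <- NULL

  strip <- function(terms) {
    kept <- Filter(function(t) !mg %in% t$indices, terms)
    lapply(kept, function(t) { t$indices <- remap[t$indices]; t })
  }
  bonds <- strip(chlA$bonds)
  for (t in strip(chlA$constraints))
    bonds[[length(bonds) + 1L]] <-
      harmonic_term("bond", t$indices, t$equilibrium, 50000, 1L)

  cg_topology(residue, beads, bonds = bonds, constraints = list(),
              angles = strip(chlA$angles), impropers = strip(chlA$impropers),
              nrexcl = chlA$nrexcl,
              notes = sprintf("%s: derived from %s (Mg bead removed, charges zeroed, constraints -> bonds k=50000)",
                              residue, chlA$molecule_name))
}

#' Build the 4-bead oxygen-evolving cluster model
#'
#' The CaMn4O5 cluster is modeled by 4 beads connected by all 6 pairwise
#' bonds with a force constant of 10,000 kJ mol^-1 nm^-2; equilibrium
#' distances come from the supplied (mapped-structure) coordinates. The
#' cluster carries a 2+ charge; by default it is distributed as +0.5 e per
#' bead (total +2), with `charge_mode = "per_bead"` assigning +2 e to each
#' bead record instead.
#'
#' @param coords 4 x 3 matrix of bead coordinates (nm).
#' @param charge_mode "cluster" (default; +0.5 e per bead, +2 total) or
#'   "per_bead" (+2 e per bead).
#' @param bead_type Martini type stamped on the cluster beads.
#' @return a `cg_topology`.
#' @export
build_oex <- function(coords, charge_mode = c("cluster", "per_bead"),
                      bead_type = "Q5") {
  charge_mode <- match.arg(charge_mode)
  coords <- as.matrix(coords)
  if (nrow(coords) < 4L) stop("need 4 bead coordinates for the OEX cluster")
  if (nrow(coords) > 4L) stop("the OEX cluster has exactly 4 beads")
  q <- if (charge_mode == "cluster") 0.5 else 2.0
  beads <- data.frame(index = 1:4, type = bead_type, residue = "OEX",
                      name = paste0("OX", 1:4), charge = q,
                      mass = martini_bead_mass(bead_type),
                      stringsAsFactors = FALSE)
  pairs <- utils::combn(4, 2)
  bonds <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    r0 <- vnorm(coords[i1, ] - coords[i2, ])
    if (r0 <= 0) stop("coincident OEX beads")
    harmonic_term("bond", c(i1, i2), r0, 10000, 1L)
  })
  cg_topology("OEX", beads, bonds = bonds,
              notes = sprintf("OEX: CaMn4O5 cluster, 4 beads / 6 bonds k=10000, %s charges (+%g e per bead)",
                              charge_mode, q))
}

#' Build harmonic cofactor-protein restraints
#'
#' For each (cofactor bead, protein bead) pair the equilibrium distance is
#' the observed pair distance in the supplied structure; the default force
#' constant is 1000 kJ mol^-1 nm^-2 (Mg-protein chlorophyll restraints and
#' pheophytin A elastic bonds), with 300 kJ mol^-1 nm^-2 the convention for
#' generic cofactor elastic bonds.
#'
#' @param frame a `cg_frame` holding both partners' coordinates.
#' @param pairs 2-column matrix of site indices (cofactor, protein).
#' @param k force constant(s), kJ mol^-1 nm^-2 (recycled over pairs).
#' @return a `restraint_set` data.frame with columns i, j, r0, k.
#' @export
build_restraints <- function(frame, pairs, k = 1000) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  k <- rep_len(k, nrow(pairs))
  if (any(k <= 0)) stop("restraint force constants must be positive")
  r0 <- vapply(seq_len(nrow(pairs)), function(i)
    vnorm(frame$coords[pairs[i, 1], ] - frame$coords[pairs[i, 2], ]),
    numeric(1))
  if (any(r0 <= 1e-9)) stop("coincident beads in restraint pair")
  structure(data.frame(i = pairs[, 1], j = pairs[, 2], r0 = r0, k = k),
            class = c("restraint_set", "data.frame"))
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set: %d harmonic restraints, k in [%g, %g] kJ/mol/nm^2>\n",
              nrow(x), min(x$k), max(x$k)))
  print.data.frame(x, ...)
  invisible(x)
}
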