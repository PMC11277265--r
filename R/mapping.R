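# Atom-to-bead mappings: the plain-text mapping format, validation, and
# projection of atomistic frames onto bead coordinates.
#
# Mapping file grammar (line oriented, ';' comments):
#   [molecule] <name> <formal_charge>
#   [atoms]
#   <name> <element> <mass> <electrons>
#   [bead] <name> <martini_type> <charge> : <atom1> <atom2> ...
#   [bonds] / [angles] / [impropers]
#   <beadname> <beadname> [...]

#' Parse a mapping specification
#'
#' Reads the plain-text mapping format into a validated `molecule_mapping`:
#' the atom table (united-atom masses and electron counts, implicit
#' hydrogens folded in), the bead assignments with Martini 3 types and
#' charges, and the bead-level bonded graph (bonds, angles, impropers).
#'
#' Validation enforces the mapping invariants: every atom is mapped to one
#' bead (or exactly two, for doubly-mapped atoms), bead sizes respect the
#' Martini size classes (regular 2-6 heavy atoms, S 2-4, T 1-3), bead
#' charges are multiples of 0.05 e and sum to the declared formal charge,
#' bonded terms reference existing beads, and the bead-bond graph is
#' connected.
#'
#' @param text character scalar (file content) or vector of lines.
#' @return a `molecule_mapping` object.
#' @seealso [read_mapping()], [project_frame()], [electrons_per_bead()]
#' @export
parse_mapping <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  text <- sub(";.*$", "", text)
  text <- trimws(text)
  text <- text[nzchar(text)]

  mol_name <- NULL
  formal_charge <- NA_real_
  atoms <- list()
  beads <- list()
  pairs <- list(bonds = list(), angles = list(), impropers = list())
  section <- ""

  for (ln in text) {
    if (startsWith(ln, "[molecule]")) {
      tok <- strsplit(ln, "\\s+")[[1]]
      mol_name <- tok[2]
      formal_charge <- as.numeric(tok[3])
      section <- ""
    } else if (startsWith(ln, "[atoms]")) {
      section <- "atoms"
    } else if (startsWith(ln, "[bead]")) {
      rest <- trimws(sub("^\\[bead\\]", "", ln))
      halves <- strsplit(rest, ":", fixed = TRUE)[[1]]
      if (length(halves) != 2) stop("malformed [bead] line: ", ln)
      head <- strsplit(trimws(halves[1]), "\\s+")[[1]]
      if (length(head) != 3) stop("malformed [bead] line: ", ln)
      beads[[length(beads) + 1L]] <- list(
        name = head[1], martini_type = head[2], charge = as.numeric(head[3]),
        atoms = strsplit(trimws(halves[2]), "\\s+")[[1]])
    } else if (ln %in% c("[bonds]", "[angles]", "[impropers]")) {
      section <- gsub("\\[|\\]", "", ln)
    } else if (section == "atoms") {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) != 4) stop("malformed atom record: ", ln)
      atoms[[length(atoms) + 1L]] <- list(
        name = tok[1], element = tok[2],
        mass = as.numeric(tok[3]), electrons = as.numeric(tok[4]))
    } else if (section %in% c("bonds", "angles", "impropers")) {
      pairs[[section]][[length(pairs[[section]]) + 1L]] <- strsplit(ln, "\\s+")[[1]]
    } else {
      stop("unexpected line outside any section: ", ln)
    }
  }

  if (is.null(mol_name) || is.na(formal_charge))
    stop("missing [molecule] header")

  atom_df <- data.frame(
    name = vapply(atoms, `[[`, character(1), "name"),
    element = vapply(atoms, `[[`, character(1), "element"),
    mass = vapply(atoms, `[[`, numeric(1), "mass"),
    electrons = vapply(atoms, `[[`, numeric(1), "electrons"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(atom_df$name)) stop("duplicate atom names")
  if (any(atom_df$mass <= 0)) stop("atom masses must be positive")
  if (any(atom_df$electrons < 1)) stop("atom electron counts must be >= 1")

  bead_names <- vapply(beads, `[[`, character(1), "name")
  if (anyDuplicated(bead_names)) stop("duplicate bead names")

  # atom references and per-atom multiplicity
  counts <- stats::setNames(integer(nrow(atom_df)), atom_df$name)
  for (b in beads) {
    bad <- setdiff(b$atoms, atom_df$name)
    if (length(bad))
      stop("unmapped reference: bead ", b$name, " lists unknown atom(s) ",
           paste(bad, collapse = ", "))
    if (anyDuplicated(b$atoms)) stop("bead ", b$name, " lists an atom twice")
    counts[b$atoms] <- counts[b$atoms] + 1L
    nh <- length(b$atoms)
    cls <- bead_size_class(b$martini_type)
    lim <- switch(cls, T = c(1L, 3L), S = c(2L, 4L), R = c(2L, 6L))
    # metal ions map 1:1 whatever the bead size class (e.g. Fe -> SQ3p)
    is_metal_ion <- nh == 1L &&
      toupper(atom_df$element[match(b$atoms, atom_df$name)]) %in%
        c("MG", "FE", "MN", "CA", "ZN", "NA", "K", "CL")
    if (!is_metal_ion && (nh < lim[1] || nh > lim[2]))
      stop("bead ", b$name, " (", b$martini_type, ") maps ", nh,
           " atoms; allowed ", lim[1], "-", lim[2], " for size class ", cls)
    if (abs(b$charge / 0.05 - round(b$charge / 0.05)) > 1e-9)
      stop("bead ", b$name, " charge ", b$charge, " is not a multiple of 0.05 e")
  }
  if (any(counts == 0L))
    stop("unmapped reference: atom(s) not assigned to any bead: ",
         paste(atom_df$name[counts == 0L], collapse = ", "))
  if (any(counts > 2L))
    stop("over-mapping: atom(s) in more than two beads: ",
         paste(atom_df$name[counts > 2L], collapse = ", "))

  qsum <- sum(vapply(beads, `[[`, numeric(1), "charge"))
  if (abs(qsum - formal_charge) > 1e-9)
    stop(sprintf("charge inconsistency: bead charges sum to %.4f but formal charge is %.4f",
                 qsum, formal_charge))

  idx_of <- function(nm, arity, kind) {
    lapply(nm, function(tok) {
      if (length(tok) != arity) stop("malformed ", kind, " record")
      miss <- setdiff(tok, bead_names)
      if (length(miss)) stop("unmapped reference: ", kind, " names unknown bead(s) ",
                             paste(miss, collapse = ", "))
      match(tok, bead_names)
    })
  }
  bonds <- idx_of(pairs$bonds, 2L, "bond")
  angles <- idx_of(pairs$angles, 3L, "angle")
  impropers <- idx_of(pairs$impropers, 4L, "improper")

  # connectivity of the bead-bond graph
  nb <- length(beads)
  if (nb > 1L) {
    adj <- vector("list", nb)
    for (b in bonds) {
      adj[[b[1]]] <- c(adj[[b[1]]], b[2])
      adj[[b[2]]] <- c(adj[[b[2]]], b[1])
    }
    seen <- logical(nb)
    queue <- 1L
    seen[1L] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    if (!all(seen))
      stop("bead-bond graph is not connected (bead ",
           bead_names[which(!seen)[1]], " unreachable)")
  }

  structure(list(
    molecule_name = mol_name,
    formal_charge = formal_charge,
    atoms = atom_df,
    beads = beads,
    bonds = bonds,
    angles = angles,
    impropers = impropers), class = "molecule_mapping")
}

#' Read a mapping file
#'
#' @param path path to a mapping file.
#' @return a `molecule_mapping`.
#' @export
read_mapping <- function(path) parse_mapping(readLines(path))

#' @export
print.molecule_mapping <- function(x, ...) {
  cat(sprintf("<molecule_mapping %s: %d atoms -> %d beads; %d bonds, %d angles, %d impropers; charge %+g e>\n",
              x$molecule_name, nrow(x$atoms), length(x$beads),
              length(x$bonds), length(x$angles), length(x$impropers),
              x$formal_charge))
  invisible(x)
}

#' @export
format.molecule_mapping <- function(x, ...) {
  # re-emit the mapping in its file format
  out <- c(sprintf("[molecule] %s %g", x$molecule_name, x$formal_charge),
           "[atoms]",
           sprintf("%s %s %.3f %g", x$atoms$name, x$atoms$element,
                   x$atoms$mass, x$atoms$electrons))
  for (b in x$beads)
    out <- c(out, sprintf("[bead] %s %s %.2f : %s", b$name, b$martini_type,
                          b$charge, paste(b$atoms, collapse = " ")))
  bead_names <- vapply(x$beads, `[[`, character(1), "name")
  emit <- function(sec, tuples) {
    if (!length(tuples)) return(character(0))
    c(sprintf("[%s]", sec),
      vapply(tuples, function(t) paste(bead_names[t], collapse = " "), character(1)))
  }
  c(out, emit("bonds", x$bonds), emit("angles", x$angles),
    emit("impropers", x$impropers))
}

#' Write a mapping to its file format
#'
#' @param mapping a `molecule_mapping`.
#' @param path output path.
#' @export
write_mapping <- function(mapping, path) {
  writeLines(format(mapping), path)
  invisible(path)
}

# membership matrix (atoms x beads), 1 where atom belongs to bead
bead_membership <- function(mapping) {
  na <- nrow(mapping$atoms)
  nb <- length(mapping$beads)
  M <- matrix(0, na, nb, dimnames = list(mapping$atoms$name, NULL))
  for (j in seq_len(nb)) M[mapping$beads[[j]]$atoms, j] <- 1
  M
}

#' Project an atomistic frame onto bead coordinates
#'
#' Each bead position is the mass-weighted mean (center of mass) of its
#' mapped atoms; a doubly-mapped atom contributes its full mass to each
#' host bead independently. `method = "cog"` uses the unweighted center of
#' geometry instead.
#'
#' @param mapping a `molecule_mapping`.
#' @param frame a `cg_frame` with one row per mapping atom, in atom order.
#' @param method "com" (default, mass-weighted) or "cog".
#' @return a `cg_frame` of bead coordinates (mapping bead order), box kept.
#' @export
project_frame <- function(mapping, frame, method = c("com", "cog")) {
  method <- match.arg(method)
  if (nrow(frame$coords) != nrow(mapping$atoms))
    stop(sprintf("projection shape error: frame has %d atoms, mapping has %d",
                 nrow(frame$coords), nrow(mapping$atoms)))
  W <- bead_membership(mapping)
  w <- if (method == "com") W * mapping$atoms$mass else W
  w <- sweep(w, 2, colSums(w), "/")
  bead_xyz <- t(w) %*% frame$coords
  rownames(bead_xyz) <- vapply(mapping$beads, `[[`, character(1), "name")
  cg_frame(bead_xyz, box = frame$box)
}

#' Project every frame of an ensemble
#'
#' @inheritParams project_frame
#' @param ensemble a `cg_ensemble` of atomistic frames.
#' @return a `cg_ensemble` of bead frames.
#' @export
project_ensemble <- function(mapping, ensemble, method = c("com", "cog")) {
  method <- match.arg(method)
  cg_ensemble(lapply(ensemble, project_frame, mapping = mapping, method = method))
}

#' Electrons carried by each bead
#'
#' Sums the electron counts of the atoms mapped into each bead. A
#' doubly-mapped atom's electrons are split equally between its two host
#' beads, so the total over beads always equals the molecular electron
#' count. Used to weight electron density profiles.
#'
#' @param mapping a `molecule_mapping`.
#' @return numeric vector (one entry per bead, mapping order); entries can
#'   be half-integers where doubly-mapped atoms carry odd electron counts.
#' @export
electrons_per_bead <- function(mapping) {
  W <- bead_membership(mapping)
  share <- W / rowSums(W)           # 1 for single-mapped, 0.5 for double
  as.numeric(t(share) %*% mapping$atoms$electrons)
}
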