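# Frames and ensembles: the coordinate containers used throughout.
# All coordinates are in nm; file readers convert Angstrom inputs (PDB, XYZ).

#' Create a single coordinate frame
#'
#' A frame holds one set of 3D positions (atoms or beads) in nm, plus an
#' optional orthorhombic box.
#'
#' @param coords numeric matrix with 3 columns (nm).
#' @param box optional numeric vector of 3 box edge lengths (nm).
#' @param names optional character vector of site names.
#' @return an object of class `cg_frame`.
#' @export
cg_frame <- function(coords, box = NULL, names = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(box)) {
    box <- as.double(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive edge lengths (nm)")
  }
  if (!is.null(names)) rownames(coords) <- names
  structure(list(coords = coords, box = box), class = "cg_frame")
}

#' Create an ensemble (ordered sequence of frames)
#'
#' @param frames list of `cg_frame` objects with a constant site count.
#' @return an object of class `cg_ensemble`.
#' @export
cg_ensemble <- function(frames) {
  if (!length(frames)) stop("empty ensemble")
  n <- nrow(frames[[1]]$coords)
  ok <- vapply(frames, function(f) inherits(f, "cg_frame") && nrow(f$coords) == n,
               logical(1))
  if (!all(ok)) stop("all frames must be cg_frame objects with equal site count")
  structure(frames, class = "cg_ensemble")
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("<cg_frame: %d sites%s>\n", nrow(x$coords),
              if (is.null(x$box)) "" else sprintf(", box %.3f x %.3f x %.3f nm",
                                                  x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' @export
print.cg_ensemble <- function(x, ...) {
  cat(sprintf("<cg_ensemble: %d frames x %d sites>\n", length(x),
              nrow(x[[1]]$coords)))
  invisible(x)
}

# Stack an ensemble into an (nframes x nsites x 3) array.
ensemble_array <- function(ens) {
  nf <- length(ens)
  ns <- nrow(ens[[1]]$coords)
  arr <- array(0, c(nf, ns, 3))
  for (i in seq_len(nf)) arr[i, , ] <- ens[[i]]$coords
  arr
}

#' Read GRO coordinate file (single or concatenated multi-frame)
#'
#' Parses the fixed-width GROMACS .gro format (coordinates already in nm).
#' Concatenated frames are returned as a `cg_ensemble`; a single frame as a
#' `cg_frame`.
#'
#' @param path file path.
#' @param multi if `TRUE` always return a `cg_ensemble`.
#' @return `cg_frame` or `cg_ensemble`.
#' @export
read_gro <- function(path, multi = FALSE) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("malformed GRO file: bad atom count at line ", i + 1L)
    at <- lines[(i + 2L):(i + 1L + natoms)]
    x <- as.numeric(substr(at, 21, 28))
    y <- as.numeric(substr(at, 29, 36))
    z <- as.numeric(substr(at, 37, 44))
    nm <- trimws(substr(at, 11, 15))
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])
    box <- if (length(boxline) >= 3 && all(boxline[1:3] > 0)) boxline[1:3] else NULL
    frames[[length(frames) + 1L]] <- cg_frame(cbind(x, y, z), box = box, names = nm)
    i <- i + 3L + natoms
  }
  if (length(frames) == 1L && !multi) frames[[1]] else cg_ensemble(frames)
}

#' Write GRO coordinate file
#'
#' @param x a `cg_frame` or `cg_ensemble`.
#' @param path output path.
#' @param names site names (recycled per frame); defaults to rownames or "X".
#' @param resname residue name stamped on every site.
#' @param title title line.
#' @export
write_gro <- function(x, path, names = NULL, resname = "MOL", title = "cgparam") {
  frames <- if (inherits(x, "cg_frame")) list(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$coords)
    nm <- names %||% rownames(f$coords) %||% sprintf("X%d", seq_len(n))
    box <- f$box %||% c(0, 0, 0)
    writeLines(title, con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       1L, resname, substr(nm, 1, 5), seq_len(n) %% 100000L,
                       f$coords[, 1], f$coords[, 2], f$coords[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

#' Read XYZ file (single or multi-frame) as an ensemble
#'
#' Plain XYZ with coordinates in Angstrom; converted to nm on read.
#'
#' @param path file path.
#' @param multi if `TRUE` always return a `cg_ensemble`.
#' @return `cg_frame` or `cg_ensemble`.
#' @export
read_xyz <- function(path, multi = FALSE) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ file at line ", i)
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    el <- vapply(rec, `[`, character(1), 1L)
    xyz <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3))) / 10
    frames[[length(frames) + 1L]] <- cg_frame(xyz, names = el)
    i <- i + 2L + n
  }
  if (length(frames) == 1L && !multi) frames[[1]] else cg_ensemble(frames)
}

#' Read a single-frame PDB file
#'
#' Coordinate parsing is delegated to [bio3d::read.pdb()]; Angstrom
#' coordinates are converted to nm and CRYST1 box edges, when present, are
#' carried over.
#'
#' @param path file path.
#' @return a `cg_frame`.
#' @export
read_pdb_frame <- function(path) {
  pdb <- bio3d::read.pdb(path)
  xyz <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z) / 10
  box <- NULL
  cry <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cry)) {
    edges <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                          substr(cry[1], 25, 33))) / 10
    if (all(is.finite(edges)) && all(edges > 0)) box <- edges
  }
  cg_frame(xyz, box = box, names = trimws(pdb$atom$elety))
}

#' Read a coordinate file by extension
#'
#' Dispatches on file extension: `.gro`, `.pdb`, `.xyz`.
#'
#' @param path file path.
#' @param multi if `TRUE` return an ensemble even for one frame.
#' @return `cg_frame` or `cg_ensemble`.
#' @export
read_frame <- function(path, multi = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gro = read_gro(path, multi = multi),
         pdb = read_pdb_frame(path),
         xyz = read_xyz(path, multi = multi),
         stop("unsupported coordinate format: .", ext))
}
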