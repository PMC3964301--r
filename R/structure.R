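## The `aastructure` container: one selected chain of an (all-atom or
## Calpha-only) structure, as an atom table ordered by residue. PDB parsing
## and writing are delegated to bio3d.

#' Construct an all-atom structure object
#'
#' @param atoms Data frame with columns `res_index` (1-based residue ordinal,
#'   non-decreasing), `res_name` (three-letter code), `res_seq` (author residue
#'   number, kept for reports only), `atom_name`, `element`, `x`, `y`, `z`
#'   (Angstrom).
#' @param chain Single chain identifier.
#' @return An object of class `aastructure`.
#' @export
aastructure <- function(atoms, chain = "A") {
  req <- c("res_index", "res_name", "res_seq", "atom_name", "element",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[req]
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (is.unsorted(atoms$res_index)) {
    stop("atoms must be ordered by residue index")
  }
  res_ids <- unique(atoms$res_index)
  if (any(diff(res_ids) <= 0)) stop("residue indices must be strictly increasing")
  ca_per_res <- tapply(atoms$atom_name == "CA", atoms$res_index, any)
  if (!all(ca_per_res)) {
    bad <- res_ids[!ca_per_res]
    bad_names <- atoms$res_name[match(bad, atoms$res_index)]
    stop("residue(s) lacking a CA atom: ",
         paste(sprintf("%s%d", bad_names, bad), collapse = ", "), call. = FALSE)
  }
  structure(list(atoms = atoms, chain = chain), class = "aastructure")
}

#' @export
print.aastructure <- function(x, ...) {
  cat(sprintf("aastructure: %d residues, %d atoms, chain %s\n",
              n_residues(x), nrow(x$atoms), x$chain))
  invisible(x)
}

#' Number of residues in a structure
#' @param x An `aastructure`.
#' @return Integer residue count.
#' @export
n_residues <- function(x) {
  stopifnot(inherits(x, "aastructure"))
  length(unique(x$atoms$res_index))
}

#' Residue names in sequence order
#' @param x An `aastructure`.
#' @return Character vector of three-letter codes, one per residue.
#' @export
residue_names <- function(x) {
  stopifnot(inherits(x, "aastructure"))
  idx <- !duplicated(x$atoms$res_index)
  x$atoms$res_name[idx]
}

#' Calpha coordinates of a structure
#' @param x An `aastructure`.
#' @return N x 3 numeric matrix of Calpha positions in Angstrom, sequence order.
#' @export
calpha_coords <- function(x) {
  stopifnot(inherits(x, "aastructure"))
  ca <- x$atoms[x$atoms$atom_name == "CA", ]
  ca <- ca[!duplicated(ca$res_index), ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Read a single chain of a PDB file
#'
#' Parses a PDB file (through bio3d), keeps standard `ATOM` records of one
#' chain, drops hetero/solvent records, and orders atoms by residue. Every
#' residue must carry a Calpha atom.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier to select; `NULL` (default) takes the first
#'   chain present.
#' @return An [aastructure()].
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  .check_pdb_records(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain, " in ", path)
  # order by author residue number + insertion code, then assign ordinals
  ins <- ifelse(is.na(at$insert), "", at$insert)
  res_key <- paste(formatC(at$resno, width = 8, flag = "0"), ins)
  ord <- order(match(res_key, unique(res_key)))
  at <- at[ord, , drop = FALSE]
  res_key <- res_key[ord]
  res_index <- match(res_key, unique(res_key))
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(at$elety), 1L, 1L)
  }
  aastructure(
    data.frame(
      res_index = res_index,
      res_name  = toupper(trimws(at$resid)),
      res_seq   = at$resno,
      atom_name = trimws(at$elety),
      element   = trimws(elem),
      x = at$x, y = at$y, z = at$z,
      stringsAsFactors = FALSE
    ),
    chain = chain
  )
}

# Minimal record validation so a malformed coordinate line is reported with
# its line number rather than failing deep inside the parser.
.check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  coord <- which(rec %in% c("ATOM  ", "HETATM"))
  for (ln in coord) {
    fields <- c(substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
                substr(lines[ln], 47, 54))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("unparsable coordinate record at line %d of %s", ln, path),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a structure to a PDB file
#'
#' @param x An [aastructure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "aastructure"))
  at <- x$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file  = path,
    xyz   = xyz,
    type  = rep("ATOM", nrow(at)),
    resno = at$res_index,
    resid = at$res_name,
    eleno = seq_len(nrow(at)),
    elety = at$atom_name,
    chain = rep(x$chain, nrow(at))
  )
  invisible(path)
}
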