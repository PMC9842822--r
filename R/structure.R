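#' Peptide structure container
#'
#' A `helix_structure` holds an ordered atom table for a capped
#' poly-alanine chain (ACE-(Ala)n-NME) or one of its model variants. Atom
#' order is chain order; residues are indexed 0-based with ACE = 0 and
#' NME = n + 1.
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `resid`
#'   (integer), `resname`, `x`, `y`, `z` (Angstrom).
#' @param label character label, e.g. `"WH_alpha-5"`.
#' @param helix_class one of `"alpha"`, `"three_ten"`, `"none"`.
#' @param check validate atom clash / element consistency (default TRUE).
#' @return An object of class `helix_structure`.
#' @export
helix_structure <- function(atoms, label = "", helix_class = "none", check = TRUE) {
  helix_class <- match.arg(helix_class, c("alpha", "three_ten", "none"))
  need <- c("atom_name", "element", "resid", "resname", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  atoms <- as.data.frame(atoms)[, need]
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  s <- structure(list(atoms = atoms, label = label, helix_class = helix_class),
                 class = "helix_structure")
  if (check) validate_structure(s)
  s
}

validate_structure <- function(s) {
  at <- s$atoms
  guessed <- ifelse(grepl("^[0-9]*H", at$atom_name), "H",
                    substr(sub("^[0-9]+", "", at$atom_name), 1, 1))
  bad <- which(guessed != at$element)
  if (length(bad))
    stop("element inconsistent with atom name for atom(s) ",
         paste(at$atom_name[bad], collapse = ", "), call. = FALSE)
  if (nrow(at) > 1) {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    if (min(d) < 0.5)
      stop("atoms closer than 0.5 Angstrom: clash in structure '", s$label, "'",
           call. = FALSE)
  }
  invisible(s)
}

#' @export
print.helix_structure <- function(x, ...) {
  cat(sprintf("<helix_structure> %s  class=%s  %d atoms, residues %d..%d\n",
              x$label, x$helix_class, nrow(x$atoms),
              min(x$atoms$resid), max(x$atoms$resid)))
  invisible(x)
}

#' @export
as.data.frame.helix_structure <- function(x, ...) x$atoms

n_atoms <- function(s) nrow(s$atoms)

atom_xyz <- function(s, i) as.numeric(s$atoms[i, c("x", "y", "z")])

xyz_matrix <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

## Resolve "resid:atom_name" (or an integer row index) to a row index.
resolve_atom <- function(structure, ref) {
  if (is.numeric(ref)) {
    i <- as.integer(ref)
    if (i < 1 || i > n_atoms(structure))
      stop("reference error: atom index out of range", call. = FALSE)
    return(i)
  }
  parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("reference error: atom reference must be 'resid:name'", call. = FALSE)
  i <- which(structure$atoms$resid == as.integer(parts[1]) &
             structure$atoms$atom_name == parts[2])
  if (length(i) != 1)
    stop("reference error: no unique atom ", ref, " in '", structure$label, "'",
         call. = FALSE)
  i
}

## Number of alanine residues of a chain model.
chain_n <- function(s) sum(s$atoms$resname == "ALA" & s$atoms$atom_name == "CA")

#' Write a structure to a PDB file
#'
#' Serializes through the standard fixed-column PDB v3 ATOM records
#' (coordinates to 3 decimals) using bio3d.
#'
#' @param structure a `helix_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(structure, file) {
  at <- structure$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = round(xyz, 3),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resid, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$atom_name,
                   chain = rep("A", nrow(at)),
                   elesy = at$element)
  invisible(file)
}

#' Read a structure from a PDB file
#'
#' @param file PDB path.
#' @param label,helix_class metadata to attach (PDB files do not carry them).
#' @return A `helix_structure`.
#' @export
read_pdb <- function(file, label = basename(file), helix_class = "none") {
  lines <- readLines(file)
  rec <- grepl("^ATOM  |^HETATM", lines)
  short <- which(rec & nchar(lines) < 54)
  if (length(short))
    stop("parse error: truncated ATOM record at line ", short[1], call. = FALSE)
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  if (any(is.na(at$x) | is.na(at$y) | is.na(at$z)))
    stop("parse error: missing coordinates in ", file, call. = FALSE)
  el <- trimws(at$elesy)
  miss <- is.na(el) | el == ""
  el[miss] <- ifelse(grepl("^[0-9]*H", trimws(at$elety[miss])), "H",
                     substr(trimws(at$elety[miss]), 1, 1))
  helix_structure(
    data.frame(atom_name = trimws(at$elety), element = el,
               resid = at$resno, resname = trimws(at$resid),
               x = at$x, y = at$y, z = at$z,
               stringsAsFactors = FALSE),
    label = label, helix_class = helix_class)
}
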