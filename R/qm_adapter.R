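## Text adapter for an external quantum-chemistry engine. The engine is
## never invoked here: the package writes input decks and parses output
## documents and cube grids produced elsewhere.

HARTREE_TO_KCAL <- 627.5095
BOHR_PER_ANGSTROM <- 1 / 0.52917721092

#' Quantum-chemistry job specification
#'
#' @param method exchange-correlation method label; default the
#'   dispersion-corrected functional used for the helix energetics.
#' @param basis basis-set label.
#' @param task `"single_point"` or `"constrained_optimization"`.
#' @param frozen_dihedrals list of integer length-4 atom-index vectors to
#'   freeze; required (non-empty) for a constrained optimization.
#' @return Object of class `qm_job_spec`.
#' @export
qm_job_spec <- function(method = "B97D", basis = "6-31+G(d)",
                        task = c("single_point", "constrained_optimization"),
                        frozen_dihedrals = list()) {
  task <- match.arg(task)
  if (task == "constrained_optimization" && !length(frozen_dihedrals))
    stop("constrained optimization requires a non-empty frozen dihedral list",
         call. = FALSE)
  structure(list(method = method, basis = basis, task = task,
                 frozen_dihedrals = frozen_dihedrals),
            class = "qm_job_spec")
}

#' All backbone phi/psi dihedral atom quadruples of a chain model
#'
#' Convenience for constrained optimizations that freeze the backbone
#' torsions at their ideal values.
#'
#' @param structure a helix chain model.
#' @return List of integer length-4 atom-index vectors.
#' @export
backbone_dihedrals <- function(structure) {
  n <- chain_n(structure)
  out <- list()
  for (i in seq_len(n)) {
    cm1 <- resolve_atom(structure, sprintf("%d:C", i - 1))
    Ni <- resolve_atom(structure, sprintf("%d:N", i))
    CAi <- resolve_atom(structure, sprintf("%d:CA", i))
    Ci <- resolve_atom(structure, sprintf("%d:C", i))
    Nn <- resolve_atom(structure, sprintf("%d:N", i + 1))
    out <- c(out, list(c(cm1, Ni, CAi, Ci), c(Ni, CAi, Ci, Nn)))
  }
  out
}

#' Write an input deck for the external engine
#'
#' Gaussian-style free-format input: route line with method/basis and, for
#' constrained optimizations, modredundant dihedral-freeze directives;
#' coordinates in Angstrom, one line per atom.
#'
#' @param structure a `helix_structure`.
#' @param job a `qm_job_spec`.
#' @param file optional path; if NULL the text is returned invisibly.
#' @return Character vector of input lines.
#' @export
write_qm_input <- function(structure, job = qm_job_spec(), file = NULL) {
  if (n_atoms(structure) == 0) stop("empty structure", call. = FALSE)
  route <- sprintf("#P %s/%s%s", job$method, job$basis,
                   if (job$task == "constrained_optimization")
                     " Opt=ModRedundant" else "")
  at <- structure$atoms
  coords <- sprintf(" %-2s  %14.8f %14.8f %14.8f", at$element, at$x, at$y, at$z)
  lines <- c(route, "", structure$label, "", "0 1", coords, "")
  if (job$task == "constrained_optimization") {
    frz <- vapply(job$frozen_dihedrals,
                  function(d) sprintf("D %d %d %d %d F", d[1], d[2], d[3], d[4]),
                  character(1))
    lines <- c(lines, frz, "")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Parse the final total electronic energy from an engine output
#'
#' Extracts the last `SCF Done:  E(...) = <value>` marker (hartree) and
#' converts to kcal/mol at 627.5095 kcal/mol per hartree.
#'
#' @param text character vector of output lines, or a file path.
#' @return `energy_value` (kcal/mol, provenance `"qm"`).
#' @export
parse_qm_total_energy <- function(text) {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text)
  hits <- regmatches(text, regexpr(
    "SCF Done:\\s+E\\([^)]*\\)\\s*=\\s*(-?[0-9]*\\.?[0-9]+([DdEe][-+]?[0-9]+)?)",
    text))
  if (!length(hits))
    stop("parse error: no 'SCF Done' energy marker found", call. = FALSE)
  val <- sub(".*=\\s*", "", hits[length(hits)])
  hartree <- as.numeric(gsub("[Dd]", "e", val))
  energy_value(hartree * HARTREE_TO_KCAL, "qm")
}

#' Read a Gaussian cube file
#'
#' Follows the cube conventions: two comment lines; atom count and origin;
#' three axis records (count and step vector, Bohr); atom records; then
#' values with the z index varying fastest.
#'
#' @param file cube path.
#' @return A `volumetric_grid`.
#' @export
read_cube <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 6) stop("parse error: cube header truncated", call. = FALSE)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr <- num(lines[3])
  natoms <- as.integer(hdr[1]); origin <- hdr[2:4]
  counts <- integer(3); axes <- matrix(0, 3, 3)
  for (k in 1:3) {
    v <- num(lines[3 + k])
    counts[k] <- as.integer(v[1]); axes[k, ] <- v[2:4]
  }
  atoms <- NULL
  if (natoms > 0) {
    rec <- t(vapply(lines[7:(6 + natoms)], num, numeric(5), USE.NAMES = FALSE))
    atoms <- data.frame(Z = as.integer(rec[, 1]), charge = rec[, 2],
                        x = rec[, 3], y = rec[, 4], z = rec[, 5])
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[(7 + natoms):length(lines)]),
                                     "\\s+")))
  if (length(vals) != prod(counts))
    stop("parse error: expected ", prod(counts), " grid values, found ",
         length(vals), call. = FALSE)
  volumetric_grid(origin, axes, counts, vals, atoms = atoms)
}

#' Write a Gaussian cube file
#'
#' @param grid a `volumetric_grid`.
#' @param file output path.
#' @param comment two header comment lines.
#' @return `file`, invisibly.
#' @export
write_cube <- function(grid, file, comment = c("helixhb volumetric grid",
                                               "density (e/Bohr^3)")) {
  atoms <- grid$atoms
  if (is.null(atoms))
    atoms <- data.frame(Z = 1L, charge = 0, x = 0, y = 0, z = 0)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(comment[1:2], con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nrow(atoms),
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  for (k in 1:3)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$counts[k],
                       grid$axes[k, 1], grid$axes[k, 2], grid$axes[k, 3]), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", atoms$Z, atoms$charge,
                     atoms$x, atoms$y, atoms$z), con)
  ## z-fastest ordering, six values per record
  v <- as.numeric(aperm(grid$values, 3:1))
  idx <- split(seq_along(v), ceiling(seq_along(v) / 6))
  writeLines(vapply(idx, function(ii) paste(sprintf("%13.5E", v[ii]),
                                            collapse = " "), character(1)), con)
  invisible(file)
}
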