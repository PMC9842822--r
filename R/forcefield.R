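#' Nonbonded force-field parameters
#'
#' Per-atom-class partial charges (elementary charge units) and
#' Lennard-Jones parameters (R_min/2 in Angstrom, epsilon in kcal/mol)
#' in the AMBER ff99SB family, with Lorentz-Berthelot-style combination
#' producing A_ij = eps_ij R_min,ij^12 and B_ij = 2 eps_ij R_min,ij^6
#' (R_min,ij = R_i + R_j, eps_ij = sqrt(eps_i eps_j)). The four backbone
#' charges default to q_N0 = -0.4157, q_H0 = 0.2719, q_C0 = 0.5973,
#' q_O0 = -0.5679.
#'
#' @param q_N,q_H,q_C,q_O backbone partial charges (e).
#' @param coulomb_constant electrostatic conversion constant in
#'   kcal Angstrom / (mol e^2); 332.0637 makes q q'/r an energy in
#'   kcal/mol for charges in e and distances in Angstrom.
#' @return An object of class `ff_params`: list with `charges` (named,
#'   keyed `RESNAME:ATOM`), `lj` (data.frame type/rmin2/eps), `type_of`
#'   (named map from `RESNAME:ATOM` to LJ type) and `coulomb_constant`.
#' @export
ff_params <- function(q_N = -0.4157, q_H = 0.2719, q_C = 0.5973, q_O = -0.5679,
                      coulomb_constant = 332.0637) {
  stopifnot(is.finite(c(q_N, q_H, q_C, q_O, coulomb_constant)))
  charges <- c(
    "ALA:N" = q_N, "ALA:H" = q_H, "ALA:C" = q_C, "ALA:O" = q_O,
    "ALA:CA" = 0.0337, "ALA:HA" = 0.0823, "ALA:CB" = -0.1825, "ALA:HB" = 0.0603,
    "ACE:C" = q_C, "ACE:O" = q_O, "ACE:CH3" = -0.3662, "ACE:HH" = 0.1123,
    "NME:N" = q_N, "NME:H" = q_H, "NME:CH3" = -0.1490, "NME:HH" = 0.0976,
    "NMA:C" = q_C, "NMA:O" = q_O, "NMA:N" = q_N, "NMA:H" = q_H,
    "NMA:CH3" = -0.3662, "NMA:HH" = 0.1123, "NMA:CN" = -0.1490,
    "NMA:HN" = 0.0976,
    "ANY:HV" = 0.0)
  lj <- data.frame(
    type = c("N", "H", "C", "O", "CT", "H1", "HC"),
    rmin2 = c(1.8240, 0.6000, 1.9080, 1.6612, 1.9080, 1.3870, 1.4870),
    eps = c(0.1700, 0.0157, 0.0860, 0.2100, 0.1094, 0.0157, 0.0157),
    stringsAsFactors = FALSE)
  type_of <- c(
    "ALA:N" = "N", "ALA:H" = "H", "ALA:C" = "C", "ALA:O" = "O",
    "ALA:CA" = "CT", "ALA:HA" = "H1", "ALA:CB" = "CT", "ALA:HB" = "HC",
    "ACE:C" = "C", "ACE:O" = "O", "ACE:CH3" = "CT", "ACE:HH" = "HC",
    "NME:N" = "N", "NME:H" = "H", "NME:CH3" = "CT", "NME:HH" = "H1",
    "NMA:C" = "C", "NMA:O" = "O", "NMA:N" = "N", "NMA:H" = "H",
    "NMA:CH3" = "CT", "NMA:HH" = "HC", "NMA:CN" = "CT", "NMA:HN" = "H1",
    "ANY:HV" = "HC")
  structure(list(charges = charges, lj = lj, type_of = type_of,
                 coulomb_constant = coulomb_constant,
                 q0 = c(N = q_N, H = q_H, C = q_C, O = q_O)),
            class = "ff_params")
}

## Canonical parameter key for one atom: strips methyl-H numbering and
## maps cap hydrogens (HV*) to a shared class.
atom_key <- function(resname, atom_name) {
  if (grepl("^HV", atom_name)) return("ANY:HV")
  base <- if (grepl("^H", atom_name)) sub("[0-9]+$", "", atom_name) else atom_name
  paste0(resname, ":", base)
}

atom_charges <- function(structure, params) {
  keys <- mapply(atom_key, structure$atoms$resname, structure$atoms$atom_name)
  q <- unname(params$charges[keys])
  if (anyNA(q))
    stop("reference error: no charge for atom class(es) ",
         paste(unique(keys[is.na(q)]), collapse = ", "), call. = FALSE)
  q
}

atom_lj <- function(structure, params) {
  keys <- mapply(atom_key, structure$atoms$resname, structure$atoms$atom_name)
  types <- unname(params$type_of[keys])
  if (anyNA(types))
    stop("reference error: no LJ type for atom class(es) ",
         paste(unique(keys[is.na(types)]), collapse = ", "), call. = FALSE)
  i <- match(types, params$lj$type)
  list(rmin2 = params$lj$rmin2[i], eps = params$lj$eps[i])
}

## A_ij, B_ij for vectors of per-atom LJ parameters.
lj_ab <- function(rmin2_i, eps_i, rmin2_j, eps_j) {
  rmin <- rmin2_i + rmin2_j
  eps <- sqrt(eps_i * eps_j)
  list(A = eps * rmin^12, B = 2 * eps * rmin^6)
}
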