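#' Energy value with provenance
#'
#' A plain numeric (kcal/mol) carrying a `provenance` attribute, one of
#' `"mm"`, `"mm_modified"`, `"qm"`, `"toy"`.
#'
#' @param value numeric, kcal/mol; must be finite.
#' @param provenance character tag.
#' @return Numeric of class `energy_value`.
#' @export
energy_value <- function(value, provenance = c("mm", "mm_modified", "qm", "toy")) {
  provenance <- match.arg(provenance)
  if (!is.finite(value)) stop("numeric error: non-finite energy", call. = FALSE)
  structure(as.numeric(value), class = "energy_value", provenance = provenance)
}

#' @export
print.energy_value <- function(x, ...) {
  cat(sprintf("%.6f kcal/mol [%s]\n", unclass(x), attr(x, "provenance")))
  invisible(x)
}

## 4x4 matrix of distances between two sets of atom indices.
pair_distances <- function(structure, idx_a, idx_b) {
  xyz <- xyz_matrix(structure)
  outer(idx_a, idx_b, Vectorize(function(i, j) vnorm(xyz[i, ] - xyz[j, ])))
}

unit_indices <- function(structure, unit)
  vapply(unit[c("C", "O", "N", "H")], function(r) resolve_atom(structure, r),
         numeric(1))

#' Classical hydrogen-bond energy of one backbone H-bond
#'
#' Sums, over the 16 ordered atom pairs between the acceptor peptide unit
#' \{C, O, N, H\} and the donor unit \{C, O, N, H\}, the vacuum Coulomb
#' term k q_i q_j / r_ij and the Lennard-Jones term
#' A_ij / r_ij^12 - B_ij / r_ij^6, with no cutoff, scaling or screening.
#'
#' @param structure a `helix_structure` containing the eight unit atoms.
#' @param hbond an `hbond_pair` (or n-s label resolvable in `structure`).
#' @param params `ff_params`.
#' @param charges optional full per-atom charge vector overriding the
#'   parameter-table charges (used by the polarized-charge model).
#' @return `energy_value` in kcal/mol.
#' @export
mm_hbond_energy <- function(structure, hbond, params = ff_params(),
                            charges = NULL) {
  if (is.character(hbond)) hbond <- find_hbond(structure, hbond)
  ia <- unit_indices(structure, hbond$acceptor_unit)
  id <- unit_indices(structure, hbond$donor_unit)
  r <- pair_distances(structure, ia, id)
  if (any(r < 0.1)) stop("geometry error: overlapping atoms", call. = FALSE)
  q <- if (is.null(charges)) atom_charges(structure, params) else charges
  lj <- atom_lj(structure, params)
  ab <- lj_ab(rep(lj$rmin2[ia], times = 4), rep(lj$eps[ia], times = 4),
              rep(lj$rmin2[id], each = 4), rep(lj$eps[id], each = 4))
  coul <- params$coulomb_constant * outer(q[ia], q[id]) / r
  ljm <- matrix(ab$A, 4, 4) / r^12 - matrix(ab$B, 4, 4) / r^6
  prov <- if (is.null(charges)) "mm" else "mm_modified"
  energy_value(sum(coul) + sum(ljm), prov)
}

#' Strictly pairwise-additive total energy (toy oracle backend)
#'
#' Full double sum of the same Coulomb + Lennard-Jones pair potential as
#' [mm_hbond_energy()] over all atom pairs of a subset. Being additive by
#' construction, it serves as the independent oracle for the
#' inclusion-exclusion combination: applied to cap-free fragment subsets,
#' the four-term combination must equal the direct group-group
#' interaction at machine precision.
#'
#' @param structure a `helix_structure`.
#' @param params `ff_params`.
#' @param atom_subset integer atom row indices (default: all atoms).
#' @param charges optional per-atom charge override (full-length vector).
#' @return `energy_value` with provenance `"toy"`.
#' @export
pairwise_total_energy <- function(structure, params = ff_params(),
                                  atom_subset = NULL, charges = NULL) {
  if (is.null(atom_subset)) atom_subset <- seq_len(n_atoms(structure))
  if (any(atom_subset < 1 | atom_subset > n_atoms(structure)))
    stop("reference error: subset outside structure", call. = FALSE)
  m <- length(atom_subset)
  if (m < 2) return(energy_value(0, "toy"))
  q <- (if (is.null(charges)) atom_charges(structure, params) else charges)[atom_subset]
  lj <- atom_lj(structure, params)
  rmin2 <- lj$rmin2[atom_subset]; eps <- lj$eps[atom_subset]
  xyz <- xyz_matrix(structure)[atom_subset, , drop = FALSE]
  ## collect every pair term, then reduce with a single sum(): R
  ## accumulates in extended precision, keeping each member total
  ## accurate to ~1 ulp so that inclusion-exclusion differences of
  ## near-identical totals stay at machine precision
  terms <- vector("list", m - 1)
  for (i in seq_len(m - 1)) {
    j <- (i + 1):m
    dv <- sweep(xyz[j, , drop = FALSE], 2, xyz[i, ], "-")
    r <- sqrt(rowSums(dv^2))
    if (any(r < 0.1)) stop("geometry error: overlapping atoms", call. = FALSE)
    ab <- lj_ab(rmin2[i], eps[i], rmin2[j], eps[j])
    terms[[i]] <- c(params$coulomb_constant * q[i] * q[j] / r,
                    ab$A / r^12, -ab$B / r^6)
  }
  terms <- unlist(terms)
  val <- sum(terms)
  out <- energy_value(val, "toy")
  ## two-double representation: the rounding remainder of the total,
  ## recovered by a second extended-precision pass, lets downstream
  ## inclusion-exclusion cancel the large bonded-pair terms exactly
  attr(out, "residual") <- sum(c(terms, -val))
  out
}

#' Direct acceptor-group/donor-group interaction energy (oracle)
#'
#' The pair-potential interaction between the acceptor C=O atom pair and
#' the donor N-H atom pair only: the quantity the inclusion-exclusion
#' combination must reproduce exactly under an additive backend.
#'
#' @inheritParams mm_hbond_energy
#' @return `energy_value` with provenance `"toy"`.
#' @export
group_interaction_energy <- function(structure, hbond, params = ff_params()) {
  ia <- vapply(hbond$acceptor_unit[c("C", "O")],
               function(r) resolve_atom(structure, r), numeric(1))
  id <- vapply(hbond$donor_unit[c("N", "H")],
               function(r) resolve_atom(structure, r), numeric(1))
  q <- atom_charges(structure, params)
  lj <- atom_lj(structure, params)
  xyz <- xyz_matrix(structure)
  e <- 0
  for (i in ia) for (j in id) {
    r <- vnorm(xyz[i, ] - xyz[j, ])
    ab <- lj_ab(lj$rmin2[i], lj$eps[i], lj$rmin2[j], lj$eps[j])
    e <- e + params$coulomb_constant * q[i] * q[j] / r + ab$A / r^12 - ab$B / r^6
  }
  energy_value(e, "toy")
}
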