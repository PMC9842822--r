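#' Polarization coupling coefficients
#'
#' The four coefficients coupling a peptide group's N-H and C=O charge
#' modifiers to the dipole-dipole interaction energies with its
#' nearest-neighbour groups. With the default electrostatic constant the
#' interaction energies are in kcal/mol, so the coefficients carry units
#' of (kcal/mol)^-1.
#'
#' @param lambda_HO,lambda_HH,lambda_OO,lambda_OH numeric coefficients.
#' @return Named numeric of class `lambda_params`.
#' @export
lambda_params <- function(lambda_HO = 0, lambda_HH = 0,
                          lambda_OO = 0, lambda_OH = 0) {
  l <- c(HO = as.numeric(lambda_HO), HH = as.numeric(lambda_HH),
         OO = as.numeric(lambda_OO), OH = as.numeric(lambda_OH))
  if (!all(is.finite(l))) stop("lambda coefficients must be finite", call. = FALSE)
  structure(l, class = "lambda_params")
}

## Peptide group k of a chain model: C,O of residue k and N,H of residue
## k + 1. Returns NULL when any member atom is absent.
group_atoms <- function(structure, k) {
  refs <- c(C = sprintf("%d:C", k), O = sprintf("%d:O", k),
            N = sprintf("%d:N", k + 1), H = sprintf("%d:H", k + 1))
  idx <- suppressWarnings(tryCatch(
    vapply(refs, function(r) resolve_atom(structure, r), numeric(1)),
    error = function(e) NULL))
  ## peptide groups are defined along a chain; the disconnected
  ## N-methylacetamide pair of an MH model has none
  if (!is.null(idx) && any(structure$atoms$resname[idx] == "NMA")) return(NULL)
  idx
}

## Indices of the peptide groups present in a chain model (0..n for
## ACE-(Ala)n-NME).
group_range <- function(structure) {
  ks <- sort(unique(structure$atoms$resid))
  Filter(function(k) !is.null(group_atoms(structure, k)), ks)
}

#' Local C=O and N-H dipoles of the peptide groups
#'
#' For group k, mu_CO = (q_C - q_O)(r_C - r_O)/2 centred at the C-O
#' midpoint and mu_NH = (q_H - q_N)(r_H - r_N)/2 centred at the H-N
#' midpoint, in e Angstrom, using the supplied (by default the original,
#' unmodified) charges.
#'
#' @param structure a chain model.
#' @param params `ff_params` providing the charges.
#' @return List keyed by group index (as character) of lists with
#'   `group_index`, `mu_CO`, `mu_NH`, `center_CO`, `center_NH`.
#' @export
compute_dipoles <- function(structure, params = ff_params()) {
  q0 <- params$q0
  out <- list()
  for (k in group_range(structure)) {
    idx <- group_atoms(structure, k)
    rC <- atom_xyz(structure, idx[["C"]]); rO <- atom_xyz(structure, idx[["O"]])
    rN <- atom_xyz(structure, idx[["N"]]); rH <- atom_xyz(structure, idx[["H"]])
    out[[as.character(k)]] <- list(
      group_index = k,
      mu_CO = 0.5 * (q0[["C"]] - q0[["O"]]) * (rC - rO),
      mu_NH = 0.5 * (q0[["H"]] - q0[["N"]]) * (rH - rN),
      center_CO = (rC + rO) / 2,
      center_NH = (rH + rN) / 2)
  }
  out
}

#' Dipole-dipole interaction energy
#'
#' U = kappa [ mu1.mu2 / r^3 - 3 (mu1.r)(mu2.r) / r^5 ] with r the
#' center-to-center vector. With dipoles in e Angstrom, centres in
#' Angstrom and kappa = 332.0637 kcal Angstrom/(mol e^2), U is in
#' kcal/mol; kappa = 1 gives the bare e^2/Angstrom^3 convention.
#'
#' @param mu1,mu2 length-3 dipole vectors (e Angstrom).
#' @param c1,c2 length-3 centres (Angstrom).
#' @param kappa electrostatic constant.
#' @return Numeric energy.
#' @export
dipole_interaction <- function(mu1, c1, mu2, c2, kappa = 332.0637) {
  r <- c2 - c1
  rn <- vnorm(r)
  if (rn < 1e-9) stop("geometry error: coincident dipole centres", call. = FALSE)
  kappa * (sum(mu1 * mu2) / rn^3 - 3 * sum(mu1 * r) * sum(mu2 * r) / rn^5)
}

#' Fractional charge modifiers from neighbour dipole couplings
#'
#' For each peptide group i, delta_H^i = lambda_HO U(mu_NH^i, mu_CO^{i-1})
#' + lambda_HH U(mu_NH^i, mu_NH^{i-1}) and delta_O^i = lambda_OO
#' U(mu_CO^i, mu_CO^{i+1}) + lambda_OH U(mu_CO^i, mu_NH^{i+1}); only the
#' nearest-neighbour groups contribute and terms whose neighbour does not
#' exist (chain termini) vanish. delta_N and delta_C follow from the local
#' neutrality constraints delta_N q_N0 = -delta_H q_H0 and delta_C q_C0 =
#' -delta_O q_O0, so every group's total charge is conserved exactly. The
#' dipoles entering U are computed from the original charges (one-shot
#' correction, no self-consistency).
#'
#' @param structure a chain model.
#' @param lambdas `lambda_params`.
#' @param params `ff_params`.
#' @param kappa electrostatic constant passed to [dipole_interaction()].
#' @return data.frame with columns `group`, `delta_N`, `delta_H`,
#'   `delta_C`, `delta_O`.
#' @export
charge_deltas <- function(structure, lambdas = lambda_params(),
                          params = ff_params(), kappa = 332.0637) {
  dip <- compute_dipoles(structure, params)
  ks <- vapply(dip, `[[`, numeric(1), "group_index")
  q0 <- params$q0
  U <- function(g1, f1, g2, f2) {
    a <- dip[[as.character(g1)]]; b <- dip[[as.character(g2)]]
    if (is.null(a) || is.null(b)) return(0)
    dipole_interaction(a[[paste0("mu_", f1)]], a[[paste0("center_", f1)]],
                       b[[paste0("mu_", f2)]], b[[paste0("center_", f2)]],
                       kappa = kappa)
  }
  rows <- lapply(ks, function(i) {
    dH <- lambdas[["HO"]] * U(i, "NH", i - 1, "CO") +
          lambdas[["HH"]] * U(i, "NH", i - 1, "NH")
    dO <- lambdas[["OO"]] * U(i, "CO", i + 1, "CO") +
          lambdas[["OH"]] * U(i, "CO", i + 1, "NH")
    data.frame(group = i, delta_N = -dH * q0[["H"]] / q0[["N"]], delta_H = dH,
               delta_C = -dO * q0[["O"]] / q0[["C"]], delta_O = dO)
  })
  do.call(rbind, rows)
}

## Full per-atom charge vector with the polarization modifiers applied:
## q_X^i = q_X0 (1 - delta_X^i) for the backbone N, H, C, O; all other
## atoms keep their table charges.
modified_charges <- function(structure, lambdas, params = ff_params(),
                             kappa = 332.0637) {
  q <- atom_charges(structure, params)
  deltas <- charge_deltas(structure, lambdas, params, kappa)
  at <- structure$atoms
  for (r in seq_len(nrow(deltas))) {
    k <- deltas$group[r]
    tweak <- function(resid, name, delta) {
      i <- which(at$resid == resid & at$atom_name == name)
      if (length(i) == 1) q[i] <<- q[i] * (1 - delta)
    }
    tweak(k, "C", deltas$delta_C[r])
    tweak(k, "O", deltas$delta_O[r])
    tweak(k + 1, "N", deltas$delta_N[r])
    tweak(k + 1, "H", deltas$delta_H[r])
  }
  q
}

#' Classical H-bond energy with dipole-polarized charges
#'
#' Evaluates the 16-pair Coulomb + Lennard-Jones H-bond energy with the
#' backbone charges replaced by q_X^i = q_X0 (1 - delta_X^i) in the
#' Coulomb term (the Lennard-Jones term is unchanged). Reduces exactly to
#' [mm_hbond_energy()] when all coefficients are zero.
#'
#' @inheritParams mm_hbond_energy
#' @param lambdas `lambda_params`.
#' @param kappa electrostatic constant for the dipole couplings.
#' @return `energy_value` with provenance `"mm_modified"`.
#' @export
modified_mm_hbond_energy <- function(structure, hbond,
                                     lambdas = lambda_params(),
                                     params = ff_params(), kappa = 332.0637) {
  if (is.character(hbond)) hbond <- find_hbond(structure, hbond)
  q <- modified_charges(structure, lambdas, params, kappa)
  mm_hbond_energy(structure, hbond, params, charges = q)
}
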