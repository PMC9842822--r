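#' Energy quartet for the inclusion-exclusion combination
#'
#' @param sys,noA,noD,noAD total energies (kcal/mol) of the full system,
#'   the system lacking the acceptor group, the system lacking the donor
#'   group, and the system lacking both. `energy_value`s carrying a
#'   summation `residual` attribute (see [pairwise_total_energy()]) keep
#'   it, so the combination can run at extended precision.
#' @return Named numeric of class `energy_quartet`.
#' @export
energy_quartet <- function(sys, noA, noD, noAD) {
  vals <- list(sys, noA, noD, noAD)
  q <- c(sys = as.numeric(sys), noA = as.numeric(noA),
         noD = as.numeric(noD), noAD = as.numeric(noAD))
  if (!all(is.finite(q))) stop("numeric error: non-finite energy in quartet",
                               call. = FALSE)
  res <- vapply(vals, function(v) {
    r <- attr(v, "residual")
    if (is.null(r)) 0 else r
  }, numeric(1))
  structure(q, class = "energy_quartet", residual = stats::setNames(res, names(q)))
}

#' Hydrogen-bond energy by inclusion-exclusion
#'
#' The Negative Fragmentation Approach estimate of one H-bond's energy
#' from four total energies: E_HB = E_sys - E_noA - E_noD + E_noAD.
#'
#' @param q an `energy_quartet` (or any numeric vector with elements
#'   named sys, noA, noD, noAD).
#' @return Numeric, kcal/mol.
#' @export
nfa_energy <- function(q) {
  if (!all(c("sys", "noA", "noD", "noAD") %in% names(q)))
    stop("quartet must have elements sys, noA, noD, noAD", call. = FALSE)
  res <- attr(q, "residual")
  q <- unclass(q)
  if (!all(is.finite(q))) stop("numeric error: non-finite energy in quartet",
                               call. = FALSE)
  sgn <- c(sys = 1, noA = -1, noD = -1, noAD = 1)
  terms <- sgn * q[names(sgn)]
  ## single extended-precision reduction: near-identical totals cancel
  ## without re-rounding, and any carried summation residuals follow
  if (!is.null(res)) terms <- c(terms, sgn * res[names(sgn)])
  unname(sum(terms))
}

#' Toy-backend energy quartet of a fragment set (cap-free oracle mode)
#'
#' Evaluates the strictly additive pair-potential total energy on each
#' member of a fragment quartet with the hydrogen caps excluded from the
#' sum, so that each member's energy is exactly the pairwise sum over a
#' subset of the parent model's atoms. Under this backend the
#' inclusion-exclusion combination equals the direct acceptor-group /
#' donor-group interaction at machine precision.
#'
#' @param frags a `fragment_set`.
#' @param params `ff_params`.
#' @param include_caps include the cap hydrogens in the sums (default
#'   FALSE, the oracle mode).
#' @return An `energy_quartet`.
#' @export
toy_quartet <- function(frags, params = ff_params(), include_caps = FALSE) {
  member_energy <- function(s) {
    subset <- seq_len(n_atoms(s))
    if (!include_caps) subset <- subset[!grepl("^HV", s$atoms$atom_name)]
    pairwise_total_energy(s, params, atom_subset = subset)
  }
  energy_quartet(member_energy(frags$sys), member_energy(frags$noA),
                 member_energy(frags$noD), member_energy(frags$noAD))
}
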