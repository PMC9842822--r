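#' Ideal-helix specification
#'
#' Bundles the backbone torsions and the covalent geometry used to build an
#' ideal capped poly-alanine helix. Defaults follow the textbook ideal
#' torsions: phi/psi = (-57, -47) degrees for the alpha-helix and
#' (-49, -26) degrees for the 3-10-helix, with a planar trans peptide bond
#' (omega = 180 degrees).
#'
#' @param helix_class `"alpha"` or `"three_ten"`.
#' @param phi,psi,omega backbone torsions in degrees; defaults set by
#'   `helix_class`.
#' @param bond_table named list overriding any of the standard bond lengths
#'   (Angstrom) and angles (degrees); see `default_bond_table()`.
#' @return An object of class `helix_spec`.
#' @export
helix_spec <- function(helix_class = c("alpha", "three_ten"),
                       phi = NULL, psi = NULL, omega = 180,
                       bond_table = list()) {
  helix_class <- match.arg(helix_class)
  ideal <- switch(helix_class,
                  alpha = c(phi = -57, psi = -47),
                  three_ten = c(phi = -49, psi = -26))
  if (is.null(phi)) phi <- ideal[["phi"]]
  if (is.null(psi)) psi <- ideal[["psi"]]
  bt <- utils::modifyList(default_bond_table(), as.list(bond_table))
  lens <- unlist(bt[grep("^len_", names(bt))])
  angs <- unlist(bt[grep("^ang_", names(bt))])
  if (any(lens <= 0)) stop("bond lengths must be positive", call. = FALSE)
  if (any(angs <= 0 | angs >= 180)) stop("angles must lie in (0, 180)", call. = FALSE)
  structure(list(helix_class = helix_class, phi = phi, psi = psi,
                 omega = omega, bond_table = bt),
            class = "helix_spec")
}

#' Standard covalent geometry of the peptide backbone
#'
#' Bond lengths in Angstrom (`len_*`) and angles in degrees (`ang_*`).
#' Carbonyl oxygens and amide hydrogens are placed by in-plane trigonal
#' geometry; side-chain placement uses the L-alanine improper torsions
#' measured relative to the N-C-CA frame.
#'
#' @return Named list of geometry parameters.
#' @export
default_bond_table <- function() {
  list(
    len_n_ca = 1.458, len_ca_c = 1.525, len_c_n = 1.329,
    len_c_o = 1.231, len_n_h = 1.010, len_c_h = 1.090,
    len_ca_cb = 1.521,
    ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
    ang_c_ca_cb = 110.5, ang_c_ca_ha = 108.5, ang_methyl_h = 109.5,
    tor_cb = -122.7, tor_ha = 117.0
  )
}

#' Build an ideal whole-helix (WH) model
#'
#' Constructs ACE-(Ala)n-NME with every backbone phi/psi set to the
#' specification's values and omega trans, by sequential internal-to-
#' Cartesian placement (the first three backbone atoms span the canonical
#' frame: origin, x-axis, xy-plane). The acetyl cap contributes a C=O
#' (residue 0) and the N-methyl cap an N-H (residue n + 1), so both are
#' eligible hydrogen-bond partners. Deterministic.
#'
#' @param n number of alanine residues (>= 1).
#' @param spec a `helix_spec`; default alpha.
#' @return A `helix_structure` labelled `WH_<class>-<n>`.
#' @export
#' @examples
#' wh <- build_wh_model(5)
#' measure_dihedral(wh, "0:C", "1:N", "1:CA", "1:C")  # phi = -57
build_wh_model <- function(n, spec = helix_spec("alpha")) {
  if (!inherits(spec, "helix_spec")) stop("spec must be a helix_spec", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("invalid size: n must be an integer >= 1", call. = FALSE)
  n <- as.integer(n)
  bt <- spec$bond_table
  phi <- spec$phi; psi <- spec$psi; omega <- spec$omega

  ## backbone trace: CH3(ACE), C(ACE), N_1, CA_1, C_1, N_2, ..., C_n, N_nme, CH3(NME)
  CH3a <- c(0, 0, 0)
  Ca   <- c(bt$len_ca_c, 0, 0)
  th <- deg2rad(bt$ang_ca_c_n)
  N <- CA <- C <- vector("list", n + 1)
  N[[1]] <- Ca + bt$len_c_n * c(-cos(th), sin(th), 0)

  prevCA <- CH3a; prevC <- Ca
  for (i in seq_len(n)) {
    CA[[i]] <- place_atom(prevCA, prevC, N[[i]],
                          bt$len_n_ca, bt$ang_c_n_ca, omega)
    C[[i]] <- place_atom(prevC, N[[i]], CA[[i]],
                         bt$len_ca_c, bt$ang_n_ca_c, phi)
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                             bt$len_c_n, bt$ang_ca_c_n, psi)
    prevCA <- CA[[i]]; prevC <- C[[i]]
  }
  CH3n <- place_atom(CA[[n]], C[[n]], N[[n + 1]],
                     bt$len_n_ca, bt$ang_c_n_ca, omega)

  rows <- list()
  add <- function(name, el, resid, resname, pos) {
    rows[[length(rows) + 1]] <<- data.frame(
      atom_name = name, element = el, resid = resid, resname = resname,
      x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
  }
  methyl_h <- function(a, b, c, names, resid, resname) {
    for (k in seq_along(names))
      add(names[k], "H", resid, resname,
          place_atom(a, b, c, bt$len_c_h, bt$ang_methyl_h, 60 + 120 * (k - 1)))
  }

  ## ACE (residue 0)
  add("CH3", "C", 0L, "ACE", CH3a)
  methyl_h(N[[1]], Ca, CH3a, c("HH31", "HH32", "HH33"), 0L, "ACE")
  add("C", "C", 0L, "ACE", Ca)
  add("O", "O", 0L, "ACE", place_trigonal(Ca, CH3a, N[[1]], bt$len_c_o))

  ## Ala 1..n
  for (i in seq_len(n)) {
    pC <- if (i == 1) Ca else C[[i - 1]]
    add("N", "N", i, "ALA", N[[i]])
    add("H", "H", i, "ALA", place_trigonal(N[[i]], pC, CA[[i]], bt$len_n_h))
    add("CA", "C", i, "ALA", CA[[i]])
    add("HA", "H", i, "ALA",
        place_atom(N[[i]], C[[i]], CA[[i]], bt$len_c_h, bt$ang_c_ca_ha, bt$tor_ha))
    CB <- place_atom(N[[i]], C[[i]], CA[[i]], bt$len_ca_cb, bt$ang_c_ca_cb, bt$tor_cb)
    add("CB", "C", i, "ALA", CB)
    methyl_h(N[[i]], CA[[i]], CB, c("HB1", "HB2", "HB3"), i, "ALA")
    add("C", "C", i, "ALA", C[[i]])
    add("O", "O", i, "ALA", place_trigonal(C[[i]], CA[[i]], N[[i + 1]], bt$len_c_o))
  }

  ## NME (residue n + 1)
  add("N", "N", n + 1L, "NME", N[[n + 1]])
  add("H", "H", n + 1L, "NME", place_trigonal(N[[n + 1]], C[[n]], CH3n, bt$len_n_h))
  add("CH3", "C", n + 1L, "NME", CH3n)
  methyl_h(C[[n]], N[[n + 1]], CH3n, c("HH31", "HH32", "HH33"), n + 1L, "NME")

  cls <- if (spec$helix_class == "alpha") "alpha" else "3_10"
  helix_structure(do.call(rbind, rows),
                  label = sprintf("WH_%s-%d", cls, n),
                  helix_class = spec$helix_class)
}
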