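## Simplified-model derivation and NFA fragment generation. All retained
## atoms keep the parent coordinates bit-for-bit; only cap/methyl
## hydrogens are newly built.

atom_row <- function(s, ref) s$atoms[resolve_atom(s, ref), , drop = FALSE]

## Build three staggered methyl hydrogens on carbon `c`, bonded towards
## `b`, with torsion reference `a`; returns a 3-row data.frame.
methyl_h_rows <- function(a, b, c, resid, resname, names, len = 1.090) {
  do.call(rbind, lapply(seq_along(names), function(k) {
    p <- place_atom(a, b, c, len, 109.5, 60 + 120 * (k - 1))
    data.frame(atom_name = names[k], element = "H", resid = resid,
               resname = resname, x = p[1], y = p[2], z = p[3],
               stringsAsFactors = FALSE)
  }))
}

relabel <- function(df, resid, resname, rename = NULL) {
  df$resid <- resid
  df$resname <- resname
  if (!is.null(rename)) df$atom_name <- rename
  df
}

#' Derive the single-turn (ST) model of one H-bond
#'
#' Keeps the residues spanning one helical turn, i..i+4 (alpha) or i..i+3
#' (3-10): the acceptor residue i is truncated to an acetyl cap (its C=O
#' kept, its alpha-carbon becoming the acetyl methyl carbon) and the donor
#' residue to an N-methyl cap (N-H kept, alpha-carbon becoming the
#' N-methyl carbon), giving ACE-(Ala)3-NME for alpha and ACE-(Ala)2-NME
#' for 3-10 helices. Retained heavy atoms keep the parent coordinates
#' exactly; only the cap methyl hydrogens are rebuilt. The remapped
#' H-bond is attached as attribute `"hbond"`.
#'
#' @param wh parent `helix_structure` (a WH chain model).
#' @param hbond an `hbond_pair` of `wh` (or its n-s label).
#' @return A `helix_structure` labelled `ST_<class>-<n>`.
#' @export
make_st_model <- function(wh, hbond) {
  if (is.character(hbond)) hbond <- find_hbond(wh, hbond)
  i <- hbond$acceptor_residue; d <- hbond$donor_residue
  if (d > max(wh$atoms$resid) || i < 0)
    stop("reference error: H-bond does not belong to the structure", call. = FALSE)

  caC <- atom_xyz(wh, resolve_atom(wh, hbond$acceptor_side_ca))
  Ci  <- atom_xyz(wh, resolve_atom(wh, hbond$acceptor_unit[["C"]]))
  Oi  <- atom_xyz(wh, resolve_atom(wh, hbond$acceptor_unit[["O"]]))
  ace <- rbind(
    relabel(atom_row(wh, hbond$acceptor_side_ca), 0L, "ACE", "CH3"),
    methyl_h_rows(Oi, Ci, caC, 0L, "ACE", c("HH31", "HH32", "HH33")),
    relabel(atom_row(wh, hbond$acceptor_unit[["C"]]), 0L, "ACE"),
    relabel(atom_row(wh, hbond$acceptor_unit[["O"]]), 0L, "ACE"))

  mid <- do.call(rbind, lapply(seq_len(d - i - 1), function(k) {
    rows <- wh$atoms[wh$atoms$resid == i + k, , drop = FALSE]
    relabel(rows, k, rows$resname[1])
  }))

  caD <- atom_xyz(wh, resolve_atom(wh, hbond$donor_side_ca))
  Nd  <- atom_xyz(wh, resolve_atom(wh, hbond$donor_unit[["N"]]))
  Cd1 <- atom_xyz(wh, resolve_atom(wh, hbond$donor_unit[["C"]]))
  m <- d - i
  nme <- rbind(
    relabel(atom_row(wh, hbond$donor_unit[["N"]]), m, "NME"),
    relabel(atom_row(wh, hbond$donor_unit[["H"]]), m, "NME"),
    relabel(atom_row(wh, hbond$donor_side_ca), m, "NME", "CH3"),
    methyl_h_rows(Cd1, Nd, caD, m, "NME", c("HH31", "HH32", "HH33")))

  cls <- if (wh$helix_class == "alpha") "alpha" else "3_10"
  st <- helix_structure(rbind(ace, mid, nme),
                        label = sprintf("ST_%s-%d", cls, hbond$model_n),
                        helix_class = wh$helix_class)
  attr(st, "hbond") <- find_hbond(st, sprintf("%d-1", chain_n(st)))
  st
}

#' Derive the minimal H-bond (MH) model of one H-bond
#'
#' Extracts the two peptide groups forming the H-bond as two disconnected
#' N-methylacetamide molecules of 12 atoms each: the amide C, O, N, H and
#' the two flanking alpha-carbons (as methyl carbons) keep the parent
#' coordinates exactly; three methyl hydrogens per methyl are rebuilt at
#' 1.090 Angstrom in staggered orientation. Molecule 1 carries the
#' acceptor unit, molecule 2 the donor unit. The remapped H-bond (donor
#' N-H of molecule 2, acceptor C=O of molecule 1) is attached as
#' attribute `"hbond"`.
#'
#' @inheritParams make_st_model
#' @return A `helix_structure` labelled `MH_<class>-<n>`, helix_class
#'   `"none"`.
#' @export
make_mh_model <- function(wh, hbond) {
  if (is.character(hbond)) hbond <- find_hbond(wh, hbond)

  nma <- function(unit, ca_left_ref, ca_right_ref, resid) {
    caL <- atom_xyz(wh, resolve_atom(wh, ca_left_ref))
    caR <- atom_xyz(wh, resolve_atom(wh, ca_right_ref))
    Cp <- atom_xyz(wh, resolve_atom(wh, unit[["C"]]))
    Op <- atom_xyz(wh, resolve_atom(wh, unit[["O"]]))
    Np <- atom_xyz(wh, resolve_atom(wh, unit[["N"]]))
    rbind(
      relabel(atom_row(wh, ca_left_ref), resid, "NMA", "CH3"),
      methyl_h_rows(Op, Cp, caL, resid, "NMA", c("HH31", "HH32", "HH33")),
      relabel(atom_row(wh, unit[["C"]]), resid, "NMA"),
      relabel(atom_row(wh, unit[["O"]]), resid, "NMA"),
      relabel(atom_row(wh, unit[["N"]]), resid, "NMA"),
      relabel(atom_row(wh, unit[["H"]]), resid, "NMA"),
      relabel(atom_row(wh, ca_right_ref), resid, "NMA", "CN"),
      methyl_h_rows(Cp, Np, caR, resid, "NMA", c("HN1", "HN2", "HN3")))
  }

  i <- hbond$acceptor_residue; d <- hbond$donor_residue
  acc <- nma(hbond$acceptor_unit, hbond$acceptor_side_ca,
             ca_ref(wh, i + 1), 1L)
  don <- nma(hbond$donor_unit, ca_ref(wh, d - 1), hbond$donor_side_ca, 2L)

  cls <- if (wh$helix_class == "alpha") "alpha" else "3_10"
  mh <- helix_structure(rbind(acc, don),
                        label = sprintf("MH_%s-%d", cls, hbond$model_n),
                        helix_class = "none")
  attr(mh, "hbond") <- hbond_pair(
    model_n = hbond$model_n, s = 1L, acceptor_residue = 0L, donor_residue = 4L,
    acceptor_unit = c(C = "1:C", O = "1:O", N = "1:N", H = "1:H"),
    donor_unit = c(C = "2:C", O = "2:O", N = "2:N", H = "2:H"),
    acceptor_side_ca = "1:CH3", donor_side_ca = "2:CN")
  mh
}

#' Generate the NFA fragment quartet for one H-bond
#'
#' Implements the inclusion-exclusion fragment scheme: `noA` deletes the
#' acceptor group (the C=O atom pair), `noD` the donor group (the N-H
#' pair), `noAD` both; `sys` is the unmodified model. Each deleted pair is
#' replaced by two hydrogen caps placed along the direction of the deleted
#' bond (C-H caps at 1.090 Angstrom, the N-H cap at 1.010 Angstrom), so
#' all four members have equal atom counts and closed valence shells. The
#' scheme is applied identically to WH, ST and MH inputs.
#'
#' @param model a `helix_structure` containing the H-bond's peptide-unit
#'   atoms.
#' @param hbond the `hbond_pair`, resolvable in `model` (for ST/MH models
#'   use the remapped pair attached by the deriving function).
#' @return A list of class `fragment_set` with elements `sys`, `noA`,
#'   `noD`, `noAD`, `hbond` and `cap_log` (a data.frame of deleted atom,
#'   host atom, cap name and cap bond length).
#' @export
make_nfa_fragments <- function(model, hbond) {
  if (is.null(hbond)) stop("reference error: hbond is NULL", call. = FALSE)
  need <- c(hbond$acceptor_unit[c("C", "O")], hbond$donor_unit[c("N", "H")],
            hbond$acceptor_unit[["N"]], hbond$acceptor_side_ca,
            hbond$donor_unit[["C"]], hbond$donor_side_ca)
  idx <- vapply(need, function(r) resolve_atom(model, r), numeric(1))

  cap_row <- function(host_ref, toward_ref, len, name) {
    host <- atom_xyz(model, resolve_atom(model, host_ref))
    tow <- atom_xyz(model, resolve_atom(model, toward_ref))
    p <- host + len * vunit(tow - host)
    hr <- atom_row(model, host_ref)
    list(atoms = data.frame(atom_name = name, element = "H",
                            resid = hr$resid, resname = hr$resname,
                            x = p[1], y = p[2], z = p[3],
                            stringsAsFactors = FALSE),
         log = data.frame(deleted_atom = toward_ref, host_atom = host_ref,
                          cap_atom = name, cap_length = len,
                          stringsAsFactors = FALSE))
  }

  drop_acceptor <- list(
    cap_row(hbond$acceptor_side_ca, hbond$acceptor_unit[["C"]], 1.090, "HV1"),
    cap_row(hbond$acceptor_unit[["N"]], hbond$acceptor_unit[["C"]], 1.010, "HV2"))
  drop_donor <- list(
    cap_row(hbond$donor_unit[["C"]], hbond$donor_unit[["N"]], 1.090, "HV3"),
    cap_row(hbond$donor_side_ca, hbond$donor_unit[["N"]], 1.090, "HV4"))

  apply_deletion <- function(del_refs, caps, suffix) {
    del <- vapply(del_refs, function(r) resolve_atom(model, r), numeric(1))
    at <- model$atoms[-del, , drop = FALSE]
    at <- rbind(at, do.call(rbind, lapply(caps, `[[`, "atoms")))
    helix_structure(at, label = paste0(model$label, ":", suffix),
                    helix_class = "none", check = FALSE)
  }

  out <- list(
    sys = model,
    noA = apply_deletion(hbond$acceptor_unit[c("C", "O")], drop_acceptor, "noA"),
    noD = apply_deletion(hbond$donor_unit[c("N", "H")], drop_donor, "noD"),
    noAD = apply_deletion(c(hbond$acceptor_unit[c("C", "O")],
                            hbond$donor_unit[c("N", "H")]),
                          c(drop_acceptor, drop_donor), "noAD"),
    hbond = hbond,
    cap_log = do.call(rbind, lapply(c(drop_acceptor, drop_donor), `[[`, "log")))
  class(out) <- "fragment_set"
  out
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %s  hbond %s  (%d atoms per member)\n",
              x$sys$label, x$hbond$label, n_atoms(x$sys)))
  invisible(x)
}
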