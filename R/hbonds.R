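#' Backbone hydrogen-bond pair
#'
#' Describes one backbone H-bond of a helical chain model: the acceptor
#' C=O sits on residue `i` and the donor N-H on residue `i + 4` (alpha) or
#' `i + 3` (3-10). The s-th H-bond counting from the N-terminus of the
#' model with n alanines carries the label `n-s`, with `s = i + 1`.
#'
#' The acceptor peptide unit is the planar group C_i, O_i, N_{i+1},
#' H_{i+1}; the donor unit is C_{d-1}, O_{d-1}, N_d, H_d. The flanking
#' alpha-carbons (`acceptor_side_ca`, `donor_side_ca`) are kept as capping
#' anchors for fragment generation.
#'
#' @param model_n number of alanine residues of the parent model.
#' @param s 1-based H-bond index from the N-terminus.
#' @param acceptor_residue,donor_residue 0-based residue indices.
#' @param acceptor_unit,donor_unit named character vectors of
#'   `"resid:atom"` references with names C, O, N, H.
#' @param acceptor_side_ca,donor_side_ca `"resid:atom"` references to the
#'   carbons flanking the deleted groups.
#' @return An object of class `hbond_pair`.
#' @export
hbond_pair <- function(model_n, s, acceptor_residue, donor_residue,
                       acceptor_unit, donor_unit,
                       acceptor_side_ca, donor_side_ca) {
  stopifnot(s == acceptor_residue + 1,
            all(c("C", "O", "N", "H") %in% names(acceptor_unit)),
            all(c("C", "O", "N", "H") %in% names(donor_unit)))
  structure(list(model_n = as.integer(model_n), s = as.integer(s),
                 acceptor_residue = as.integer(acceptor_residue),
                 donor_residue = as.integer(donor_residue),
                 label = sprintf("%d-%d", model_n, s),
                 acceptor_unit = acceptor_unit, donor_unit = donor_unit,
                 acceptor_side_ca = acceptor_side_ca,
                 donor_side_ca = donor_side_ca),
            class = "hbond_pair")
}

#' @export
print.hbond_pair <- function(x, ...) {
  cat(sprintf("<hbond_pair> %s  acceptor C=O @ res %d -> donor N-H @ res %d\n",
              x$label, x$acceptor_residue, x$donor_residue))
  invisible(x)
}

## "resid:atom" reference for an atom that is CA on ALA but CH3 on caps.
ca_ref <- function(structure, resid) {
  name <- if (any(structure$atoms$resid == resid &
                  structure$atoms$atom_name == "CA")) "CA" else "CH3"
  sprintf("%d:%s", resid, name)
}

#' Enumerate backbone hydrogen bonds of a helix model
#'
#' For an alpha-helix chain with n alanines the acceptor residues are
#' i = 0..n-3 (count n - 2); for a 3-10-helix i = 0..n-2 (count n - 1).
#' The acetyl cap's C=O (residue 0) and the N-methyl cap's N-H (residue
#' n + 1) participate, which is what yields one to six H-bonds over the
#' model ranges n = 3..8 (alpha) and n = 2..7 (3-10). Pairs are returned
#' ordered by s.
#'
#' @param structure a `helix_structure` chain model with helix_class
#'   `"alpha"` or `"three_ten"`.
#' @return List of `hbond_pair`.
#' @export
enumerate_hbonds <- function(structure) {
  if (structure$helix_class == "none")
    stop("classification error: structure has no helix class", call. = FALSE)
  n <- chain_n(structure)
  gap <- if (structure$helix_class == "alpha") 4L else 3L
  i_max <- n + 1L - gap
  if (i_max < 0) return(list())
  lapply(0:i_max, function(i) {
    d <- i + gap
    hbond_pair(
      model_n = n, s = i + 1L, acceptor_residue = i, donor_residue = d,
      acceptor_unit = c(C = sprintf("%d:C", i), O = sprintf("%d:O", i),
                        N = sprintf("%d:N", i + 1), H = sprintf("%d:H", i + 1)),
      donor_unit = c(C = sprintf("%d:C", d - 1), O = sprintf("%d:O", d - 1),
                     N = sprintf("%d:N", d), H = sprintf("%d:H", d)),
      acceptor_side_ca = ca_ref(structure, i),
      donor_side_ca = ca_ref(structure, d))
  })
}

#' Find an H-bond of a model by its n-s label
#'
#' @param structure a helix chain model.
#' @param label label such as `"5-2"`.
#' @return The matching `hbond_pair`.
#' @export
find_hbond <- function(structure, label) {
  hb <- enumerate_hbonds(structure)
  hit <- Filter(function(h) h$label == label, hb)
  if (!length(hit))
    stop("reference error: no H-bond labelled ", label, " in '",
         structure$label, "'", call. = FALSE)
  hit[[1]]
}

#' Distances between neighbouring polar groups of H-bond pairs
#'
#' For every H-bond pair of every supplied structure, measures one of the
#' neighbour distances implicated in backbone depolarization: `"OO"`, the
#' carbonyl O of the acceptor residue i to the O of residue i + 1; `"HH"`,
#' the amide H of the donor residue d to the amide H of residue d - 1;
#' `"OH"`, the acceptor O_i to the amide H of residue i + 2. Returns the
#' mean and the population (divide-by-N) standard deviation.
#'
#' @param structures list of helix chain models (a single structure is
#'   accepted).
#' @param pair_kind `"OO"`, `"HH"` or `"OH"`.
#' @return List with `mean`, `sd`, `n`, and the individual `distances` (Angstrom).
#' @export
neighbor_distance_stats <- function(structures, pair_kind = c("OO", "HH", "OH")) {
  pair_kind <- match.arg(pair_kind)
  if (inherits(structures, "helix_structure")) structures <- list(structures)
  dists <- unlist(lapply(structures, function(s) {
    vapply(enumerate_hbonds(s), function(h) {
      refs <- switch(pair_kind,
        OO = c(sprintf("%d:O", h$acceptor_residue),
               sprintf("%d:O", h$acceptor_residue + 1)),
        HH = c(sprintf("%d:H", h$donor_residue - 1),
               sprintf("%d:H", h$donor_residue)),
        OH = c(sprintf("%d:O", h$acceptor_residue),
               sprintf("%d:H", h$acceptor_residue + 2)))
      a <- atom_xyz(s, resolve_atom(s, refs[1]))
      b <- atom_xyz(s, resolve_atom(s, refs[2]))
      vnorm(a - b)
    }, numeric(1))
  }))
  if (!length(dists)) stop("no-data error: no H-bond pairs found", call. = FALSE)
  m <- mean(dists)
  list(mean = m, sd = sqrt(mean((dists - m)^2)), n = length(dists),
       distances = dists)
}
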