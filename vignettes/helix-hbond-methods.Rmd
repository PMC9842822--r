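---
title: "Models and methods: helix hydrogen-bond energetics by negative fragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: helix hydrogen-bond energetics by negative fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixhb)
```

## The model systems

The package studies backbone hydrogen bonds in capped poly-alanine
helices, ACE–(Ala)$_n$–NME. Three model chemistries share atomic
coordinates for the H-bonded groups:

* **WH** (whole helix): the full chain at ideal torsions, $\varphi/\psi =
  (-57^\circ, -47^\circ)$ for the $\alpha$-helix and $(-49^\circ,
  -26^\circ)$ for the $3_{10}$-helix, $\omega = 180^\circ$;
* **ST** (single turn): the residues spanning one turn, the acceptor
  residue truncated to an acetyl cap and the donor residue to an
  N-methyl cap;
* **MH** (minimal H-bond): the two peptide groups as disconnected
  N-methylacetamide molecules.

Residues are indexed 0-based with the acetyl cap as residue 0 and the
N-methyl cap as residue $n+1$; both caps are H-bond partners (the acetyl
C=O can accept, the N-methyl N–H can donate). This gives $n-2$ H-bonds
per $\alpha$-model and $n-1$ per $3_{10}$-model, i.e. one to six over the
ranges $n = 3..8$ and $n = 2..7$, and $21 + 21 = 42$ H-bonds pooled. The
$s$-th H-bond from the N-terminus of the $n$-residue model is labelled
$n\text{-}s$, with acceptor residue $s-1$.

### Construction from internal coordinates

Chains are grown by natural-extension placement: each atom is positioned
from three reference atoms by a bond length, bond angle and torsion, with
the first three backbone atoms spanning the canonical frame (origin,
x-axis, xy-plane). The procedure is deterministic and reproduces the
requested torsions to better than $10^{-6\,\circ}$ (a round-trip property
the tests sweep over a grid of $\varphi/\psi$ pairs).

Covalent geometry is not dictated by the helix torsions, so the builder
uses standard peptide values, all overridable through
`helix_spec(bond_table = ...)`: N–C$\alpha$ 1.458, C$\alpha$–C 1.525,
C–N 1.329, C=O 1.231, N–H 1.010, C–H 1.090 Å; angles
N–C$\alpha$–C 111.2°, C$\alpha$–C–N 116.2°, C–N–C$\alpha$ 121.7°.
Carbonyl oxygens and amide hydrogens are placed by in-plane trigonal
geometry (along the external bisector of the two heavy-atom bonds), which
keeps every peptide group exactly planar. Side-chain and cap methyls use
staggered hydrogens; the L-configuration of alanine is enforced through
the improper torsion N–C–C$\alpha$–C$\beta = -122.7^\circ$, validated
against an independently generated L-alanine reference geometry. These
are *ideal-geometry starting structures*: the energy minimization under
frozen backbone torsions that precedes quantum reference calculations is
delegated to the external engine through the adapter, since no optimizer
belongs to this package's scope.

## The negative fragmentation combination

One H-bond's energy is estimated by deleting its acceptor group (the C=O
atom pair) and donor group (the N–H pair) in turn:

$$E_\mathrm{HB} = E_\mathrm{sys} - E_\mathrm{noA} - E_\mathrm{noD} + E_\mathrm{noAD}.$$

Each deleted pair is replaced by two hydrogen caps placed along the
direction of the deleted bond at fixed lengths (1.090 Å for C–H caps,
1.010 Å for the N–H cap), so all four members have equal atom counts and
closed shells. The group granularity (atom pairs rather than whole
residues) keeps the quartet members the same size and matches the
per-H-bond resolution of the combination; the capping convention is the
simplest reproducible one and every cap is logged (`cap_log`) for audit.
Fragmentation operates identically on WH, ST and MH inputs.

The same combination applies voxel-wise to electron-density grids
(`nfa_density`), and `density_difference` forms the maps that compare
model chemistries. Grid compatibility is exact-match on origin, axes and
counts — no resampling, because interpolation would silently change the
science of a voxel-wise identity.

### Correctness oracle

Under a strictly pairwise-additive energy backend, the combination
telescopes exactly to the direct acceptor-group/donor-group interaction.
The package ships such a backend (`pairwise_total_energy`, the full
Coulomb + Lennard-Jones double sum) and the tests verify the identity on
all 42 H-bonds. One numerical subtlety: member totals reach
$\sim 2 \times 10^6$ kcal/mol (bonded-pair Lennard-Jones repulsion is
included in a full double sum), where four independently rounded doubles
leave a residual of order $10^{-10}$ after cancellation. The backend
therefore carries the extended-precision remainder of its summation with
the returned value, and `nfa_energy` folds those remainders into a single
extended-precision reduction; the identity then holds to $\sim 10^{-12}$
kcal/mol. A real defect in the fragmenter (a wrong deletion, a misplaced
cap entering the sum) would surface at the $10^{-1}$ level, so the oracle
retains its full diagnostic power.

## The classical H-bond energy

For the acceptor unit $\{$C, O, N, H$\}$ and donor unit $\{$C, O, N,
H$\}$ (the two planar peptide groups), the energy is the 16-pair sum

$$E_\mathrm{HB}^\mathrm{MM} = \sum_{i,j} \frac{k\, q_i q_j}{r_{ij}}
  + \sum_{i,j}\left(\frac{A_{ij}}{r_{ij}^{12}} -
  \frac{B_{ij}}{r_{ij}^{6}}\right)$$

with $k = 332.0637$ kcal Å mol$^{-1}$ e$^{-2}$ (the conversion constant
required for kcal/mol from charges in e and distances in Å; configurable),
no cutoff, no scaling, vacuum electrostatics — the gas-phase setting of
the reference calculations. Backbone charges default to the AMBER
ff99SB values $q^0_\mathrm{N} = -0.4157$, $q^0_\mathrm{H} = 0.2719$,
$q^0_\mathrm{C} = 0.5973$, $q^0_\mathrm{O} = -0.5679$; Lennard-Jones
parameters for all atom classes come from the same force-field family,
with $A_{ij} = \varepsilon_{ij} R_{\min,ij}^{12}$, $B_{ij} =
2\varepsilon_{ij} R_{\min,ij}^{6}$, $R_{\min,ij} = R_i + R_j$,
$\varepsilon_{ij} = \sqrt{\varepsilon_i \varepsilon_j}$.

Note that the four-atom peptide unit is *not* neutral under these charges
(net $-0.1144$ e), so the 16-term sum decays as a $1/r$ monopole term at
large separation rather than as a dipole–dipole $1/r^3$ tail; the tests
assert the actual asymptotics.

## The dipole-polarized charge model

Helical packing places each C=O and N–H group close to like groups one
turn along the chain, depolarizing them and weakening the H-bond relative
to an isolated donor–acceptor pair. The correction model makes the
backbone charges structure-dependent:

$$q_X^i = q_X^0 (1 - \delta_X^i), \qquad X \in \{N, H, C, O\},$$

where peptide group $i$ comprises C, O of residue $i$ and N, H of residue
$i+1$, carrying local dipoles $\vec\mu^i_\mathrm{CO} = \tfrac12 (q_C -
q_O)(\vec r_C - \vec r_O)$ and $\vec\mu^i_\mathrm{NH} = \tfrac12 (q_H -
q_N)(\vec r_H - \vec r_N)$ centred at the respective bond midpoints. The
modifiers are driven by nearest-neighbour dipole–dipole couplings

$$\delta_H^i = \lambda_\mathrm{HO} U(\vec\mu^i_\mathrm{NH},
  \vec\mu^{i-1}_\mathrm{CO}) + \lambda_\mathrm{HH}
  U(\vec\mu^i_\mathrm{NH}, \vec\mu^{i-1}_\mathrm{NH}),$$
$$\delta_O^i = \lambda_\mathrm{OO} U(\vec\mu^i_\mathrm{CO},
  \vec\mu^{i+1}_\mathrm{CO}) + \lambda_\mathrm{OH}
  U(\vec\mu^i_\mathrm{CO}, \vec\mu^{i+1}_\mathrm{NH}),$$

with $U(\vec\mu_1, \vec\mu_2) = \kappa [\vec\mu_1 \cdot \vec\mu_2 / r^3 -
3 (\vec\mu_1 \cdot \vec r)(\vec\mu_2 \cdot \vec r)/r^5]$ over the
centre-to-centre vector. Terms whose neighbour group does not exist (chain
termini) vanish, and $\delta_N, \delta_C$ follow from exact local
neutrality, $\delta_N^i q_N^0 = -\delta_H^i q_H^0$ and $\delta_C^i q_C^0
= -\delta_O^i q_O^0$, so every group's total charge is conserved to
machine precision under any coefficients. The dipoles entering $U$ are
computed from the original charges — the correction is one-shot, not
self-consistent, which keeps the fitted coefficients' meaning fixed. Only
the Coulomb term sees the modified charges; Lennard-Jones is untouched.

### The coupling-constant convention

Two conventions for $\kappa$ are exposed. With $\kappa = 332.0637$, $U$
is an energy in kcal/mol and the $\lambda$ carry (kcal/mol)$^{-1}$; with
$\kappa = 1$, $U$ is in bare e$^2$/Å$^3$. The default is the kcal/mol
convention, and every result records which was used. The package's own
recovery and reference-synthesis studies run under $\kappa = 1$: with the
four-coefficient set used throughout ($\lambda_\mathrm{HO} = -11.535$,
$\lambda_\mathrm{HH} = 38.517$, $\lambda_\mathrm{OO} = 16.967$,
$\lambda_\mathrm{OH} = 4.587$), the bare convention yields fractional
modifiers $|\delta| \le 0.17$ — physically sensible depolarization —
whereas the kcal/mol convention would scale them by 332 into meaningless
territory. (A note on that coefficient list: its published source names
$\lambda_\mathrm{OO}$ twice; the second value is assigned to
$\lambda_\mathrm{OH}$, the only reading consistent with the four named
parameters.)

## Fitting the coefficients

`fit_lambda` minimizes $\sum (E^\mathrm{MM_{modified}}_\mathrm{HB}(\lambda)
- E^\mathrm{ref}_\mathrm{HB})^2$ over the pooled 42-H-bond set by damped
Gauss–Newton iteration: numeric forward-difference sensitivities
(step $10^{-6}$), normal-equation steps with a $10^{-12}$ ridge for
rank-safety, step halving until the objective decreases, convergence when
the decrease falls below $10^{-10}$ (kcal/mol)$^2$, starting from
$\lambda = 0$. The objective is quartic in $\lambda$ (both partner
charges are modified), hence iterative rather than one linear solve; the
accepted-step sequence is monotone by construction, and the solution is
invariant to reference-row order because rows are canonicalized against
the model set before fitting. An independent Levenberg–Marquardt
implementation (`minpack.lm`) reproduces the solution in the test suite.

Because the modifiers are linear in $\lambda$ for fixed geometry, the
fitter precomputes, per H-bond, the Lennard-Jones constant, the 16
distances and each unit atom's coefficient row, reducing every objective
evaluation to a few small matrix products.

### The synthetic reference generator

`synthesize_reference` produces reference tables as model predictions at
a prescribed true coefficient vector plus i.i.d. Gaussian noise — the
stand-in for a fragmentation-derived quantum reference table, which
cannot be produced desk-side because it requires hours-to-days of
external DFT. What the generator emulates: the pooled 21 + 21 H-bond
coverage, energies in the physical $-4$ to $-6$ kcal/mol range, and a
controllable noise floor. What it does not emulate: systematic
quantum-classical discrepancies (charge transfer, many-body polarization
beyond nearest neighbours, short-bond quantum effects in $3_{10}$
contacts), which in real data are structure-correlated rather than
i.i.d. Passing recovery tests therefore demonstrates that the fitter and
model are correct and identifiable — not that four coefficients suffice
for real helices. At zero noise the fit recovers generating coefficients
to $10^{-6}$ (observed: $3 \times 10^{-11}$); at $\sigma = 0.1$ kcal/mol
the seed-averaged estimates stay within three standard errors, with
$\lambda_\mathrm{HH}$ the most weakly identified (its coupling term is
smallest).

## Degenerate inputs and numerical edges

Zero-length vectors in dihedral or placement geometry, coincident dipole
centres, overlapping atoms ($r < 0.1$ Å) in energy sums, non-finite
energies in quartets, lattice mismatches in grid algebra and unresolvable
H-bond or reference keys all raise typed errors naming the offending
field. PDB round-trips preserve names, residue indices and coordinates at
the format's 3-decimal precision; cube round-trips preserve the z-fastest
value layout at 6 significant digits.

## Problem sizes

The default study conditions are the standard model ranges ($n \le 8$,
87 atoms at most), 42 H-bonds, $41^3$-point density grids and a 20-seed
noise sweep; the full test suite and the reproduction script each run in
about a minute on one CPU. Larger helices, finer grids or longer sweeps
scale linearly through the same interfaces.

## Known limitations

* Alanine side chains only; no left-handed or $\pi$-helices, no solvent.
* The hydrogen-capping geometry of the source fragmentation studies is
  not published; the fixed-length bond-direction convention here is a
  declared choice, logged per fragment.
* The external engine's optimized geometries differ from the ideal-
  geometry starting points (ideal-geometry neighbour O···O distances,
  e.g., average 3.30 Å versus 3.51 Å after constrained optimization), so
  quantities tied to optimized structures require the adapter round trip.
* The polarization model stops at nearest-neighbour groups and does not
  polarize side chains or cap methyls.
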