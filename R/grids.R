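#' Regular volumetric scalar grid
#'
#' Holds an electron density (or density difference) on a regular 3-D
#' lattice following the Gaussian-cube conventions: an origin and three
#' step vectors in Bohr, values in e/Bohr^3 stored with the third (z)
#' index varying fastest on file.
#'
#' @param origin length-3 numeric, Bohr.
#' @param axes 3x3 numeric matrix; row k is the step vector of axis k (Bohr).
#' @param counts length-3 positive integers.
#' @param values numeric array of dim `counts` (or a vector of
#'   `prod(counts)` values in z-fastest order).
#' @param atoms optional data.frame (`Z`, `charge`, `x`, `y`, `z` in Bohr)
#'   carried to cube files.
#' @return An object of class `volumetric_grid`.
#' @export
volumetric_grid <- function(origin, axes, counts, values, atoms = NULL) {
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  counts <- as.integer(counts)
  stopifnot(length(origin) == 3, length(counts) == 3, all(counts > 0))
  if (!is.array(values))
    values <- aperm(array(as.numeric(values), dim = rev(counts)), 3:1)
  if (!identical(dim(values), as.integer(counts)))
    stop("counts do not match value-array extent", call. = FALSE)
  structure(list(origin = origin, axes = axes, counts = counts,
                 values = values, atoms = atoms),
            class = "volumetric_grid")
}

#' @export
print.volumetric_grid <- function(x, ...) {
  cat(sprintf("<volumetric_grid> %d x %d x %d, voxel volume %.6g Bohr^3, integral %.6g e\n",
              x$counts[1], x$counts[2], x$counts[3],
              abs(det(x$axes)), grid_integral(x)))
  invisible(x)
}

#' Integral of a grid over its volume
#'
#' Riemann sum: sum of voxel values times the voxel volume |det(axes)|.
#'
#' @param g a `volumetric_grid`.
#' @return Numeric (electrons, for a density grid).
#' @export
grid_integral <- function(g) sum(g$values) * abs(det(g$axes))

check_combinable <- function(a, b) {
  if (!identical(a$counts, b$counts))
    stop("grid-incompatibility error: counts differ", call. = FALSE)
  if (!isTRUE(all(a$origin == b$origin)))
    stop("grid-incompatibility error: origin differs", call. = FALSE)
  if (!isTRUE(all(a$axes == b$axes)))
    stop("grid-incompatibility error: axes differ", call. = FALSE)
  invisible(TRUE)
}

#' Density change upon H-bond formation (inclusion-exclusion)
#'
#' Voxel-wise combination rho_sys - rho_noA - rho_noD + rho_noAD of four
#' grids on the identical lattice (no resampling: origin, axes and counts
#' must agree exactly). Metadata is copied from `sys`.
#'
#' @param sys,noA,noD,noAD `volumetric_grid`s.
#' @return A `volumetric_grid` holding the density change.
#' @export
nfa_density <- function(sys, noA, noD, noAD) {
  for (g in list(noA, noD, noAD)) check_combinable(sys, g)
  out <- sys
  out$values <- sys$values - noA$values - noD$values + noAD$values
  out
}

#' Voxel-wise difference of two density-change grids
#'
#' @param a,b `volumetric_grid`s on the identical lattice.
#' @return A `volumetric_grid` holding a - b.
#' @export
density_difference <- function(a, b) {
  check_combinable(a, b)
  out <- a
  out$values <- a$values - b$values
  out
}

#' Sum of isotropic Gaussian blobs on a grid
#'
#' Builds a synthetic density as a sum of normalized 3-D Gaussians, each
#' integrating (over all space) to a prescribed electron count. Used to
#' generate analytically controlled fixtures for the density
#' inclusion-exclusion machinery.
#'
#' @param centers m x 3 matrix of blob centers (Bohr).
#' @param electrons length-m electron counts (may be negative for
#'   polarization-like features).
#' @param sigma blob width(s) in Bohr (recycled).
#' @param origin,axes,counts lattice definition as in [volumetric_grid()];
#'   `axes` must be diagonal-orthogonal for this generator.
#' @return A `volumetric_grid`.
#' @export
gaussian_blob_grid <- function(centers, electrons, sigma, origin, axes, counts) {
  centers <- matrix(centers, ncol = 3)
  stopifnot(nrow(centers) == length(electrons))
  sigma <- rep_len(sigma, nrow(centers))
  counts <- as.integer(counts)
  ax <- matrix(as.numeric(axes), 3, 3)
  xs <- origin[1] + (seq_len(counts[1]) - 1) * ax[1, 1]
  ys <- origin[2] + (seq_len(counts[2]) - 1) * ax[2, 2]
  zs <- origin[3] + (seq_len(counts[3]) - 1) * ax[3, 3]
  vals <- array(0, dim = counts)
  for (m in seq_len(nrow(centers))) {
    norm <- electrons[m] / ((2 * pi * sigma[m]^2)^1.5)
    gx <- exp(-(xs - centers[m, 1])^2 / (2 * sigma[m]^2))
    gy <- exp(-(ys - centers[m, 2])^2 / (2 * sigma[m]^2))
    gz <- exp(-(zs - centers[m, 3])^2 / (2 * sigma[m]^2))
    vals <- vals + norm * outer(gx, outer(gy, gz))
  }
  volumetric_grid(origin, ax, counts, vals)
}

#' Synthetic density quartet for one H-bond
#'
#' Emulates the four single-point densities entering the
#' inclusion-exclusion map: a shared backbone density, an acceptor-group
#' blob (present in sys and noD), a donor-group blob (present in sys and
#' noA), and, in the full system only, a zero-integral polarization dipole
#' pair representing the density shift upon H-bond formation. The
#' inclusion-exclusion of the four grids is then exactly that dipole pair,
#' whose integral vanishes analytically.
#'
#' @param base_electrons electron count of the shared backbone blob.
#' @param group_electrons electron count of each deleted group (12 for a
#'   peptide-unit-sized group).
#' @param shift_electrons magnitude of the polarization pair.
#' @param counts grid points per axis (cubic grid).
#' @param spacing grid spacing, Bohr.
#' @return List with elements `sys`, `noA`, `noD`, `noAD`
#'   (`volumetric_grid`s).
#' @export
synthetic_density_quartet <- function(base_electrons = 36, group_electrons = 12,
                                      shift_electrons = 0.05,
                                      counts = c(41, 41, 41), spacing = 0.5) {
  origin <- -(counts - 1) / 2 * spacing
  axes <- diag(rep(spacing, 3))
  mk <- function(centers, electrons, sigma)
    gaussian_blob_grid(centers, electrons, sigma, origin, axes, counts)
  c_base <- c(0, 0, 0); c_acc <- c(-2.5, 0, 0); c_don <- c(2.5, 0, 0)
  base <- rbind(c_base); grp_a <- rbind(c_acc); grp_d <- rbind(c_don)
  sys <- mk(rbind(base, grp_a, grp_d, c(-1, 0, 0), c(1, 0, 0)),
            c(base_electrons, group_electrons, group_electrons,
              shift_electrons, -shift_electrons),
            c(1.5, 1.0, 1.0, 0.8, 0.8))
  noA <- mk(rbind(base, grp_d), c(base_electrons, group_electrons), c(1.5, 1.0))
  noD <- mk(rbind(base, grp_a), c(base_electrons, group_electrons), c(1.5, 1.0))
  noAD <- mk(base, base_electrons, 1.5)
  list(sys = sys, noA = noA, noD = noD, noAD = noAD)
}
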