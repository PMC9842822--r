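#' Build the pooled WH H-bond set
#'
#' Constructs every whole-helix model over the standard size ranges
#' (n = 3..8 alpha, n = 2..7 for the 3-10 class; 21 H-bonds each, 42
#' pooled) and enumerates their H-bonds. This is the model set over which
#' the polarization coefficients are fitted.
#'
#' @param alpha_n,three_ten_n integer vectors of chain lengths.
#' @return List of entries, each a list with `structure`, `hbond`,
#'   `model_label`, `hbond_label`.
#' @export
wh_hbond_set <- function(alpha_n = 3:8, three_ten_n = 2:7) {
  entries <- list()
  for (cls in c("alpha", "three_ten")) {
    ns <- if (cls == "alpha") alpha_n else three_ten_n
    for (n in ns) {
      wh <- build_wh_model(n, helix_spec(cls))
      for (hb in enumerate_hbonds(wh))
        entries[[length(entries) + 1]] <- list(
          structure = wh, hbond = hb,
          model_label = wh$label, hbond_label = hb$label)
    }
  }
  entries
}

set_keys <- function(set)
  vapply(set, function(e) paste(e$model_label, e$hbond_label), character(1))

#' Root-mean-square deviation between predictions and reference
#'
#' @param predictions,ref numeric vectors; if named, values are matched by
#'   name, otherwise positionally (equal lengths required).
#' @return RMSD, in the units of the inputs.
#' @export
rmsd <- function(predictions, ref) {
  if (!is.null(names(predictions)) && !is.null(names(ref))) {
    keys <- intersect(names(predictions), names(ref))
    if (!length(keys)) stop("no-data error: no matching keys", call. = FALSE)
    predictions <- predictions[keys]; ref <- ref[keys]
  }
  if (length(predictions) != length(ref) || !length(ref))
    stop("no-data error: prediction/reference length mismatch", call. = FALSE)
  sqrt(mean((as.numeric(predictions) - as.numeric(ref))^2))
}

#' Synthesize a reference H-bond energy table
#'
#' Generates reference energies as the polarized-charge model prediction
#' at a prescribed true coefficient vector plus optional Gaussian noise:
#' the synthetic stand-in for a fragmentation-derived quantum reference
#' table, used for parameter-recovery studies.
#'
#' @param set H-bond set from [wh_hbond_set()].
#' @param lambda_true `lambda_params` generating the table.
#' @param noise_sd Gaussian noise standard deviation, kcal/mol (>= 0).
#' @param seed integer seed; same seed, same table.
#' @param params `ff_params`.
#' @param kappa electrostatic constant for the dipole couplings.
#' @return data.frame with columns `model_label`, `hbond_label`, `E_ref`
#'   (kcal/mol) and `source` (`"synthetic"`).
#' @export
synthesize_reference <- function(set, lambda_true = lambda_params(),
                                 noise_sd = 0, seed = 1,
                                 params = ff_params(), kappa = 332.0637) {
  stopifnot(noise_sd >= 0)
  e <- vapply(set, function(en)
    as.numeric(modified_mm_hbond_energy(en$structure, en$hbond, lambda_true,
                                        params, kappa)), numeric(1))
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    e <- e + stats::rnorm(length(e), 0, noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  data.frame(model_label = vapply(set, `[[`, character(1), "model_label"),
             hbond_label = vapply(set, `[[`, character(1), "hbond_label"),
             E_ref = e, source = "synthetic", stringsAsFactors = FALSE)
}

## Fast predictor: the charge modifiers are linear in the four
## coefficients (the dipoles entering U are fixed), so each H-bond's
## modified energy reduces to a Coulomb form with charges affine in
## lambda plus a constant Lennard-Jones term. Precomputing the linear
## coefficient rows once makes the fit independent of structure size.
build_predictor <- function(set, params, kappa) {
  basis <- diag(4)
  per_entry <- lapply(set, function(en) {
    s <- en$structure; hb <- en$hbond
    ia <- unit_indices(s, hb$acceptor_unit)
    id <- unit_indices(s, hb$donor_unit)
    r <- pair_distances(s, ia, id)
    lj <- atom_lj(s, params)
    ab <- lj_ab(rep(lj$rmin2[ia], times = 4), rep(lj$eps[ia], times = 4),
                rep(lj$rmin2[id], each = 4), rep(lj$eps[id], each = 4))
    e_lj <- sum(matrix(ab$A, 4, 4) / r^12 - matrix(ab$B, 4, 4) / r^6)
    q0 <- atom_charges(s, params)
    ## delta of each of the 8 unit atoms is B %*% lambda
    dB <- vapply(1:4, function(k) {
      l <- lambda_params(basis[k, 1], basis[k, 2], basis[k, 3], basis[k, 4])
      qk <- modified_charges(s, l, params, kappa)
      ifelse(q0 == 0, 0, 1 - qk / q0)
    }, numeric(length(q0)))
    list(ia = ia, id = id, r = r, e_lj = e_lj, q0 = q0,
         dB_a = dB[ia, , drop = FALSE], dB_d = dB[id, , drop = FALSE])
  })
  kc <- params$coulomb_constant
  function(lambda) {
    vapply(per_entry, function(p) {
      qa <- p$q0[p$ia] * (1 - as.numeric(p$dB_a %*% lambda))
      qd <- p$q0[p$id] * (1 - as.numeric(p$dB_d %*% lambda))
      sum(kc * outer(qa, qd) / p$r) + p$e_lj
    }, numeric(1))
  }
}

#' Fit the four polarization coefficients to reference energies
#'
#' Minimizes the sum of squared deviations between the polarized-charge
#' model predictions and the reference energies by damped Gauss-Newton
#' iteration with numerically estimated sensitivities: starting from the
#' initial coefficients (default all zero), each step solves the
#' linearized normal equations and is halved until the objective
#' decreases; convergence is declared when the objective decreases by
#' less than `tol` between iterations. Deterministic given its inputs and
#' invariant to the ordering of the reference rows.
#'
#' @param set H-bond set from [wh_hbond_set()]; every reference row must
#'   resolve to one of its entries.
#' @param ref reference table as from [synthesize_reference()] (columns
#'   `model_label`, `hbond_label`, `E_ref`).
#' @param init initial `lambda_params`.
#' @param tol convergence tolerance on the objective decrease
#'   ((kcal/mol)^2).
#' @param max_iter iteration cap; exceeding it flags `converged = FALSE`
#'   rather than erroring.
#' @param params `ff_params`.
#' @param kappa electrostatic constant for the dipole couplings.
#' @return List of class `lambda_fit` with `lambdas` (`lambda_params`),
#'   `rmsd_before`, `rmsd_after` (kcal/mol), `iterations`, `converged`.
#' @export
fit_lambda <- function(set, ref, init = lambda_params(), tol = 1e-10,
                       max_iter = 200, params = ff_params(), kappa = 332.0637) {
  if (nrow(ref) < 4)
    stop("at least four reference rows are required", call. = FALSE)
  keys <- set_keys(set)
  rkeys <- paste(ref$model_label, ref$hbond_label)
  pos <- match(rkeys, keys)
  if (anyNA(pos))
    stop("reference error: unresolvable reference row(s): ",
         paste(rkeys[is.na(pos)], collapse = "; "), call. = FALSE)
  ## canonical row order: by position in the set, so the fit is invariant
  ## to the ordering of the reference table
  ord <- order(pos)
  pos <- pos[ord]
  y <- ref$E_ref[ord]
  predict_all <- build_predictor(set[pos], params, kappa)

  lam <- as.numeric(init)
  obj <- function(l) sum((predict_all(l) - y)^2)
  f0 <- obj(lam)
  rmsd_before <- sqrt(f0 / length(y))
  h <- 1e-6
  iterations <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    resid <- predict_all(lam) - y
    J <- vapply(1:4, function(k) {
      lp <- lam; lp[k] <- lp[k] + h
      (predict_all(lp) - resid - y) / h
    }, numeric(length(y)))
    step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(4), crossprod(J, resid)),
                     error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      cand <- lam - alpha * as.numeric(step)
      fc <- obj(cand)
      if (fc <= f0 || alpha < 1e-12) break
      alpha <- alpha / 2
    }
    if (fc > f0) break
    dec <- f0 - fc
    lam <- cand; f0 <- fc
    if (dec < tol) { converged <- TRUE; break }
  }
  structure(list(
    lambdas = lambda_params(lam[1], lam[2], lam[3], lam[4]),
    rmsd_before = rmsd_before,
    rmsd_after = sqrt(f0 / length(y)),
    iterations = iterations, converged = converged),
    class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  l <- x$lambdas
  cat(sprintf(paste0("<lambda_fit> HO=%.4f HH=%.4f OO=%.4f OH=%.4f\n",
                     "  RMSD %.4f -> %.4f kcal/mol (%d iterations, %s)\n"),
              l[["HO"]], l[["HH"]], l[["OO"]], l[["OH"]],
              x$rmsd_before, x$rmsd_after, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
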