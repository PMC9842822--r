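test_that("local dipoles follow the printed charges and the bond geometry", {
  p <- ff_params()
  dip <- compute_dipoles(wh_alpha_5, p)
  # |mu_CO| = (q_C - q_O) |r_C - r_O| / 2 with the 1.231 A carbonyl bond
  expected <- 0.5 * (0.5973 - (-0.5679)) * 1.231
  for (d in dip) {
    expect_equal(sqrt(sum(d$mu_CO^2)), expected, tolerance = 1e-9)
    expect_equal(sqrt(sum(d$mu_NH^2)), 0.5 * (0.2719 - (-0.4157)) * 1.010,
                 tolerance = 1e-9)
  }
  # orientation: mu_CO parallel to r_C - r_O (vanishing cross product,
  # positive projection)
  at <- wh_alpha_5$atoms
  rC <- unlist(at[at$resid == 0 & at$atom_name == "C", c("x", "y", "z")])
  rO <- unlist(at[at$resid == 0 & at$atom_name == "O", c("x", "y", "z")])
  bond <- rC - rO
  mu <- dip[["0"]]$mu_CO
  cross <- c(mu[2] * bond[3] - mu[3] * bond[2],
             mu[3] * bond[1] - mu[1] * bond[3],
             mu[1] * bond[2] - mu[2] * bond[1])
  expect_lt(max(abs(cross)), 1e-12)
  expect_gt(sum(mu * bond), 0)
  expect_length(dip, 6)  # groups 0..5 for ACE-(Ala)5-NME
  # equal charges give a null dipole
  dip0 <- compute_dipoles(wh_alpha_5, ff_params(q_C = -0.5679, q_O = -0.5679))
  expect_equal(max(abs(vapply(dip0, function(d) sqrt(sum(d$mu_CO^2)),
                              numeric(1)))), 0)
})

test_that("dipoles rotate with the structure", {
  th <- 1.1
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- wh_alpha_5
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")]) %*% rot
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
  d0 <- compute_dipoles(wh_alpha_5)
  d1 <- compute_dipoles(moved)
  for (k in names(d0))
    expect_equal(d1[[k]]$mu_CO, as.numeric(d0[[k]]$mu_CO %*% rot),
                 tolerance = 1e-12)
})

test_that("dipole-dipole interaction matches closed forms", {
  mu <- c(0, 0, 0.4)
  # parallel dipoles side by side, perpendicular to r: U = k m1 m2 / r^3
  r <- 3
  expect_equal(dipole_interaction(mu, c(0, 0, 0), mu, c(r, 0, 0), kappa = 1),
               0.16 / r^3)
  # collinear head-to-tail: U = -2 k m1 m2 / r^3
  expect_equal(dipole_interaction(mu, c(0, 0, 0), mu, c(0, 0, r), kappa = 1),
               -2 * 0.16 / r^3)
  # magic angle: 3 cos^2(theta) = 1 makes the interaction vanish
  ct <- 1 / sqrt(3)
  cvec <- r * c(sqrt(1 - ct^2), 0, ct)
  expect_lt(abs(dipole_interaction(mu, c(0, 0, 0), mu, cvec, kappa = 1)), 1e-12)
  # kappa scales linearly
  expect_equal(dipole_interaction(mu, c(0, 0, 0), mu, c(r, 0, 0), kappa = 332.0637),
               332.0637 * 0.16 / r^3)
  expect_error(dipole_interaction(mu, c(1, 1, 1), mu, c(1, 1, 1)), "coincident")
})

test_that("charge modifiers vanish at zero coupling and scale linearly", {
  d0 <- charge_deltas(wh_alpha_5, lambda_params())
  expect_true(all(abs(as.matrix(d0[, -1])) == 0))
  lam <- lambda_params(-2, 3, 1.5, -0.5)
  d1 <- charge_deltas(wh_alpha_5, lam, kappa = 1)
  d2 <- charge_deltas(wh_alpha_5, lambda_params(-4, 6, 3, -1), kappa = 1)
  expect_equal(as.matrix(d2[, -1]), 2 * as.matrix(d1[, -1]), tolerance = 1e-12)
  # terminal groups have no upstream/downstream neighbour
  expect_equal(d1$delta_H[d1$group == 0], 0)
  expect_equal(d1$delta_O[d1$group == max(d1$group)], 0)
})

test_that("charge modifiers equal a hand evaluation of the neighbour couplings", {
  lam <- lambda_params(1.25, -0.75, 2, 0.5)
  p <- ff_params()
  dip <- compute_dipoles(wh_310_4, p)
  d <- charge_deltas(wh_310_4, lam, p, kappa = 1)
  # group 2: delta_H from (NH_2, CO_1) and (NH_2, NH_1); delta_O from
  # (CO_2, CO_3) and (CO_2, NH_3)
  U <- function(a, fa, b, fb) dipole_interaction(
    dip[[a]][[paste0("mu_", fa)]], dip[[a]][[paste0("center_", fa)]],
    dip[[b]][[paste0("mu_", fb)]], dip[[b]][[paste0("center_", fb)]], kappa = 1)
  dH_hand <- 1.25 * U("2", "NH", "1", "CO") + (-0.75) * U("2", "NH", "1", "NH")
  dO_hand <- 2 * U("2", "CO", "3", "CO") + 0.5 * U("2", "CO", "3", "NH")
  expect_equal(d$delta_H[d$group == 2], dH_hand, tolerance = 1e-12)
  expect_equal(d$delta_O[d$group == 2], dO_hand, tolerance = 1e-12)
  # neutrality constraints hold exactly
  q0 <- p$q0
  expect_equal(d$delta_N * q0[["N"]], -d$delta_H * q0[["H"]])
  expect_equal(d$delta_C * q0[["C"]], -d$delta_O * q0[["O"]])
})

test_that("every peptide group's total charge is conserved under any coupling", {
  lam <- lambda_params(-11.535, 38.517, 16.967, 4.587)
  for (kappa in c(1, 332.0637)) {
    q0 <- helixhb:::atom_charges(wh_alpha_5, ff_params())
    q1 <- helixhb:::modified_charges(wh_alpha_5, lam, ff_params(), kappa)
    at <- wh_alpha_5$atoms
    for (k in 0:5) {
      grp <- (at$resid == k & at$atom_name %in% c("C", "O")) |
             (at$resid == k + 1 & at$atom_name %in% c("N", "H"))
      # machine precision relative to the modified-charge magnitudes
      # (delta * q can reach ~30 e under the kcal/mol coupling convention)
      expect_lt(abs(sum(q1[grp]) - sum(q0[grp])), 1e-13)
    }
  }
})

test_that("the modified H-bond energy reduces to MM at zero coupling and matches brute force", {
  for (case in list(list(s = wh_alpha_5, l = "5-2"),
                    list(s = wh_310_4, l = "4-1"))) {
    hb <- find_hbond(case$s, case$l)
    e_mm <- mm_hbond_energy(case$s, hb)
    e_0 <- modified_mm_hbond_energy(case$s, hb, lambda_params())
    expect_identical(as.numeric(e_0), as.numeric(e_mm))
    lam <- lambda_params(-11.535, 38.517, 16.967, 4.587)
    q_mod <- helixhb:::modified_charges(case$s, lam, ff_params(), kappa = 1)
    e_mod <- modified_mm_hbond_energy(case$s, hb, lam, kappa = 1)
    expect_equal(as.numeric(e_mod),
                 brute_hbond_energy(case$s, hb, charges = q_mod),
                 tolerance = 1e-12)
    expect_identical(attr(e_mod, "provenance"), "mm_modified")
  }
})

test_that("charge modifiers are invariant under rigid-body motion", {
  lam <- lambda_params(3, -1, 2, 0.7)
  d0 <- charge_deltas(wh_310_4, lam, kappa = 1)
  th <- -0.4
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- wh_310_4
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")]) %*% rot
  moved$atoms$x <- xyz[, 1] - 8; moved$atoms$y <- xyz[, 2] + 2
  moved$atoms$z <- xyz[, 3] + 11
  d1 <- charge_deltas(moved, lam, kappa = 1)
  expect_equal(as.matrix(d1[, -1]), as.matrix(d0[, -1]), tolerance = 1e-10)
})
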