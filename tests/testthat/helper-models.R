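# Shared fixtures, built once per test run. All structures are generated
# in code; nothing is read from disk.

wh_alpha_5 <- build_wh_model(5, helix_spec("alpha"))
wh_310_4 <- build_wh_model(4, helix_spec("three_ten"))

paper_lambdas <- lambda_params(-11.535, 38.517, 16.967, 4.587)

# Independent brute-force 16-term pair sum used as the energy oracle:
# deliberately written scalar-by-scalar, independent of the package's
# vectorized path.
brute_hbond_energy <- function(structure, hbond, params = ff_params(),
                               charges = NULL) {
  at <- structure$atoms
  find1 <- function(ref) {
    p <- strsplit(ref, ":")[[1]]
    which(at$resid == as.integer(p[1]) & at$atom_name == p[2])
  }
  q_of <- function(i) {
    if (!is.null(charges)) return(charges[i])
    key <- helixhb:::atom_key(at$resname[i], at$atom_name[i])
    params$charges[[key]]
  }
  lj_of <- function(i) {
    key <- helixhb:::atom_key(at$resname[i], at$atom_name[i])
    t <- params$type_of[[key]]
    r <- params$lj[params$lj$type == t, ]
    c(r$rmin2, r$eps)
  }
  e <- 0
  for (an in c("C", "O", "N", "H")) for (dn in c("C", "O", "N", "H")) {
    i <- find1(hbond$acceptor_unit[[an]])
    j <- find1(hbond$donor_unit[[dn]])
    dx <- at$x[i] - at$x[j]; dy <- at$y[i] - at$y[j]; dz <- at$z[i] - at$z[j]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    li <- lj_of(i); lj <- lj_of(j)
    rmin <- li[1] + lj[1]; eps <- sqrt(li[2] * lj[2])
    e <- e + params$coulomb_constant * q_of(i) * q_of(j) / r +
      eps * rmin^12 / r^12 - 2 * eps * rmin^6 / r^6
  }
  e
}
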