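# CVS-CIS: sigma vector, Davidson solver, symmetry and consistency

test_that("sigma applied to unit vectors reproduces the dense CIS matrix", {
  ref <- cached_ref("h2o")
  sp <- partition_orbitals(ref, "O")
  df <- assemble_J(ref, sp)
  asys <- adc_system(df, "cvs")
  A <- cis_matrix(asys)
  n <- nrow(A)
  for (k in seq_len(n)) {
    e <- numeric(n); e[k] <- 1
    expect_lt(max(abs(as.vector(cis_sigma(e, asys)) - A[, k])), 1e-12)
  }
})

test_that("orbital-energy limit: without coupling sigma is diagonal", {
  # a 1x1 singles space reduces solve_cis to the single diagonal element
  ref <- cached_ref("h2")
  df <- assemble_J(ref, full_space(ref))
  asys <- adc_system(df, "full")
  A <- cis_matrix(asys)
  cis <- solve_cis(asys, 1)
  expect_equal(cis$omega[1], A[1, 1], tolerance = 1e-10)
})

test_that("H2 singlet CIS equals the closed-form two-level expression", {
  ref <- cached_ref("h2")
  df <- exact_df(ref, full_space(ref))
  asys <- adc_system(df, "full")
  g <- rcadc:::.oracle_mo_eri(ref, 1:2)
  cf <- two_level_closed_forms(ref$eps[1], ref$eps[2],
                               g[1, 2, 1, 2], g[1, 1, 2, 2])
  expect_equal(solve_cis(asys, 1)$omega[1], cf$omega_cis, tolerance = 1e-12)
})

test_that("Davidson eigenvalues match dense diagonalisation on fixtures", {
  for (fx in c("h2o", "co")) {
    ref <- cached_ref(fx)
    el <- intersect(c("O", "C"), ref$molecule$atoms)[1]
    sp <- partition_orbitals(ref, el)
    asys <- adc_system(assemble_J(ref, sp), "cvs")
    A <- cis_matrix(asys)
    dense <- sort(eigen(A, symmetric = TRUE)$values)
    n <- min(nrow(A), 3L)
    cis <- solve_cis(asys, n)
    expect_equal(cis$omega, dense[seq_len(n)], tolerance = 1e-10)
  }
  expect_error(solve_cis(adc_system(assemble_J(
    cached_ref("h2o"), partition_orbitals(cached_ref("h2o"), "O")), "cvs"),
    1000), "exceeds")
})

test_that("the CIS response is Hermitian", {
  ref <- cached_ref("nh3")
  sp <- partition_orbitals(ref, "N")
  asys <- adc_system(assemble_J(ref, sp), "cvs")
  n <- length(asys$occs) * asys$nv
  set.seed(11)
  for (rep in 1:5) {
    u <- rnorm(n); v <- rnorm(n)
    expect_equal(sum(u * cis_sigma(v, asys)), sum(v * cis_sigma(u, asys)),
                 tolerance = 1e-12)
  }
})

test_that("symmetry-degenerate and near-degenerate CIS pairs", {
  # CO 1s->pi*(x,y): exactly degenerate by angular momentum
  ref <- cached_ref("co")
  sp <- partition_orbitals(ref, "C")
  asys <- adc_system(assemble_J(ref, sp), "cvs")
  cis <- solve_cis(asys, 2)
  expect_lt(abs(cis$omega[2] - cis$omega[1]), 1e-9)
  # ethene: the 1sigma_g/1sigma_u core pair splits only by core hopping
  ref2 <- cached_ref("c2h4")
  sp2 <- partition_orbitals(ref2, "C")
  cis2 <- solve_cis(adc_system(assemble_J(ref2, sp2), "cvs"), 2)
  expect_lt(abs(cis2$omega[2] - cis2$omega[1]) * hartree_to_ev, 0.05)
})

test_that("enlarging the active core to all occupieds recovers full CIS", {
  ref <- cached_ref("h2o")
  df_full <- assemble_J(ref, full_space(ref))
  asys_full <- adc_system(df_full, "cvs")   # every occupied is "core"
  A <- cis_matrix(adc_system(df_full, "full"))
  dense <- sort(eigen(A, symmetric = TRUE)$values)
  expect_equal(solve_cis(asys_full, 3)$omega, dense[1:3], tolerance = 1e-9)
})
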