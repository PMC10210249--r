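# ADC(2): MP2 intermediates, omega-dependent sigma, folded solver, and the
# perturbation-order consistency oracle

test_that("two-level MP2 energy matches the closed form exactly", {
  ref <- cached_ref("h2")
  df <- exact_df(ref, full_space(ref))
  asys <- adc_system(df, "full")
  mp2 <- mp2_intermediates(asys)
  g <- rcadc:::.oracle_mo_eri(ref, 1:2)
  cf <- two_level_closed_forms(ref$eps[1], ref$eps[2],
                               g[1, 2, 1, 2], g[1, 1, 2, 2])
  expect_equal(mp2$e_mp2, cf$e_mp2, tolerance = 1e-12)
})

test_that("MP2 energy agrees with an independent dense spatial evaluation", {
  ref <- cached_ref("h2o")
  mp2x <- mp2_intermediates(adc_system(exact_df(ref, full_space(ref)), "full"))
  df <- assemble_J(ref, full_space(ref))
  mp2 <- mp2_intermediates(adc_system(df, "full"))
  # spatial-orbital closed-shell MP2 from dense integrals, no DF
  g <- rcadc:::.oracle_mo_eri(ref, seq_len(ref$n_ao))
  no <- ref$n_occ; nv <- ref$n_ao - no
  e2 <- 0
  for (i in 1:no) for (j in 1:no) for (a in 1:nv) for (b in 1:nv) {
    iajb <- g[i, no + a, j, no + b]
    ibja <- g[i, no + b, j, no + a]
    e2 <- e2 + iajb * (2 * iajb - ibja) /
      (ref$eps[i] + ref$eps[j] - ref$eps[no + a] - ref$eps[no + b])
  }
  # the spin-orbital machinery must match the closed-shell spatial formula
  # exactly at identical integrals; the fitted tensor then carries only the
  # fitting error
  expect_equal(mp2x$e_mp2, e2, tolerance = 1e-10)
  expect_lt(abs(mp2$e_mp2 - e2), 2e-4)
})

test_that("decoupling limits of the sigma vector", {
  ref <- cached_ref("h2o")
  sp <- partition_orbitals(ref, "O")
  asys <- adc_system(assemble_J(ref, sp), "cvs")
  mp2 <- mp2_intermediates(asys)
  cis <- solve_cis(asys, 1)
  r <- cis$vectors[, 1]
  # all second-order terms off: sigma = omega_CIS * r for a converged CIS state
  s0 <- sigma_vector(r, cis$omega[1], asys, mp2, include = character(0))
  expect_equal(as.vector(s0), cis$omega[1] * r, tolerance = 1e-9)
  # linearity at fixed omega
  set.seed(3)
  n <- length(r)
  u <- rnorm(n); v <- rnorm(n)
  om <- cis$omega[1] + 0.05
  s_lin <- sigma_vector(2 * u - 3 * v, om, asys, mp2)
  s_sep <- 2 * sigma_vector(u, om, asys, mp2) -
    3 * sigma_vector(v, om, asys, mp2)
  expect_lt(max(abs(s_lin - s_sep)), 1e-12)
  # Hermiticity of the effective Jacobian at fixed omega
  expect_equal(sum(u * sigma_vector(v, om, asys, mp2)),
               sum(v * sigma_vector(u, om, asys, mp2)), tolerance = 1e-11)
})

test_that("doubles coefficients respect the CVS restriction and poles error", {
  ref <- cached_ref("h2o")
  sp <- partition_orbitals(ref, "O")
  asys <- adc_system(assemble_J(ref, sp), "cvs")
  cis <- solve_cis(asys, 1)
  g <- doubles_coefficients(cis$vectors[, 1], cis$omega[1], asys)
  # exactly one active-core occupied index per double
  core2 <- asys$core2
  for (k in seq_len(asys$no2)) for (l in seq_len(asys$no2))
    if (!xor(core2[k], core2[l]))
      expect_true(all(g[k, l, , ] == 0))
  b <- rcadc:::.fold_b(asys, rcadc:::.embed_singlet(asys, cis$vectors[, 1]))
  hit <- which(abs(b) > 1e-3, arr.ind = TRUE)[1, ]
  pole <- asys$delta[hit[1], hit[2], hit[3], hit[4]]
  expect_error(doubles_coefficients(cis$vectors[, 1], pole, asys), "pole")
})

test_that("folded solver energies are eigenvalues of the explicit matrix", {
  ref <- cached_ref("h2o")
  sp <- partition_orbitals(ref, "O")
  df <- assemble_J(ref, sp)
  asys <- adc_system(df, "cvs")
  mp2 <- mp2_intermediates(asys)
  cis <- solve_cis(asys, 2)
  states <- solve_adc2(asys, mp2, cis, e_tol = 1e-9, r_tol = 1e-7)
  dm <- dense_adc2_matrix(ref, sp, "cvs", eri = df)
  evals <- eigen((dm$M + t(dm$M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  for (st in states)
    expect_lt(min(abs(evals - st$omega)), 1e-8)
  # self-consistency at convergence: omega = <r, sigma(r, omega)>
  for (st in states) {
    rq <- sum(st$r * sigma_vector(st$r, st$omega, asys, mp2))
    expect_equal(rq, st$omega, tolerance = 2e-6)
  }
})

test_that("with second-order terms zeroed the solver returns CIS energies", {
  ref <- cached_ref("co")
  sp <- partition_orbitals(ref, "C")
  asys <- adc_system(assemble_J(ref, sp), "cvs")
  mp2 <- mp2_intermediates(asys)
  mp2z <- mp2
  mp2z$M2sp <- 0 * mp2z$M2sp
  mp2z$t2 <- 0 * mp2z$t2
  asys_z <- asys
  asys_z$OOOV <- 0 * asys_z$OOOV   # kills the coupling
  asys_z$OVVV <- 0 * asys_z$OVVV
  cis <- solve_cis(asys, 2)
  st <- solve_adc2(asys_z, mp2z, cis)
  expect_equal(vapply(st, function(s) s$omega, 0), cis$omega,
               tolerance = 1e-8)
})

test_that("ADC(2) excitation energies are exact through second order", {
  # coupling-strength scaling H(s) = h + s W with a self-consistent
  # reference: the ADC(2)-vs-FCI deviation of singly-excited states must
  # shrink as s^3 (ratio ~ 8 when s doubles)
  h4 <- molecule(rep("H", 4), cbind(0, 0, c(0, 0.9, 2.0, 3.1)))
  delta <- matrix(NA_real_, 2, 3)
  for (li in 1:2) {
    s <- c(0.1, 0.2)[li]
    ref <- compute_reference(h4, "sto-3g", two_electron_scale = s)
    f <- fci_oracle(ref)
    sp <- full_space(ref)
    dm <- dense_adc2_matrix(ref, sp, "full")
    ev <- eigen((dm$M + t(dm$M)) / 2, symmetric = TRUE)
    ord <- order(ev$values)
    vals <- ev$values[ord]; vecs <- ev$vectors[, ord, drop = FALSE]
    ns <- dm$n_singles
    w <- colSums(vecs[seq_len(ns), , drop = FALSE]^2)
    idx <- which(w > 0.5)
    for (k in 1:3) {
      rvec <- vecs[seq_len(ns), idx[k + 1]]  # states 2-4: clean cubic decay
      v <- numeric(length(f$dets))
      for (s1 in seq_len(ns))
        v <- v + rvec[s1] * f$singles_csf(dm$singles$i[s1], dm$singles$a[s1])
      root <- which.max(abs(crossprod(f$vectors, v)))
      delta[li, k] <- vals[idx[k + 1]] - (f$energies[root] - f$energies[1])
    }
  }
  ratio <- delta[2, ] / delta[1, ]
  expect_true(all(abs(delta[1, ]) < 5e-3))
  expect_true(all(ratio > 6 & ratio < 10))
})

test_that("amplitudes never reference frozen orbitals", {
  ref <- cached_ref("h2co")
  sp <- partition_orbitals(ref, "O")        # C 1s frozen
  df <- assemble_J(ref, sp)
  asys <- adc_system(df, "cvs")
  # the frozen orbital is simply absent from the tensor dimensions
  expect_identical(asys$no, ref$n_occ - 1L)
  expect_identical(dim(mp2_intermediates(asys)$t2)[1], 2L * (ref$n_occ - 1L))
})
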