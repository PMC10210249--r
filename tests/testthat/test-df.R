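# density fitting: metric, three-center tensor, ERI reconstruction

test_that("metric inverse square root has closed-form and product behaviour", {
  expect_equal(metric_inverse_sqrt(diag(3)), diag(3), tolerance = 1e-13)
  expect_equal(metric_inverse_sqrt(diag(c(4, 9))), diag(c(1 / 2, 1 / 3)),
               tolerance = 1e-13)
  set.seed(7)
  A <- matrix(rnorm(36), 6)
  V <- crossprod(A) + diag(6)      # SPD
  W <- metric_inverse_sqrt(V)
  expect_lt(max(abs(t(W) %*% V %*% W - diag(6))), 1e-11)
  expect_error(metric_inverse_sqrt(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(metric_inverse_sqrt(diag(c(1e-14, 1e-15))), "degenerate")
})

test_that("DF reconstruction approximates dense ERIs on H2", {
  ref <- cached_ref("h2")
  sp <- full_space(ref)
  df <- assemble_J(ref, sp)
  g_dense <- rcadc:::.oracle_mo_eri(ref, 1:2)
  g_df <- rcadc:::.df_mo_eri(df)
  expect_lt(max(abs(g_df - g_dense)), 1e-3)
})

test_that("reconstructed ERIs are exactly symmetric under pq <-> rs", {
  ref <- cached_ref("h2o")
  sp <- partition_orbitals(ref, "O")
  df <- assemble_J(ref, sp)
  n <- df$n_mo
  set.seed(1)
  for (rep in 1:20) {
    idx <- sample(n, 4, replace = TRUE)
    expect_identical(reconstruct_eri(df, idx[1], idx[2], idx[3], idx[4]),
                     reconstruct_eri(df, idx[3], idx[4], idx[1], idx[2]))
  }
  expect_error(reconstruct_eri(df, 0, 1, 1, 1), "outside")
})

test_that("metric-dressed tensor agrees with the independent contraction order", {
  # (pq|rs) ~ (pq|P) (V^-1)_PQ (Q|rs), contracted without the J factorisation
  ref <- cached_ref("h2")
  sp <- full_space(ref)
  df <- assemble_J(ref, sp)
  V2 <- rcadc:::.ao_eri_2c(ref$aux_shells)
  B <- rcadc:::.ao_eri_3c(ref$shells, ref$aux_shells)
  nao <- ref$n_ao; naux <- nrow(V2)
  C <- ref$C
  Bm <- matrix(B, nao * nao, naux)
  # MO transform of (mu nu|P)
  Bmo <- matrix(0, nao * nao, naux)
  for (P in seq_len(naux))
    Bmo[, P] <- as.vector(crossprod(C, matrix(Bm[, P], nao, nao) %*% C))
  Vinv <- solve(V2)
  G_ref <- Bmo %*% Vinv %*% t(Bmo)
  G_J <- tcrossprod(df$J)
  expect_lt(max(abs(G_ref - G_J)), 1e-10)
})

test_that("degenerate limiting cases of the reconstruction", {
  df0 <- structure(list(J = matrix(0, 4, 3), n_mo = 2, n_Q = 3),
                   class = "rcadc_df")
  expect_identical(reconstruct_eri(df0, 1, 2, 2, 1), 0)
  # rank-1 J: reconstruction is the product of the two slice values
  J1 <- matrix(c(1, 2, 2, 4), 4, 1)
  df1 <- structure(list(J = J1, n_mo = 2, n_Q = 1), class = "rcadc_df")
  expect_equal(reconstruct_eri(df1, 1, 1, 2, 2), J1[1] * J1[4])
})

test_that("DF error in CVS-CIS energies is below 2 meV on fixtures", {
  for (fx in c("h2o", "co")) {
    ref <- cached_ref(fx)
    el <- intersect(c("C", "O"), ref$molecule$atoms)[1]
    sp <- partition_orbitals(ref, el)
    df <- assemble_J(ref, sp)
    w_df <- solve_cis(adc_system(df, "cvs"), 2)$omega
    dfx <- exact_df(ref, sp)
    w_dense <- solve_cis(adc_system(dfx, "cvs"), 2)$omega
    expect_lt(max(abs(w_df - w_dense)) * hartree_to_ev, 2e-3)
  }
})
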