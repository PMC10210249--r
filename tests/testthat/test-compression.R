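# NAF and VNO compression machinery

test_that("NAF singular values match a direct SVD of the unfolded tensor", {
  set.seed(21)
  J <- matrix(rnorm(9 * 8), 9, 8)      # (pq) x Q
  df <- structure(list(J = J, n_mo = 3, n_Q = 8), class = "rcadc_df")
  naf <- build_naf(df, 0)
  sv <- svd(J)$d
  expect_equal(sqrt(naf$importance[seq_along(sv)]), sv, tolerance = 1e-11)
  expect_identical(naf$n_kept, 8L)
})

test_that("NAF rotation at eps = 0 leaves reconstructed ERIs unchanged", {
  ref <- cached_ref("h2o")
  sp <- partition_orbitals(ref, "O")
  df <- assemble_J(ref, sp)
  naf <- build_naf(df, 0)
  df2 <- apply_naf(df, naf)
  expect_lt(max(abs(tcrossprod(df$J) - tcrossprod(df2$J))), 1e-12)
})

test_that("a rank-1 tensor keeps exactly one NAF", {
  u <- c(1, -2, 0.5, 3)
  w <- c(2, 1, 0.25)
  df <- structure(list(J = outer(u, w), n_mo = 2, n_Q = 3),
                  class = "rcadc_df")
  naf <- build_naf(df, 1e-6)
  expect_identical(naf$n_kept, 1L)
})

test_that("discarded Frobenius weight equals the dropped W eigenvalues", {
  set.seed(5)
  for (rep in 1:3) {
    J <- matrix(rnorm(16 * 10), 16, 10)
    df <- structure(list(J = J, n_mo = 4, n_Q = 10), class = "rcadc_df")
    eps <- 1.0
    naf <- build_naf(df, eps)
    Jk <- J %*% naf$rotation %*% t(naf$rotation)
    dropped <- sum(naf$importance[sqrt(pmax(naf$importance, 0)) < eps])
    expect_equal(sum((J - Jk)^2), dropped, tolerance = 1e-10)
  }
})

test_that("MP2 density on H2 equals the closed-form virtual occupation", {
  ref <- cached_ref("h2")
  df <- exact_df(ref, full_space(ref))
  asys <- adc_system(df, "full")
  mp2 <- mp2_intermediates(asys)
  D <- mp2_vv_density(asys, mp2)
  g <- rcadc:::.oracle_mo_eri(ref, 1:2)
  t_cf <- two_level_closed_forms(ref$eps[1], ref$eps[2],
                                 g[1, 2, 1, 2], g[1, 1, 2, 2])$t
  expect_equal(D[1, 1], 2 * t_cf^2, tolerance = 1e-12)
})

test_that("MP2 density is PSD and shrinks when the gap is widened", {
  ref <- cached_ref("h2o")
  df <- assemble_J(ref, full_space(ref))
  asys <- adc_system(df, "full")
  D <- mp2_vv_density(asys, mp2_intermediates(asys))
  expect_lt(max(abs(D - t(D))), 1e-12)
  expect_gt(min(eigen(D, symmetric = TRUE)$values), -1e-10)
  tr0 <- sum(diag(D))
  for (shift in c(0.5, 1.0)) {
    asys_s <- asys
    asys_s$eps_v2 <- asys$eps_v2 + shift
    asys_s$delta <- asys$delta + 2 * shift
    tr1 <- sum(diag(mp2_vv_density(asys_s, mp2_intermediates(asys_s))))
    expect_lt(tr1, tr0)
    tr0 <- tr1
  }
})

test_that("CIS(D) density: CIS term is a trace-1 outer product", {
  ref <- cached_ref("h2o")
  sp <- partition_orbitals(ref, "O")
  asys <- adc_system(assemble_J(ref, sp), "cvs")
  cis <- solve_cis(asys, 1)
  r <- matrix(cis$vectors[, 1], 1, asys$nv)
  D0 <- cisd_vv_density(asys, r, cis$omega[1], include_doubles = FALSE)
  expect_equal(sum(diag(D0)), 1, tolerance = 1e-12)
  expect_equal(D0, crossprod(r), tolerance = 1e-12)
  D1 <- cisd_vv_density(asys, r, cis$omega[1])
  expect_lt(max(abs(D1 - t(D1))), 1e-12)
  expect_error(cisd_vv_density(asys, 2 * r, cis$omega[1]), "normalised")
})

test_that("state averaging is an equal-weight elementwise mean", {
  A <- matrix(c(2, 1, 1, 4), 2)
  B <- matrix(0, 2, 2)
  expect_equal(state_averaged_density(A, A)$D, A)
  expect_equal(state_averaged_density(A, B)$D, A / 2)
  expect_error(state_averaged_density(A, diag(3)), "mismatch")
  # eigenvalue interlacing sanity
  set.seed(9)
  X <- crossprod(matrix(rnorm(25), 5)); Y <- crossprod(matrix(rnorm(25), 5))
  avg <- state_averaged_density(X, Y)$D
  expect_lte(max(eigen(avg)$values),
             mean(c(max(eigen(X)$values), max(eigen(Y)$values))) + 1e-10)
})

test_that("VNO truncation bookkeeping and threshold behaviour", {
  D <- diag(c(1e-3, 1e-6))
  vno <- build_vno(D, 7.5e-5, eps_v = c(0.5, 1.5))
  expect_identical(vno$n_kept, 1L)
  expect_equal(vno$pct_kept, 50)
  expect_error(build_vno(D, 10, eps_v = c(0.5, 1.5)), "every virtual")
  # eps = 0 keeps everything and semicanonicalisation recovers the Fock
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  D2 <- Q %*% diag(c(0.5, 0.1, 0.01, 1e-4)) %*% t(Q)
  eps_v <- c(0.2, 0.4, 0.9, 1.7)
  v0 <- build_vno(D2, 0, eps_v)
  expect_identical(v0$n_kept, 4L)
  expect_equal(v0$eps, eps_v, tolerance = 1e-12)
  F_rot <- crossprod(v0$rotation, v0$rotation * eps_v)
  expect_lt(max(abs(F_rot - diag(v0$eps))), 1e-10)
})

test_that("second NAF truncation never enlarges and usually shrinks", {
  ref <- cached_ref("h2o", "6-31g")
  sp <- partition_orbitals(ref, "O")
  df <- assemble_J(ref, sp)
  naf1 <- build_naf(df, 0.1)
  df1 <- apply_naf(df, naf1)
  asys <- adc_system(df1, "cvs")
  mp2 <- mp2_intermediates(asys)
  cis <- solve_cis(asys, 1)
  d_mp2 <- mp2_vv_density(asys, mp2)
  red <- reduce_state(df1, asys, mp2, d_mp2, cis$vectors[, 1], cis$omega[1],
                      7.5e-5, 0.1)
  expect_lte(red$df$n_Q, naf1$n_kept)
  expect_lt(red$df$n_Q, df$n_Q)      # strictly below the canonical n_Q
})
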