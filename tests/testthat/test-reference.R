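# Hartree-Fock reference and CVS orbital partition

test_that("H2 in a two-function basis reproduces the closed-form RHF energy", {
  ref <- cached_ref("h2")
  # symmetry fixes the occupied MO: (chi1 + chi2)/sqrt(2(1+S12));
  # evaluate the RHF energy from the AO integrals directly
  shells <- ref$shells
  ints <- rcadc:::.ao_oneints(shells, ref$molecule$xyz_bohr, ref$molecule$z)
  S12 <- ints$S[1, 2]
  c1 <- 1 / sqrt(2 * (1 + S12))
  h <- ints$T + ints$V
  g <- rcadc:::.ao_eri_dense(shells)
  cvec <- c(c1, c1)
  h11 <- sum(outer(cvec, cvec) * h)
  J11 <- 0
  for (m in 1:2) for (n in 1:2) for (l in 1:2) for (s in 1:2)
    J11 <- J11 + cvec[m] * cvec[n] * cvec[l] * cvec[s] * g[m, n, l, s]
  e_closed <- 2 * h11 + J11 + nuclear_repulsion(ref$molecule)
  expect_equal(ref$energy, e_closed, tolerance = 1e-10)
  expect_identical(ref$n_occ, 1L)
})

test_that("electron counting and core identification on the water fixture", {
  ref <- cached_ref("h2o")
  expect_identical(ref$n_occ, 5L)
  # the lowest canonical MO is the O 1s: ~ -20 Hartree scale
  expect_lt(ref$eps[1], -18)
  expect_gt(ref$eps[1], -22)
  sp <- partition_orbitals(ref, "O")
  expect_identical(length(sp$active_core), 1L)
  expect_identical(length(sp$inactive_occupied), 4L)
  expect_identical(length(sp$frozen_core), 0L)
})

test_that("a single-function basis with no virtuals is refused", {
  he <- fixture_molecule("he")
  expect_error(compute_reference(he, "sto-3g"), "no virtual")
})

test_that("two equivalent carbons give two active-core orbitals", {
  ref <- cached_ref("c2h4")
  sp <- partition_orbitals(ref, "C")
  expect_identical(length(sp$active_core), 2L)
})

test_that("freeze-other-cores policy removes the spectator core", {
  ref <- cached_ref("h2co")
  sp_o <- partition_orbitals(ref, "O")
  expect_identical(length(sp_o$frozen_core), 1L)   # the C 1s
  expect_identical(length(sp_o$active_core), 1L)
  sp_o2 <- partition_orbitals(ref, "O", frozen_policy = "none")
  expect_identical(length(sp_o2$frozen_core), 0L)
  # frozen orbital is absent from every correlated tensor
  df <- assemble_J(ref, sp_o)
  expect_identical(df$n_occ, ref$n_occ - 1L)
})

test_that("the CVS partition is complete and disjoint on every fixture", {
  for (fx in c("h2o", "nh3", "co", "hf", "ch4", "c2h4", "h2co")) {
    ref <- cached_ref(fx)
    el <- intersect(c("C", "N", "O", "F"), ref$molecule$atoms)[1]
    sp <- partition_orbitals(ref, el)
    all_idx <- sort(c(sp$frozen_core, sp$active_core,
                      sp$inactive_occupied, sp$virtual))
    expect_identical(all_idx, seq_len(ref$n_ao))
    expect_length(unique(all_idx), ref$n_ao)
    expect_gt(length(sp$active_core), 0L)
  }
})

test_that("selector errors are explicit", {
  ref <- cached_ref("h2o")
  expect_error(partition_orbitals(ref, "N"), "not present")
})
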