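# transition moments and oscillator strengths

test_that("transition density matches exact determinant algebra", {
  ref <- cached_ref("h4")
  df <- assemble_J(ref, full_space(ref))
  asys <- adc_system(df, "full")
  mp2 <- mp2_intermediates(asys)
  cis <- solve_cis(asys, 1)
  st <- solve_adc2(asys, mp2, cis, states = 1)[[1]]
  blocks <- rcadc:::transition_density_blocks(asys, mp2, st$r, st$omega)
  det <- det_transition_density(ref, asys, mp2, st$r, st$omega)
  expect_lt(max(abs(det$ov - blocks$ov)), 1e-12)
  expect_lt(max(abs(det$vo - blocks$vo)), 1e-12)
  # oo/vv agree up to cubic orthogonalisation remainders
  expect_lt(max(abs(det$oo - blocks$oo)), 1e-4)
  expect_lt(max(abs(det$vv - blocks$vv)), 1e-4)
})

test_that("CIS-order density reproduces the dense CIS oscillator strength", {
  ref <- cached_ref("h2o")
  sp <- partition_orbitals(ref, "O")
  dfx <- exact_df(ref, sp)
  asys <- adc_system(dfx, "cvs")
  mp2 <- mp2_intermediates(asys)
  cis <- solve_cis(asys, 2)
  for (k in 1:2) {
    fake <- structure(list(omega = cis$omega[k],
                           r = matrix(cis$vectors[, k], 1, asys$nv),
                           converged = TRUE),
                      class = "rcadc_state")
    mom <- oscillator_strength(fake, asys, mp2, order = "cis")
    # dense oracle: f = 2/3 omega |sqrt(2) sum r mu|^2 from exact MO dipoles
    mu <- vapply(dfx$dip, function(m) {
      sqrt(2) * sum(matrix(cis$vectors[, k], 1, asys$nv) *
                    m[asys$occs, asys$no + seq_len(asys$nv), drop = FALSE])
    }, 0)
    f_ref <- 2 / 3 * cis$omega[k] * sum(mu^2)
    expect_equal(mom$f, f_ref, tolerance = 1e-8)
  }
})

test_that("a symmetry-forbidden core transition carries no intensity", {
  # ethene C K-edge: the gerade member of the 1s pair is dipole-forbidden
  ref <- cached_ref("c2h4")
  sp <- partition_orbitals(ref, "C")
  df <- assemble_J(ref, sp)
  asys <- adc_system(df, "cvs")
  mp2 <- mp2_intermediates(asys)
  cis <- solve_cis(asys, 2)
  st <- solve_adc2(asys, mp2, cis)
  f <- vapply(st, function(s) oscillator_strength(s, asys, mp2)$f, 0)
  expect_lt(min(f), 1e-8)
  expect_gte(min(f), 0)
})

test_that("oscillator strengths are invariant under rigid translation", {
  base <- fixture_molecule("h2o")
  shifted <- molecule(base$atoms, base$xyz + 5)
  f_of <- function(mol) {
    ref <- compute_reference(mol, "sto-3g")
    sp <- partition_orbitals(ref, "O")
    asys <- adc_system(assemble_J(ref, sp), "cvs")
    mp2 <- mp2_intermediates(asys)
    st <- solve_adc2(asys, mp2, solve_cis(asys, 2))
    vapply(st, function(s) oscillator_strength(s, asys, mp2)$f, 0)
  }
  expect_lt(max(abs(f_of(base) - f_of(shifted))), 1e-8)
})

test_that("summed intensity of a degenerate pair is rotation invariant", {
  base <- fixture_molecule("co")
  th <- 0.61
  Rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rot2 <- rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  rotated <- molecule(base$atoms, base$xyz %*% t(Rot2 %*% Rot))
  fsum_of <- function(mol) {
    ref <- compute_reference(mol, "sto-3g")
    sp <- partition_orbitals(ref, "O")
    asys <- adc_system(assemble_J(ref, sp), "cvs")
    mp2 <- mp2_intermediates(asys)
    st <- solve_adc2(asys, mp2, solve_cis(asys, 2))
    sum(vapply(st, function(s) oscillator_strength(s, asys, mp2)$f, 0))
  }
  expect_lt(abs(fsum_of(base) - fsum_of(rotated)), 1e-8)
})

test_that("unconverged states are refused", {
  ref <- cached_ref("h2")
  df <- assemble_J(ref, full_space(ref))
  asys <- adc_system(df, "full")
  mp2 <- mp2_intermediates(asys)
  bad <- structure(list(omega = 0.5, r = matrix(1, 1, 1), converged = FALSE),
                   class = "rcadc_state")
  expect_error(oscillator_strength(bad, asys, mp2), "not converged")
})
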