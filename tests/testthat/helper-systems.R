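# shared, lazily computed references (SCF is deterministic, so caching is
# safe across tests)

.sys_cache <- new.env(parent = emptyenv())

cached_ref <- function(name, basis = "sto-3g", ...) {
  key <- paste(name, basis, ...)
  if (!exists(key, .sys_cache)) {
    mol <- if (name == "h2") {
      molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74085)))
    } else if (name == "h4") {
      molecule(rep("H", 4), cbind(0, 0, c(0, 0.9, 2.0, 3.1)))
    } else fixture_molecule(name)
    assign(key, compute_reference(mol, basis, ...), .sys_cache)
  }
  get(key, .sys_cache)
}

# an exact "density-fitted" tensor: factorise the dense MO ERI matrix so the
# DF reconstruction reproduces four-center integrals to machine precision
exact_df <- function(ref, space) {
  occ <- sort(c(space$active_core, space$inactive_occupied))
  mos <- c(occ, space$virtual)
  g <- rcadc:::.oracle_mo_eri(ref, mos)
  n <- length(mos)
  G <- matrix(g, n * n, n * n)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- ev$values > 1e-12
  J <- ev$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev$values[keep]), sum(keep))
  dip <- lapply(list(x = 1, y = 2, z = 3), function(k) {
    m <- list(ref$dipole_ao$x, ref$dipole_ao$y, ref$dipole_ao$z)[[k]]
    crossprod(ref$C[, mos, drop = FALSE], m %*% ref$C[, mos, drop = FALSE])
  })
  structure(list(J = J, n_mo = n, n_Q = ncol(J), dip = dip,
                 n_occ = length(occ), n_virt = length(space$virtual),
                 core_pos = match(sort(space$active_core), occ),
                 eps_o = ref$eps[occ], eps_v = ref$eps[space$virtual],
                 mo_idx = mos),
            class = "rcadc_df")
}
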