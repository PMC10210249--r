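# Exact determinant-space evaluation of the ground-to-excited one-particle
# transition density <0|a+_p a_q|n> for the correlated model states
#   |0> = |HF> + sum_{k<l,c<d} t_klcd |Phi_klcd>
#   |n> = sum_ia R_ia a+_a a_i|HF> + sum_{k<l,c<d} g_klcd |Phi_klcd>
# (|n> orthogonalised against |0>).  Independent of every production
# contraction: pure fermionic operator algebra on occupation vectors.

det_transition_density <- function(ref, asys, mp2, r, omega) {
  nocc <- ref$n_occ
  nso <- 2L * ref$n_ao
  hf <- seq_len(2L * nocc)
  apply_ops <- function(occ, ops) {
    ph <- 1
    for (op in rev(ops)) {
      orb <- op[2]
      if (op[1] == 0) {
        pos <- match(orb, occ)
        if (is.na(pos)) return(NULL)
        ph <- ph * (-1)^(pos - 1); occ <- occ[-pos]
      } else {
        if (orb %in% occ) return(NULL)
        ph <- ph * (-1)^sum(occ < orb); occ <- sort(c(occ, orb))
      }
    }
    list(occ = occ, ph = ph)
  }
  sovirt <- function(a) 2L * nocc + a
  key <- function(occ) paste(occ, collapse = ",")
  v0 <- new.env(parent = emptyenv())
  vn <- new.env(parent = emptyenv())
  addto <- function(env, occ, val) {
    k <- key(occ)
    assign(k, (if (exists(k, env)) get(k, env) else 0) + val, env)
  }
  addto(v0, hf, 1)
  no2 <- asys$no2; nv2 <- asys$nv2
  R <- rcadc:::.embed_singlet(asys, r)
  g <- doubles_coefficients(r, omega, asys)
  for (i in seq_len(no2)) for (a in seq_len(nv2)) {
    if (abs(R[i, a]) < 1e-14) next
    x <- apply_ops(hf, list(c(1, sovirt(a)), c(0, i)))
    addto(vn, x$occ, x$ph * R[i, a])
  }
  for (k in seq_len(no2)) for (l in seq_len(no2)) if (k < l)
    for (c in seq_len(nv2)) for (d in seq_len(nv2)) if (c < d) {
      x <- apply_ops(hf, list(c(1, sovirt(c)), c(1, sovirt(d)),
                              c(0, l), c(0, k)))
      if (abs(mp2$t2[k, l, c, d]) > 1e-15)
        addto(v0, x$occ, x$ph * mp2$t2[k, l, c, d])
      if (abs(g[k, l, c, d]) > 1e-15)
        addto(vn, x$occ, x$ph * g[k, l, c, d])
    }
  # orthogonalise |n> against |0>
  keys0 <- ls(v0); keysn <- ls(vn)
  ov <- 0; n0 <- 0
  for (k in keys0) {
    n0 <- n0 + get(k, v0)^2
    if (exists(k, vn)) ov <- ov + get(k, v0) * get(k, vn)
  }
  for (k in keys0)
    addto(vn, as.integer(strsplit(k, ",")[[1]]), -get(k, v0) * ov / n0)
  gamma <- matrix(0, nso, nso)
  for (kk in ls(vn)) {
    cn <- get(kk, vn)
    if (abs(cn) < 1e-15) next
    occ <- as.integer(strsplit(kk, ",")[[1]])
    for (q in occ) for (p in seq_len(nso)) {
      x <- apply_ops(occ, list(c(1, p), c(0, q)))
      if (is.null(x)) next
      k2 <- key(x$occ)
      if (exists(k2, v0))
        gamma[p, q] <- gamma[p, q] + get(k2, v0) * x$ph * cn
    }
  }
  oidx <- seq_len(no2); vidx <- no2 + seq_len(nv2)
  list(ov = gamma[oidx, vidx], vo = gamma[vidx, oidx],
       oo = gamma[oidx, oidx], vv = gamma[vidx, vidx])
}
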