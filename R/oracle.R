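# Brute-force validation oracles (test-only API).
#
# Everything here deliberately avoids the production code paths: MO integrals
# come from dense four-center AO integrals (or, on request, from the
# DF-reconstructed ERIs so that folding can be compared at identical
# integrals), matrices are built explicitly, and a small determinant-space
# FCI provides an implementation-independent reference: for states dominated
# by single excitations, ADC(2) excitation energies must agree with FCI
# through second order in the fluctuation potential.

#' Orbital space with every occupied orbital active (no CVS restriction)
#'
#' Used by the oracles to run the engine as conventional valence ADC(2).
#' @param ref an `rcadc_scf` reference
#' @export
full_space <- function(ref) {
  structure(list(frozen_core = integer(0),
                 active_core = seq_len(ref$n_occ),
                 inactive_occupied = integer(0),
                 virtual = seq.int(ref$n_occ + 1L, ref$n_ao),
                 eps = ref$eps, n_mo = ref$n_ao),
            class = "rcadc_space")
}

# dense MO ERI array (pq|rs) over the kept MOs, from exact AO integrals
.oracle_mo_eri <- function(ref, mos) {
  C <- ref$C[, mos, drop = FALSE]
  nao <- ref$n_ao; nmo <- ncol(C)
  g <- ref$eri_ao
  for (k in 1:4) {
    d <- dim(g)
    g <- crossprod(C, matrix(g, d[1], prod(d[-1])))
    g <- array(g, c(nmo, d[-1]))
    g <- aperm(g, c(2, 3, 4, 1))  # four cycles restore (p,q,r,s)
  }
  g
}

# MO ERI array from the DF factorisation (for identical-integral comparisons)
.df_mo_eri <- function(df) {
  n <- df$n_mo
  array(tcrossprod(df$J), c(n, n, n, n))
}

# spin-orbital antisymmetrised <PQ||RS> from a spatial (pq|rs) array
.so_eri_full <- function(g) {
  n <- dim(g)[1]
  sp <- .so_sp(n); s <- .so_spin(n)
  C1 <- aperm(g, c(1, 3, 2, 4))  # [p,q,r,s] = (pr|qs)
  C2 <- aperm(g, c(1, 3, 4, 2))  # [p,q,r,s] = (ps|qr) from g[p,s,q,r]
  G1 <- C1[sp, sp, sp, sp]; G2 <- C2[sp, sp, sp, sp]
  m1 <- aperm(outer(outer(s, s, "=="), outer(s, s, "==")), c(1, 3, 2, 4))
  m2 <- aperm(outer(outer(s, s, "=="), outer(s, s, "==")), c(1, 3, 4, 2))
  G1 * m1 - G2 * m2
}

#' Explicit CVS-ADC(2) secular matrix
#'
#' Builds the full singles+doubles strict-ADC(2) matrix with the singlet
#' singles block, the first-order singles-doubles coupling, and the diagonal
#' zeroth-order doubles block, enumerating every double excitation (exactly
#' one active-core occupied index in CVS mode).
#'
#' @param ref an `rcadc_scf` reference
#' @param space an `rcadc_space` partition
#' @param mode `"cvs"` or `"full"`
#' @param eri `"dense"` (exact four-center) or a `rcadc_df` object for
#'   DF-reconstructed integrals
#' @param max_doubles refusal threshold on the doubles dimension
#' @return list: `M` (matrix), `n_singles`, `singles` (i,a spatial labels),
#'   `doubles` (k,l,c,d spin-orbital labels)
#' @export
dense_adc2_matrix <- function(ref, space, mode = c("cvs", "full"),
                              eri = "dense", max_doubles = 20000L,
                              .signs = c(x = 1, y = 1, z = 1, cpl = 1)) {
  mode <- match.arg(mode)
  occ_idx <- sort(c(space$active_core, space$inactive_occupied))
  mos <- c(occ_idx, space$virtual)
  no <- length(occ_idx); nv <- length(space$virtual)
  g <- if (identical(eri, "dense")) .oracle_mo_eri(ref, mos) else .df_mo_eri(eri)
  eps_o <- ref$eps[occ_idx]; eps_v <- ref$eps[space$virtual]
  core_pos <- match(sort(space$active_core), occ_idx)
  occs <- if (mode == "cvs") core_pos else seq_len(no)
  V <- .so_eri_full(g)
  no2 <- 2L * no; nv2 <- 2L * nv
  eo2 <- rep(eps_o, each = 2); ev2 <- rep(eps_v, each = 2)
  core2 <- .so_sp(no) %in% core_pos
  ov <- function(p) no2 + p  # virtual SO offset inside V
  # --- singles block (spatial singlet) -------------------------------------
  ns <- length(occs) * nv
  lab_i <- rep(occs, nv); lab_a <- rep(seq_len(nv), each = length(occs))
  M11 <- matrix(0, ns, ns)
  for (s1 in seq_len(ns)) for (s2 in seq_len(s1)) {
    i <- lab_i[s1]; a <- lab_a[s1]; j <- lab_i[s2]; b <- lab_a[s2]
    val <- 2 * g[i, no + a, j, no + b] - g[i, j, no + a, no + b]
    if (i == j && a == b) val <- val + eps_v[a] - eps_o[i]
    # second order (spin-orbital loops, singlet projected)
    ia <- 2L * i - 1L; aa <- 2L * a - 1L
    for (sj in 0:1) {
      jj <- 2L * j - 1L + sj; bb <- 2L * b - 1L + sj
      m2 <- 0
      if (ia == jj) {
        for (k in seq_len(no2)) for (l in seq_len(no2)) for (c in seq_len(nv2)) {
          t1 <- V[k, l, ov(aa), ov(c)] /
            (eo2[k] + eo2[l] - ev2[aa] - ev2[c])
          t2_ <- V[k, l, ov(bb), ov(c)] /
            (eo2[k] + eo2[l] - ev2[bb] - ev2[c])
          m2 <- m2 - .signs[["x"]] * 0.25 *
            (t1 * V[k, l, ov(bb), ov(c)] + V[k, l, ov(aa), ov(c)] * t2_)
        }
      }
      if (aa == bb) {
        for (k in seq_len(no2)) for (c in seq_len(nv2)) for (d in seq_len(nv2)) {
          t1 <- V[ia, k, ov(c), ov(d)] /
            (eo2[ia] + eo2[k] - ev2[c] - ev2[d])
          t2_ <- V[jj, k, ov(c), ov(d)] /
            (eo2[jj] + eo2[k] - ev2[c] - ev2[d])
          m2 <- m2 - .signs[["y"]] * 0.25 *
            (t1 * V[jj, k, ov(c), ov(d)] + V[ia, k, ov(c), ov(d)] * t2_)
        }
      }
      for (k in seq_len(no2)) for (c in seq_len(nv2)) {
        t1 <- V[ia, k, ov(aa), ov(c)] /
          (eo2[ia] + eo2[k] - ev2[aa] - ev2[c])
        t2_ <- V[jj, k, ov(bb), ov(c)] /
          (eo2[jj] + eo2[k] - ev2[bb] - ev2[c])
        m2 <- m2 + .signs[["z"]] * 0.5 *
          (t1 * V[jj, k, ov(bb), ov(c)] + V[ia, k, ov(aa), ov(c)] * t2_)
      }
      val <- val + m2  # sum over sj realises the singlet projection
    }
    M11[s1, s2] <- M11[s2, s1] <- val
  }
  # --- doubles enumeration -------------------------------------------------
  dk <- integer(0); dl <- integer(0); dc <- integer(0); dd <- integer(0)
  for (k in seq_len(no2)) for (l in seq_len(no2)) if (k < l) {
    keep <- if (mode == "cvs") xor(core2[k], core2[l]) else TRUE
    if (!keep) next
    for (c in seq_len(nv2)) for (d in seq_len(nv2)) if (c < d) {
      dk <- c(dk, k); dl <- c(dl, l); dc <- c(dc, c); dd <- c(dd, d)
    }
  }
  nd <- length(dk)
  if (nd > max_doubles)
    stop("doubles space too large for the dense oracle: ", nd,
         " configurations (cap ", max_doubles, ")")
  M22 <- if (nd) ev2[dc] + ev2[dd] - eo2[dk] - eo2[dl] else numeric(0)
  M12 <- matrix(0, ns, nd)
  if (nd) for (s1 in seq_len(ns)) {
    i <- lab_i[s1]; a <- lab_a[s1]
    for (sp in 0:1) {
      ia <- 2L * i - 1L + sp; aa <- 2L * a - 1L + sp
      cpl <- numeric(nd)
      for (Dx in seq_len(nd)) {
        k <- dk[Dx]; l <- dl[Dx]; c <- dc[Dx]; d <- dd[Dx]
        vv <- 0
        if (aa == c) vv <- vv + V[k, l, ia, ov(d)]
        if (aa == d) vv <- vv - V[k, l, ia, ov(c)]
        if (ia == l) vv <- vv - .signs[["cpl"]] * V[k, ov(aa), ov(c), ov(d)]
        if (ia == k) vv <- vv + .signs[["cpl"]] * V[l, ov(aa), ov(c), ov(d)]
        cpl[Dx] <- vv
      }
      M12[s1, ] <- M12[s1, ] + cpl / sqrt(2)
    }
  }
  M <- rbind(cbind(M11, M12),
             cbind(t(M12), diag(M22, nd)))
  list(M = M, n_singles = ns,
       singles = data.frame(i = lab_i, a = lab_a),
       doubles = data.frame(k = dk, l = dl, c = dc, d = dd))
}

#' Eigenvalues of the explicit CVS-ADC(2) matrix
#'
#' @inheritParams dense_adc2_matrix
#' @param n_states how many singles-dominated roots to return
#' @param min_singles_weight minimum squared singles component for a root to
#'   count as an excitation of the folded problem
#' @return ascending excitation energies (Hartree)
#' @export
dense_adc2_eigenvalues <- function(ref, space, n_states,
                                   mode = c("cvs", "full"), eri = "dense",
                                   min_singles_weight = 1e-8) {
  mode <- match.arg(mode)
  dm <- dense_adc2_matrix(ref, space, mode, eri)
  ev <- eigen((dm$M + t(dm$M)) / 2, symmetric = TRUE)
  w <- colSums(ev$vectors[seq_len(dm$n_singles), , drop = FALSE]^2)
  vals <- ev$values[w > min_singles_weight]
  sort(vals)[seq_len(n_states)]
}

#' Closed-form two-level (one occupied, one virtual) reference values
#'
#' @param eps_i,eps_a orbital energies (Hartree)
#' @param iaia the exchange-type ERI (ia|ia)
#' @param iiaa the Coulomb-type ERI (ii|aa)
#' @return list with the closed-shell MP2 energy `e_mp2`, singlet CIS
#'   excitation energy `omega_cis`, and MP2 amplitude `t`
#' @export
two_level_closed_forms <- function(eps_i, eps_a, iaia, iiaa) {
  if (abs(eps_a - eps_i) < 1e-12) stop("degenerate orbital pair (pole)")
  list(e_mp2 = iaia^2 / (2 * (eps_i - eps_a)),
       omega_cis = (eps_a - eps_i) + 2 * iaia - iiaa,
       t = iaia / (2 * (eps_i - eps_a)))
}

# ------------------------------------------------------------------- FCI
# determinant-space full CI on the kept MOs; tiny systems only
.slater_phase <- function(occ, p_remove, p_add) {
  # phase of a_add^+ a_remove |occ>, occ sorted
  pos_r <- match(p_remove, occ)
  ph <- (-1)^(pos_r - 1L)
  occ2 <- occ[-pos_r]
  pos_a <- sum(occ2 < p_add)
  ph * (-1)^pos_a
}

#' Determinant-space FCI energies (oracle)
#'
#' Diagonalises the full Hamiltonian in the Ms = 0 determinant basis, for a
#' Hamiltonian along the Moller-Plesset partition path
#' `H(lambda) = F + lambda (H - F)`.  Used to verify that ADC(2) excitation
#' energies of singly-excited states are correct through second order in the
#' fluctuation potential.
#'
#' @param ref an `rcadc_scf` reference (small system!)
#' @param lambda coupling-strength scaling of the fluctuation potential
#' @param max_dets refusal threshold on the determinant count
#' @return list: `energies` (ascending), `vectors`, `dets` (list of sorted
#'   spin-orbital occupation vectors), and `singles_csf(i, a)` giving the
#'   normalised singlet single-excitation CSF in the determinant basis
#' @export
fci_oracle <- function(ref, lambda = 1.0, max_dets = 2000L) {
  nmo <- ref$n_ao
  mos <- seq_len(nmo)
  g <- .oracle_mo_eri(ref, mos)
  h <- crossprod(ref$C, ref$hcore %*% ref$C)
  V <- .so_eri_full(g)
  nso <- 2L * nmo
  sp <- .so_sp(nmo); spn <- .so_spin(nmo)
  hso <- h[sp, sp] * outer(spn, spn, "==")
  eps_so <- rep(ref$eps, each = 2)
  nel <- ref$molecule$n_electrons
  na <- nel %/% 2L
  alpha_orbs <- seq(1L, nso, by = 2L)
  beta_orbs <- seq(2L, nso, by = 2L)
  astr <- utils::combn(alpha_orbs, na, simplify = FALSE)
  bstr <- utils::combn(beta_orbs, na, simplify = FALSE)
  dets <- list()
  for (A in astr) for (B in bstr)
    dets[[length(dets) + 1L]] <- sort(c(A, B))
  ndet <- length(dets)
  if (ndet > max_dets)
    stop("FCI determinant space too large: ", ndet)
  occm <- matrix(FALSE, ndet, nso)
  for (d in seq_len(ndet)) occm[d, dets[[d]]] <- TRUE
  H <- matrix(0, ndet, ndet)
  Fd <- numeric(ndet)
  for (d1 in seq_len(ndet)) {
    o1 <- dets[[d1]]
    Fd[d1] <- sum(eps_so[o1])
    e <- sum(diag(hso)[o1])
    for (x in seq_along(o1)) for (y in seq_along(o1))
      if (x < y) e <- e + V[o1[x], o1[y], o1[x], o1[y]]
    H[d1, d1] <- e
    if (d1 == ndet) next
    for (d2 in seq.int(d1 + 1L, ndet)) {
      diff1 <- which(occm[d1, ] & !occm[d2, ])
      if (length(diff1) > 2L) next
      diff2 <- which(occm[d2, ] & !occm[d1, ])
      o2 <- dets[[d2]]
      if (length(diff1) == 1L) {
        p <- diff1; q <- diff2
        ph <- .slater_phase(o1, p, q)
        common <- setdiff(o1, p)
        val <- hso[p, q]
        for (m in common) val <- val + V[p, m, q, m]
        H[d1, d2] <- H[d2, d1] <- ph * val
      } else {
        p1 <- diff1[1]; p2 <- diff1[2]; q1 <- diff2[1]; q2 <- diff2[2]
        # phase: remove p1,p2 from o1; add q1,q2
        ph <- .slater_phase(o1, p2, q2)
        otmp <- sort(c(setdiff(o1, p2), q2))
        ph <- ph * .slater_phase(otmp, p1, q1)
        H[d1, d2] <- H[d2, d1] <- ph * V[p1, p2, q1, q2]
      }
    }
  }
  Hl <- lambda * H + (1 - lambda) * diag(Fd)
  ev <- eigen((Hl + t(Hl)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  ev$values <- ev$values[ord]
  ev$vectors <- ev$vectors[, ord, drop = FALSE]
  hf_occ <- sort(c(alpha_orbs[seq_len(na)], beta_orbs[seq_len(na)]))
  det_key <- vapply(dets, paste, "", collapse = ",")
  find_det <- function(occ) match(paste(sort(occ), collapse = ","), det_key)
  singles_csf <- function(i, a) {
    v <- numeric(ndet)
    for (s in 0:1) {
      p <- 2L * i - 1L + s
      q <- 2L * (ref$n_occ + a) - 1L + s  # a counts virtuals
      occ <- c(setdiff(hf_occ, p), q)
      ph <- .slater_phase(hf_occ, p, q)
      v[find_det(occ)] <- v[find_det(occ)] + ph / sqrt(2)
    }
    v
  }
  list(energies = ev$values, vectors = ev$vectors, dets = dets,
       hf_index = find_det(hf_occ), singles_csf = singles_csf)
}

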