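# The CVS-ADC(2) engine.
#
# Internally the correlated equations are evaluated in a spin-orbital
# representation with singlet spin adaptation realised by embedding: a
# spatial singles vector r_Ia enters as r/sqrt(2) on both spin components,
# every sigma contraction commutes with total spin, and the result is mapped
# back to the spatial singlet basis.  The strict-ADC(2) doubles block is
# diagonal, so the doubles space is never stored: the singles-doubles
# coupling is folded into an omega-dependent contribution (the effective
# Jacobian), evaluated on the fly from the density-fitted tensor.
#
# Spin-orbital convention: spatial p -> 2p-1 (alpha), 2p (beta).

.so_sp <- function(n) rep(seq_len(n), each = 2L)
.so_spin <- function(n) rep(c(1L, 2L), n)

# spatial chemist-ordered block (ab|cd) as 4D array [a,b,c,d]
.spat4 <- function(df, A, B, C, D) {
  m <- .eri_block(df, A, B, C, D)   # rows (b fastest, a), cols (d fastest, c)
  a <- array(m, c(length(B), length(A), length(D), length(C)))
  aperm(a, c(2, 1, 4, 3))
}

# antisymmetrised physicist spin-orbital tensor <PQ||RS> over spatial sets
.so_tensor <- function(df, P, Q, R, S) {
  C1 <- aperm(.spat4(df, P, R, Q, S), c(1, 3, 2, 4))  # [p,q,r,s] = (pr|qs)
  C2 <- aperm(.spat4(df, P, S, Q, R), c(1, 3, 4, 2))  # [p,q,r,s] = (ps|qr)
  spP <- .so_sp(length(P)); sP <- .so_spin(length(P))
  spQ <- .so_sp(length(Q)); sQ <- .so_spin(length(Q))
  spR <- .so_sp(length(R)); sR <- .so_spin(length(R))
  spS <- .so_sp(length(S)); sS <- .so_spin(length(S))
  G1 <- C1[spP, spQ, spR, spS, drop = FALSE]
  G2 <- C2[spP, spQ, spR, spS, drop = FALSE]
  m_pr <- outer(sP, sR, "=="); m_qs <- outer(sQ, sS, "==")
  m_ps <- outer(sP, sS, "=="); m_qr <- outer(sQ, sR, "==")
  M1 <- aperm(outer(m_pr, m_qs), c(1, 3, 2, 4))  # (P,R,Q,S) -> (P,Q,R,S)
  M2 <- aperm(outer(m_ps, m_qr), c(1, 3, 4, 2))  # (P,S,Q,R) -> (P,Q,R,S)
  G1 * M1 - G2 * M2
}

#' Build the working system for CVS-ADC(2) calculations
#'
#' Precomputes, from a density-fitted tensor, every integral block the CIS
#' and ADC(2) sigma vectors need: the (spin-orbital, antisymmetrised)
#' occupied-occupied-virtual-virtual block, the two singles-doubles coupling
#' blocks, orbital-energy denominators, and the CVS doubles mask (exactly one
#' active-core occupied index per double).
#'
#' @param df an `rcadc_df` tensor (canonical or reduced)
#' @param mode `"cvs"` restricts singles to active-core occupieds and doubles
#'   to exactly one active-core index; `"full"` gives conventional valence
#'   ADC(2) (used by the validation oracles)
#' @return an `rcadc_asys` object
#' @export
adc_system <- function(df, mode = c("cvs", "full")) {
  mode <- match.arg(mode)
  no <- df$n_occ; nv <- df$n_virt
  o <- seq_len(no); v <- no + seq_len(nv)
  occs <- if (mode == "cvs") df$core_pos else o
  if (mode == "cvs" && length(df$core_pos) == 0L)
    stop("CVS calculation requested but the space has no active core")
  no2 <- 2L * no; nv2 <- 2L * nv
  eps_o2 <- rep(df$eps_o, each = 2L)
  eps_v2 <- rep(df$eps_v, each = 2L)
  core2 <- .so_sp(no) %in% df$core_pos
  OOVV <- .so_tensor(df, o, o, v, v)
  OOOV <- .so_tensor(df, o, o, o, v)
  OVVV <- .so_tensor(df, o, v, v, v)
  # doubles denominators eps_c + eps_d - eps_k - eps_l as [k,l,c,d]
  Dkl <- outer(eps_o2, eps_o2, "+")
  Dcd <- outer(eps_v2, eps_v2, "+")
  delta <- aperm(outer(Dcd, Dkl, function(cd, kl) cd - kl), c(3, 4, 1, 2))
  occ2 <- .so_sp(no) %in% occs
  pair_mask <- if (mode == "cvs")
    outer(core2, core2, xor) else
    array(TRUE, c(no2, no2))
  mask4 <- array(pair_mask, c(no2, no2, nv2, nv2))
  structure(list(mode = mode, no = no, nv = nv, no2 = no2, nv2 = nv2,
                 occs = occs, occ2 = occ2, core2 = core2,
                 eps_o = df$eps_o, eps_v = df$eps_v,
                 eps_o2 = eps_o2, eps_v2 = eps_v2,
                 OOVV = OOVV, OOOV = OOOV, OVVV = OVVV,
                 delta = delta, mask4 = mask4, df = df),
            class = "rcadc_asys")
}

# embed a spatial singles matrix r[occs x nv] into the spin-orbital singles
# space (all occupieds x all virtuals, zeros outside the singles-occupied set)
.embed_singlet <- function(asys, r) {
  R <- matrix(0, asys$no2, asys$nv2)
  io <- 2L * asys$occs
  iv <- 2L * seq_len(asys$nv)
  R[io - 1L, iv - 1L] <- r / sqrt(2)
  R[io, iv] <- r / sqrt(2)
  R
}

.project_singlet <- function(asys, R) {
  io <- 2L * asys$occs
  iv <- 2L * seq_len(asys$nv)
  sqrt(2) * R[io - 1L, iv - 1L, drop = FALSE]
}

#' MP2 ground-state intermediates
#'
#' Forms the first-order (MP2) doubles amplitudes in the frozen-core space of
#' the system and contracts them into the static second-order intermediates
#' of the ADC(2) singles block (a virtual-virtual block, its
#' occupied-occupied analogue, and the non-diagonal amplitude-dressed term),
#' together with the MP2 correlation energy.
#'
#' @param asys an `rcadc_asys` system
#' @return an `rcadc_mp2` object with the amplitude tensor `t2`
#'   (spin-orbital), intermediates `Xv`, `Yo`, the second-order singles
#'   matrix `M2sp` in the spatial singlet basis, and `e_mp2` (Hartree)
#' @export
mp2_intermediates <- function(asys) {
  small <- abs(asys$delta) < 1e-8 & abs(asys$OOVV) > 1e-10
  if (any(small))
    stop("vanishing MP2 denominator for an occupied/virtual pair ",
         "with non-zero coupling")
  t2 <- -asys$OOVV / asys$delta        # t_kl^cd = <kl||cd>/(e_k+e_l-e_c-e_d)
  t2[abs(asys$delta) < 1e-8] <- 0
  e_mp2 <- 0.25 * sum(t2 * asys$OOVV)
  no2 <- asys$no2; nv2 <- asys$nv2
  # static second-order singles terms; with t = <kl||cd>/(e_occ - e_virt)
  # the diagonal blocks enter with a minus sign and the amplitude-dressed
  # non-diagonal term with a plus (verified against the FCI order test)
  # Xv[a,b] = -1/4 sum_klc ( t_kl^ac <kl||bc> + <kl||ac> t_kl^bc )
  Tm <- matrix(aperm(t2, c(1, 2, 4, 3)), no2 * no2 * nv2, nv2)
  Vm <- matrix(aperm(asys$OOVV, c(1, 2, 4, 3)), no2 * no2 * nv2, nv2)
  P <- crossprod(Tm, Vm)
  Xv <- -0.25 * (P + t(P))
  # Yo[i,j] = 1/4 sum_kcd ( t_ik^cd <jk||cd> + <ik||cd> t_jk^cd )
  Tm <- matrix(aperm(t2, c(2, 3, 4, 1)), no2 * nv2 * nv2, no2)
  Vm <- matrix(aperm(asys$OOVV, c(2, 3, 4, 1)), no2 * nv2 * nv2, no2)
  Q <- crossprod(Tm, Vm)
  Yo <- -0.25 * (Q + t(Q))
  # Z[(i,a),(j,b)] = +1/2 ( R1 + R1^T ), R1 = sum_kc t_ik^ac <jk||bc>
  T1 <- matrix(aperm(t2, c(1, 3, 2, 4)), no2 * nv2, no2 * nv2)
  V1 <- matrix(aperm(asys$OOVV, c(1, 3, 2, 4)), no2 * nv2, no2 * nv2)
  R1 <- tcrossprod(T1, V1)
  M2so <- kronecker(Xv, diag(no2)) + kronecker(diag(nv2), Yo) +
    0.5 * (R1 + t(R1))
  # project onto the spatial singlet singles basis (all occupieds)
  io <- 2L * seq_len(asys$no); iv <- 2L * seq_len(asys$nv)
  paa <- as.vector(outer(io - 1L, (iv - 2L) * no2, "+"))
  pbb <- as.vector(outer(io, (iv - 1L) * no2, "+"))
  M2sp <- M2so[paa, paa, drop = FALSE] + M2so[paa, pbb, drop = FALSE]
  structure(list(t2 = t2, Xv = Xv, Yo = Yo, M2sp = M2sp, e_mp2 = e_mp2),
            class = "rcadc_mp2")
}

#' Dense CVS-CIS singles matrix
#'
#' The spin-adapted singlet CIS matrix over the singles space of the system:
#' `(e_a - e_I) + 2(Ia|Jb) - (IJ|ab)`, with occupied labels restricted to the
#' active core in CVS mode.
#'
#' @param asys an `rcadc_asys` system
#' @return symmetric matrix of dimension `length(occs) * n_virt` (occupied
#'   index fastest)
#' @export
cis_matrix <- function(asys) {
  df <- asys$df
  occs <- asys$occs; no_s <- length(occs); nv <- asys$nv
  o <- occs; v <- asys$no + seq_len(nv)
  iajb <- .spat4(df, o, v, o, v)       # [i,a,j,b] = (ia|jb)
  ijab <- .spat4(df, o, o, v, v)       # [i,j,a,b] = (ij|ab)
  K <- aperm(ijab, c(1, 3, 2, 4))      # [i,a,j,b] = (ij|ab)
  A <- 2 * iajb - K
  A <- matrix(A, no_s * nv, no_s * nv)
  de <- as.vector(outer(asys$eps_o[occs], asys$eps_v,
                        function(ei, ea) ea - ei))
  A + diag(de, no_s * nv)
}

#' CVS-CIS sigma vector
#'
#' Applies the singlet CIS response matrix to a singles vector using
#' density-fitted contractions (no explicit matrix).
#'
#' @param r singles matrix (`length(occs)` x `n_virt`)
#' @param asys an `rcadc_asys` system
#' @return sigma as a matrix of the same shape
#' @export
cis_sigma <- function(r, asys) {
  df <- asys$df
  occs <- asys$occs; no_s <- length(occs); nv <- asys$nv
  r <- matrix(r, no_s, nv)
  o <- occs; v <- asys$no + seq_len(nv)
  Jov <- .J_rows(df, o, v)                  # rows (a fastest, i), nQ cols
  nQ <- ncol(Jov)
  rvec <- as.vector(t(r))                   # a fastest
  cQ <- crossprod(Jov, rvec)                # nQ
  coul <- matrix(2 * (Jov %*% cQ), nv, no_s)  # [a,i]
  Jvv <- .J_rows(df, v, v)
  Joo <- .J_rows(df, o, o)
  # exchange: sum_jb (ij|ab) r_jb
  W <- r %*% matrix(Jvv, nv, nv * nQ)       # [j, (a,Q)]  (b contracted)
  W <- aperm(array(W, c(no_s, nv, nQ)), c(1, 3, 2))
  L <- aperm(array(Joo, c(no_s, no_s, nQ)), c(2, 1, 3))  # [i,j,Q]
  exch <- matrix(L, no_s, no_s * nQ) %*% matrix(W, no_s * nQ, nv)
  de <- outer(asys$eps_o[occs], asys$eps_v, function(ei, ea) ea - ei)
  de * r + t(coul) - exch
}

# ---------------------------------------------------------------- doubles
# b_klcd = sum_ia M1_{ia,klcd} R_ia for an embedded spin-orbital singles R
.fold_b <- function(asys, R) {
  no2 <- asys$no2; nv2 <- asys$nv2
  # U[k,l,d,c'] = sum_i <kl||id> R_ic'
  OOOVm <- matrix(aperm(asys$OOOV, c(1, 2, 4, 3)), no2 * no2 * nv2, no2)
  U <- array(OOOVm %*% R, c(no2, no2, nv2, nv2))     # [k,l,d,c]
  t1 <- aperm(U, c(1, 2, 4, 3))                      # [k,l,c,d]
  # W[k,c,d,l'] = sum_a <ka||cd> R_l'a
  OVVVm <- matrix(aperm(asys$OVVV, c(1, 3, 4, 2)), no2 * nv2 * nv2, nv2)
  W <- array(OVVVm %*% t(R), c(no2, nv2, nv2, no2))  # [k,c,d,l]
  t3 <- aperm(W, c(1, 4, 2, 3))                      # [k,l,c,d]
  b <- t1 - aperm(t1, c(1, 2, 4, 3)) - t3 + aperm(t3, c(2, 1, 3, 4))
  b * asys$mask4
}

# sigma contribution sum_D M1_{ia,D} g_D with g = b / (omega - delta)
.fold_sigma <- function(asys, g) {
  no2 <- asys$no2; nv2 <- asys$nv2
  OOOVm <- matrix(aperm(asys$OOOV, c(1, 2, 4, 3)), no2 * no2 * nv2, no2)
  gm1 <- matrix(aperm(g, c(1, 2, 4, 3)), no2 * no2 * nv2, nv2)
  termA <- crossprod(OOOVm, gm1)                     # [i,a]
  OVVVm <- matrix(aperm(asys$OVVV, c(1, 3, 4, 2)), no2 * nv2 * nv2, nv2)
  gm2 <- matrix(aperm(g, c(2, 3, 4, 1)), no2 * nv2 * nv2, no2)
  termB <- t(crossprod(OVVVm, gm2))                  # [i,a]
  0.5 * (termA + termB)
}

#' Omega-dependent doubles coefficients of a singles vector
#'
#' Forms, on the fly, the first-order doubles coefficients
#' `c_D = (M_21 r)_D / (omega - Delta_D)` of the folded ADC(2) problem
#' (CVS-restricted to exactly one active-core occupied index).  The full
#' doubles tensor is returned for diagnostics and density construction; the
#' solver itself only ever contracts it immediately.
#'
#' @param r spatial singles matrix over the singles space
#' @param omega excitation energy (Hartree) entering the denominators
#' @param asys an `rcadc_asys` system
#' @return spin-orbital doubles tensor `[k,l,c,d]`
#' @export
doubles_coefficients <- function(r, omega, asys) {
  if (!is.finite(omega)) stop("omega must be finite")
  R <- .embed_singlet(asys, r)
  b <- .fold_b(asys, R)
  den <- omega - asys$delta
  bad <- abs(den) < 1e-10 & abs(b) > 1e-12
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "omega hits a doubles denominator pole at (k=%d,l=%d,c=%d,d=%d)",
      w[1], w[2], w[3], w[4]))
  }
  g <- b / den
  g[abs(den) < 1e-10] <- 0
  g
}

#' Full CVS-ADC(2) sigma vector
#'
#' `sigma = sigma_CIS + sigma^(2)`, where the second-order part collects the
#' ground-state-amplitude (MP2 intermediate) terms and the folded,
#' omega-dependent doubles terms.
#'
#' @param r spatial singles matrix
#' @param omega current excitation energy (Hartree)
#' @param asys an `rcadc_asys` system
#' @param mp2 intermediates from [mp2_intermediates()]
#' @param include internal switch (subset of `c("m2", "doubles")`) used by
#'   limit tests
#' @return sigma as a singles matrix
#' @export
sigma_vector <- function(r, omega, asys, mp2,
                         include = c("m2", "doubles")) {
  occs <- asys$occs; no_s <- length(occs); nv <- asys$nv
  r <- matrix(r, no_s, nv)
  sig <- cis_sigma(r, asys)
  if ("m2" %in% include) {
    sel <- as.vector(outer(occs, (seq_len(nv) - 1L) * asys$no, "+"))
    M2 <- mp2$M2sp[sel, sel, drop = FALSE]
    sig <- sig + matrix(M2 %*% as.vector(r), no_s, nv)
  }
  if ("doubles" %in% include) {
    g <- doubles_coefficients(r, omega, asys)
    sig <- sig + .project_singlet(asys, .fold_sigma(asys, g))
  }
  sig
}

# ------------------------------------------------------------- solvers
# generic block Davidson for a Hermitian matvec
.davidson <- function(matvec, dim, n_states, diag_pre, tol = 1e-7,
                      max_iter = 200L, max_sub = NULL, guess = NULL) {
  if (n_states > dim) stop("n_states exceeds the singles dimension (", dim, ")")
  if (is.null(max_sub)) max_sub <- min(dim, max(20L * n_states, 40L))
  if (is.null(guess)) {
    ord <- order(diag_pre)[seq_len(n_states)]
    guess <- matrix(0, dim, n_states)
    guess[cbind(ord, seq_len(n_states))] <- 1
  }
  V <- qr.Q(qr(guess))
  AV <- NULL
  for (it in seq_len(max_iter)) {
    if (is.null(AV)) AV <- apply(V, 2, matvec) else {
      new <- seq.int(ncol(AV) + 1L, ncol(V))
      AV <- cbind(AV, apply(V[, new, drop = FALSE], 2, matvec))
    }
    H <- crossprod(V, AV); H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    ord <- order(ev$values)[seq_len(n_states)]  # lowest roots
    theta <- ev$values[ord]
    Xs <- V %*% ev$vectors[, ord, drop = FALSE]
    Rs <- AV %*% ev$vectors[, ord, drop = FALSE] -
      Xs %*% diag(theta, n_states)
    rn <- sqrt(colSums(Rs^2))
    if (all(rn < tol))
      return(list(values = theta, vectors = Xs, iterations = it,
                  residuals = rn))
    if (ncol(V) + n_states > max_sub) {  # collapse
      V <- qr.Q(qr(Xs)); AV <- NULL
      next
    }
    add <- NULL
    for (k in which(rn >= tol)) {
      d <- theta[k] - diag_pre
      d[abs(d) < 1e-6] <- 1e-6
      t_ <- Rs[, k] / d
      t_ <- t_ - V %*% crossprod(V, t_)
      if (!is.null(add)) t_ <- t_ - add %*% crossprod(add, t_)
      nt <- sqrt(sum(t_^2))
      if (nt > 1e-10) add <- cbind(add, t_ / nt)
    }
    if (is.null(add)) {
      V <- qr.Q(qr(Xs)); AV <- NULL
      next
    }
    V <- cbind(V, add)
  }
  stop("Davidson failed to converge in ", max_iter,
       " iterations (residuals ", paste(format(rn), collapse = ", "), ")")
}

#' Solve the CVS-CIS equations
#'
#' Lowest eigenpairs of the Hermitian CVS-CIS problem by block Davidson with
#' an orbital-energy-difference preconditioner.
#'
#' @param asys an `rcadc_asys` system
#' @param n_states number of states
#' @param tol residual-norm convergence threshold
#' @return list with `omega` (Hartree, ascending) and `vectors` (columns are
#'   unit singles vectors, occupied index fastest)
#' @export
solve_cis <- function(asys, n_states, tol = 1e-8) {
  no_s <- length(asys$occs); nv <- asys$nv
  dim <- no_s * nv
  de <- as.vector(outer(asys$eps_o[asys$occs], asys$eps_v,
                        function(ei, ea) ea - ei))
  res <- .davidson(function(x) as.vector(cis_sigma(x, asys)),
                   dim, n_states, de, tol = tol)
  list(omega = res$values, vectors = res$vectors, iterations = res$iterations)
}

#' Solve the folded CVS-ADC(2) pseudo-eigenvalue problem
#'
#' One state at a time: a modified Davidson iteration in the singles space in
#' which the effective Jacobian is re-evaluated at the current excitation
#' energy each cycle, the energy is updated from the selected Ritz value
#' (root homing by maximal overlap with the CIS guess), and restart vectors
#' are DIIS-extrapolated from the stored residual history.
#'
#' @param asys an `rcadc_asys` system
#' @param mp2 intermediates from [mp2_intermediates()]
#' @param guesses CIS solution from [solve_cis()] (guess source and homing
#'   reference)
#' @param states which guess states to converge (default: all)
#' @param e_tol,r_tol convergence thresholds on |d omega| (Hartree) and the
#'   residual norm
#' @param max_iter iteration cap per state
#' @param diis_depth residual-history depth for the DIIS restart
#' @return list of `rcadc_state` objects: `omega` (Hartree), `omega_ev`,
#'   unit singles vector `r`, `cis_overlap`, `converged`, `iterations`
#' @export
solve_adc2 <- function(asys, mp2, guesses, states = NULL,
                       e_tol = 1e-6, r_tol = 1e-5, max_iter = 60L,
                       diis_depth = 6L) {
  if (is.null(states)) states <- seq_along(guesses$omega)
  no_s <- length(asys$occs); nv <- asys$nv
  dim <- no_s * nv
  de <- as.vector(outer(asys$eps_o[asys$occs], asys$eps_v,
                        function(ei, ea) ea - ei))
  out <- list()
  for (st in states) {
    x0 <- guesses$vectors[, st]
    omega <- guesses$omega[st]
    V <- matrix(x0, dim, 1)
    traj <- numeric(0)
    hist_x <- list(); hist_r <- list()
    converged <- FALSE
    x <- x0; theta <- omega; overlap <- 1; rnorm_ <- Inf
    for (it in seq_len(max_iter)) {
      # sigma at current omega for the whole subspace
      SV <- apply(V, 2, function(vv)
        as.vector(sigma_vector(vv, omega, asys, mp2)))
      SV <- matrix(SV, dim, ncol(V))
      H <- crossprod(V, SV); H <- (H + t(H)) / 2
      ev <- eigen(H, symmetric = TRUE)
      ovl <- abs(crossprod(V %*% ev$vectors, x0))
      root <- which.max(ovl)
      overlap <- ovl[root]
      theta <- ev$values[root]
      x <- as.vector(V %*% ev$vectors[, root])
      resid <- as.vector(SV %*% ev$vectors[, root]) - theta * x
      rnorm_ <- sqrt(sum(resid^2))
      traj <- c(traj, theta)
      if (rnorm_ < r_tol && abs(theta - omega) < e_tol) {
        omega <- theta
        converged <- TRUE
        break
      }
      omega <- theta
      hist_x[[length(hist_x) + 1L]] <- x
      hist_r[[length(hist_r) + 1L]] <- resid
      if (length(hist_x) > diis_depth) {
        hist_x <- hist_x[-1L]; hist_r <- hist_r[-1L]
      }
      if (ncol(V) >= min(dim, 20L)) {
        # DIIS-extrapolated restart from the residual history
        m <- length(hist_r)
        B <- matrix(0, m + 1L, m + 1L)
        for (i in seq_len(m)) for (j in seq_len(m))
          B[i, j] <- sum(hist_r[[i]] * hist_r[[j]])
        B[m + 1L, seq_len(m)] <- B[seq_len(m), m + 1L] <- -1
        cf <- tryCatch(solve(B, c(rep(0, m), -1))[seq_len(m)],
                       error = function(e) NULL)
        xr <- x
        if (!is.null(cf)) {
          xr <- 0
          for (i in seq_len(m)) xr <- xr + cf[i] * hist_x[[i]]
          if (sqrt(sum(xr^2)) < 1e-8) xr <- x
        }
        V <- qr.Q(qr(cbind(xr / sqrt(sum(xr^2)), x)))
        next
      }
      d <- theta - de
      d[abs(d) < 1e-6] <- 1e-6
      t_ <- resid / d
      t_ <- t_ - V %*% crossprod(V, t_)
      nt <- sqrt(sum(t_^2))
      if (nt < 1e-11) {
        V <- matrix(x, dim, 1)
        next
      }
      V <- cbind(V, t_ / nt)
    }
    if (!converged)
      stop("CVS-ADC(2) solver did not converge for state ", st,
           " (trajectory: ", paste(sprintf("%.6f", traj), collapse = " "),
           ")")
    if (overlap < 0.5)
      warning(sprintf(
        "state %d: overlap of the converged singles vector with its CVS-CIS guess is only %.3f",
        st, overlap))
    out[[length(out) + 1L]] <- structure(
      list(omega = omega, omega_ev = omega * hartree_to_ev,
           r = matrix(x / sqrt(sum(x^2)), no_s, nv),
           cis_overlap = overlap, converged = TRUE,
           iterations = it, state_index = st),
      class = "rcadc_state")
  }
  # root-collapse guard
  if (length(out) > 1L) {
    for (i in seq_len(length(out) - 1L))
      for (j in seq.int(i + 1L, length(out)))
        if (abs(sum(out[[i]]$r * out[[j]]$r)) > 0.95)
          stop("root collapse: states ", out[[i]]$state_index, " and ",
               out[[j]]$state_index, " converged to the same vector")
  }
  out
}

#' @export
print.rcadc_state <- function(x, ...) {
  cat(sprintf("excited state %d: omega = %.4f eV (%.6f Hartree), %s\n",
              x$state_index, x$omega_ev, x$omega,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
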