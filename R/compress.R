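# Cost-reduction core: natural auxiliary functions (NAF) for the fitting
# basis and state-specific frozen virtual natural orbitals (VNO) from a
# state-averaged MP2 / CVS-CIS(D) density, with the double NAF truncation of
# the combined scheme.

#' Construct the natural auxiliary function basis
#'
#' Diagonalises `W = J^T J` (auxiliary x auxiliary); eigenvector directions
#' with singular value (square root of the eigenvalue) below `eps_naf` are
#' dropped.  The retained rotation gives the best low-rank representation of
#' the three-center tensor in the least-squares sense.
#'
#' @param df an `rcadc_df` tensor
#' @param eps_naf truncation threshold on the singular values (au);
#'   0 retains everything
#' @return an `rcadc_naf` object: `rotation` (n_Q x n_kept), `importance`
#'   (descending eigenvalues of W), `n_kept`, `n_Q`
#' @export
build_naf <- function(df, eps_naf) {
  if (eps_naf < 0) stop("eps_naf must be >= 0")
  W <- crossprod(df$J)
  if (max(abs(W - t(W))) > 1e-8) stop("internal error: W not symmetric")
  ev <- eigen((W + t(W)) / 2, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  keep <- sqrt(vals) >= eps_naf
  if (!any(keep)) keep[1] <- TRUE  # never drop everything
  structure(list(rotation = ev$vectors[, keep, drop = FALSE],
                 importance = vals, n_kept = sum(keep), n_Q = df$n_Q),
            class = "rcadc_naf")
}

#' @export
print.rcadc_naf <- function(x, ...) {
  cat(sprintf("NAF basis: %d of %d auxiliary functions retained (%.1f%%)\n",
              x$n_kept, x$n_Q, 100 * x$n_kept / x$n_Q))
  invisible(x)
}

#' Rotate a DF tensor into a retained NAF basis
#'
#' @param df an `rcadc_df` tensor
#' @param naf an `rcadc_naf` object built from it
#' @return a new `rcadc_df` with `n_Q = naf$n_kept`
#' @export
apply_naf <- function(df, naf) {
  if (naf$n_Q != df$n_Q) stop("NAF basis does not match the tensor")
  df$J <- df$J %*% naf$rotation
  df$n_Q <- naf$n_kept
  df
}

# rotate the virtual blocks of a DF tensor (and its dipole blocks) by an
# n_virt x n_kept orthonormal matrix Z; new semicanonical energies eps_new
.rotate_virtuals <- function(df, Z, eps_new) {
  no <- df$n_occ; nv <- df$n_virt; nvk <- ncol(Z)
  nmo <- df$n_mo; nQ <- df$n_Q
  Tm <- matrix(0, nmo, no + nvk)
  Tm[seq_len(no), seq_len(no)] <- diag(no)
  Tm[no + seq_len(nv), no + seq_len(nvk)] <- Z
  Jarr <- array(df$J, c(nmo, nmo, nQ))
  J1 <- crossprod(Tm, matrix(Jarr, nmo, nmo * nQ))          # rotate q
  J1 <- aperm(array(J1, c(no + nvk, nmo, nQ)), c(2, 1, 3))  # [p, q', Q]
  J2 <- crossprod(Tm, matrix(J1, nmo, (no + nvk) * nQ))     # rotate p
  J2 <- aperm(array(J2, c(no + nvk, no + nvk, nQ)), c(2, 1, 3))
  df$J <- matrix(J2, (no + nvk)^2, nQ)
  df$n_mo <- no + nvk
  df$n_virt <- nvk
  df$eps_v <- eps_new
  if (!is.null(df$dip))
    df$dip <- lapply(df$dip, function(m) crossprod(Tm, m %*% Tm))
  df$mo_idx <- NULL  # no longer canonical MOs
  df
}

#' Unrelaxed MP2 virtual-virtual density
#'
#' `D_ab = 1/2 sum_klc t_kl^ac t_kl^bc` over the frozen-core amplitude
#' space, returned in the spatial-orbital basis (both spin contributions
#' summed; symmetric positive semidefinite).
#'
#' @param asys an `rcadc_asys` system
#' @param mp2 intermediates from [mp2_intermediates()]
#' @return symmetric `n_virt` x `n_virt` matrix
#' @export
mp2_vv_density <- function(asys, mp2) {
  no2 <- asys$no2; nv2 <- asys$nv2
  Tm <- matrix(aperm(mp2$t2, c(1, 2, 4, 3)), no2 * no2 * nv2, nv2)
  Dso <- 0.5 * crossprod(Tm)          # [a,b] spin-orbital
  ia <- 2L * seq_len(asys$nv) - 1L
  Dso[ia, ia, drop = FALSE] + Dso[ia + 1L, ia + 1L, drop = FALSE]
}

#' Unrelaxed CVS-CIS(D) virtual-virtual density
#'
#' CIS outer-product term `sum_I r_Ia r_Ib` (trace 1 for a normalised
#' state) plus the perturbative-doubles term built from the CVS-restricted
#' doubles coefficients evaluated at the CVS-CIS excitation energy.
#'
#' @param asys an `rcadc_asys` system
#' @param r unit spatial singles vector of the CVS-CIS state
#' @param omega_cis its excitation energy (Hartree)
#' @param include_doubles set `FALSE` to keep only the CIS term
#' @return symmetric `n_virt` x `n_virt` matrix (spatial)
#' @export
cisd_vv_density <- function(asys, r, omega_cis, include_doubles = TRUE) {
  r <- matrix(r, length(asys$occs), asys$nv)
  nr <- sqrt(sum(r^2))
  if (abs(nr - 1) > 1e-6)
    stop("CIS singles vector is not normalised (|r| = ", format(nr), ")")
  R <- .embed_singlet(asys, r)
  Dso <- crossprod(R)                 # sum_I R_Ia R_Ib
  if (include_doubles) {
    g <- doubles_coefficients(r, omega_cis, asys)
    Gm <- matrix(aperm(g, c(1, 2, 4, 3)), asys$no2^2 * asys$nv2, asys$nv2)
    Dso <- Dso + 0.5 * crossprod(Gm)
  }
  ia <- 2L * seq_len(asys$nv) - 1L
  Dso[ia, ia, drop = FALSE] + Dso[ia + 1L, ia + 1L, drop = FALSE]
}

#' State-averaged one-particle density
#'
#' Equal-weight average `D = (D_MP2 + D_CIS(D)) / 2` so that the ground- and
#' excited-state equations of one transition share a single reduced virtual
#' space.
#'
#' @param d_mp2,d_cisd matching symmetric matrices
#' @return an `rcadc_state_density` object with fields `D`, `d_mp2`,
#'   `d_cisd`
#' @export
state_averaged_density <- function(d_mp2, d_cisd) {
  if (!all(dim(d_mp2) == dim(d_cisd)))
    stop("density dimension mismatch: ", nrow(d_mp2), " vs ", nrow(d_cisd))
  structure(list(D = (d_mp2 + d_cisd) / 2, d_mp2 = d_mp2, d_cisd = d_cisd),
            class = "rcadc_state_density")
}

#' Construct and truncate the virtual natural orbital space
#'
#' Diagonalises a virtual-virtual density, keeps eigenvectors with
#' `|eigenvalue| >= eps_vno` (ranking by magnitude: CIS(D) densities can
#' carry small negative eigenvalues), and semicanonicalises the retained
#' span by re-diagonalising the virtual-virtual Fock so that
#' orbital-energy denominators remain valid.
#'
#' @param D virtual-virtual density matrix (or an `rcadc_state_density`)
#' @param eps_vno occupation-number truncation threshold
#' @param eps_v canonical virtual orbital energies (Hartree)
#' @return list: `rotation` (n_virt x n_kept, orthonormal), `eps`
#'   (semicanonical energies, ascending), `occupations` (all eigenvalues,
#'   by decreasing magnitude), `n_kept`, `pct_kept`
#' @export
build_vno <- function(D, eps_vno, eps_v) {
  if (inherits(D, "rcadc_state_density")) D <- D$D
  if (eps_vno < 0) stop("eps_vno must be >= 0")
  nv <- nrow(D)
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE)
  ord <- order(abs(ev$values), decreasing = TRUE)
  vals <- ev$values[ord]; vecs <- ev$vectors[, ord, drop = FALSE]
  keep <- abs(vals) >= eps_vno
  if (!any(keep))
    stop("eps_vno = ", eps_vno, " removes every virtual orbital")
  U <- vecs[, keep, drop = FALSE]
  Fk <- crossprod(U, U * eps_v)       # U^T diag(eps_v) U
  sc <- eigen((Fk + t(Fk)) / 2, symmetric = TRUE)
  ord2 <- order(sc$values)
  list(rotation = U %*% sc$vectors[, ord2, drop = FALSE],
       eps = sc$values[ord2], occupations = vals,
       n_kept = sum(keep), pct_kept = 100 * sum(keep) / nv)
}

#' Build the state-specific reduced subspace (VNO + second NAF truncation)
#'
#' For one CVS-CIS state: forms the state-averaged density, truncates the
#' virtual space to its important natural orbitals (semicanonicalised),
#' rotates the three-center tensor into that space, and truncates the
#' auxiliary basis a second time with the same `eps_naf`.
#'
#' @param df the (globally NAF-truncated) `rcadc_df` tensor
#' @param asys,mp2 system and MP2 intermediates built on `df`
#' @param d_mp2 precomputed MP2 virtual-virtual density on `df`
#' @param r,omega_cis the CVS-CIS state (unit vector, Hartree)
#' @param eps_vno,eps_naf truncation thresholds
#' @return list: reduced `df`, rotated unit guess `r` for the state,
#'   `vno_pct`/`naf_pct` retained percentages, `vno` bookkeeping
#' @export
reduce_state <- function(df, asys, mp2, d_mp2, r, omega_cis,
                         eps_vno, eps_naf) {
  d_cisd <- cisd_vv_density(asys, r, omega_cis)
  sd <- state_averaged_density(d_mp2, d_cisd)
  vno <- build_vno(sd, eps_vno, df$eps_v)
  df_red <- .rotate_virtuals(df, vno$rotation, vno$eps)
  naf2 <- build_naf(df_red, eps_naf)
  df_red <- apply_naf(df_red, naf2)
  r_rot <- matrix(r, length(asys$occs), asys$nv) %*% vno$rotation
  nr <- sqrt(sum(r_rot^2))
  if (nr < 1e-6)
    stop("CIS vector has no weight in the reduced virtual space")
  list(df = df_red, r = r_rot / nr, guess_weight = nr,
       vno_pct = vno$pct_kept, naf_pct = 100 * naf2$n_kept / df$n_Q,
       vno = vno)
}
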