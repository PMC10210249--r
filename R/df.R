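# Density fitting: the metric-dressed three-center MO tensor J with
# (pq|rs) ~ sum_Q J^Q_pq J^Q_rs.

#' Inverse square root of the two-center Coulomb metric
#'
#' Eigendecomposes the (symmetric, positive-definite) auxiliary Coulomb
#' metric and returns its inverse square root, discarding eigenvalues below
#' `cutoff` to guard against near-linear-dependent fitting sets.
#'
#' @param V symmetric metric matrix (Hartree)
#' @param cutoff eigenvalue cutoff (default 1e-10)
#' @return symmetric matrix `Vih` with `Vih %*% V %*% Vih = I` on the
#'   retained range
#' @export
metric_inverse_sqrt <- function(V, cutoff = 1e-10) {
  if (max(abs(V - t(V))) > 1e-8) stop("metric matrix is not symmetric")
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  keep <- ev$values > cutoff
  if (!any(keep))
    stop("degenerate auxiliary basis: all metric eigenvalues below cutoff")
  U <- ev$vectors[, keep, drop = FALSE]
  U %*% (t(U) / sqrt(ev$values[keep]))
}

#' Assemble the density-fitted three-center MO tensor
#'
#' Computes AO three-center Coulomb integrals (mu nu|P), transforms them to
#' the non-frozen MO basis, and dresses the auxiliary index with the inverse
#' square root of the two-center metric, so that four-center ERIs factorise
#' as `(pq|rs) = sum_Q J^Q_pq J^Q_rs`.
#'
#' @param ref an `rcadc_scf` reference
#' @param space an `rcadc_space` CVS partition; frozen-core orbitals are
#'   excluded from the tensor
#' @param metric_cutoff eigenvalue cutoff for [metric_inverse_sqrt()]
#' @return an `rcadc_df` object: `J` is an (n_mo^2 x n_Q) matrix over the
#'   kept MOs (occupied block first, then virtuals), with bookkeeping fields
#'   `n_occ`, `n_virt`, `core_pos`, `eps_o`, `eps_v`, `n_Q`
#' @export
assemble_J <- function(ref, space, metric_cutoff = 1e-10) {
  occ_idx <- sort(c(space$active_core, space$inactive_occupied))
  mos <- c(occ_idx, space$virtual)
  Ck <- ref$C[, mos, drop = FALSE]
  nao <- ref$n_ao
  nmo <- length(mos)
  if (nrow(Ck) != nao) stop("MO coefficient/AO dimension mismatch")
  V2 <- .ao_eri_2c(ref$aux_shells)
  naux <- nrow(V2)
  B <- .ao_eri_3c(ref$shells, ref$aux_shells)
  Vih <- metric_inverse_sqrt(V2, metric_cutoff)
  # (mu nu|P) -> (p nu|P) -> (p q|P)
  T1 <- crossprod(Ck, matrix(B, nao, nao * naux))          # nmo x (nao*naux)
  T1 <- array(T1, c(nmo, nao, naux))
  T1 <- matrix(aperm(T1, c(2, 1, 3)), nao, nmo * naux)
  T2 <- crossprod(Ck, T1)                                  # nmo x (nmo*naux)
  Jall <- matrix(array(T2, c(nmo, nmo, naux)), nmo * nmo, naux) %*% Vih
  if (!is.null(ref$eri_scale) && ref$eri_scale != 1)
    Jall <- Jall * sqrt(ref$eri_scale)
  dip <- lapply(ref$dipole_ao, function(m) crossprod(Ck, m %*% Ck))
  structure(list(J = Jall, n_mo = nmo, n_Q = ncol(Jall), dip = dip,
                 n_occ = length(occ_idx), n_virt = length(space$virtual),
                 core_pos = match(sort(space$active_core), occ_idx),
                 eps_o = ref$eps[occ_idx], eps_v = ref$eps[space$virtual],
                 mo_idx = mos),
            class = "rcadc_df")
}

#' @export
print.rcadc_df <- function(x, ...) {
  cat(sprintf("DF tensor: %d MOs (%d occ + %d virt), n_Q = %d\n",
              x$n_mo, x$n_occ, x$n_virt, x$n_Q))
  invisible(x)
}

#' Reconstruct a four-center ERI from the DF factorisation
#'
#' Diagnostic helper returning `sum_Q J^Q_pq J^Q_rs` for MO indices in the
#' kept-MO ordering of the tensor (occupied block first).
#'
#' @param df an `rcadc_df` object
#' @param p,q,r,s MO indices (1-based, kept-MO ordering)
#' @export
reconstruct_eri <- function(df, p, q, r, s) {
  n <- df$n_mo
  for (i in c(p, q, r, s))
    if (i < 1 || i > n) stop("MO index ", i, " outside the stored blocks")
  sum(df$J[(p - 1L) * n + q, ] * df$J[(r - 1L) * n + s, ])
}

# spatial ERI block (pq|rs) as a matrix (|p||q|) x (|r||s|) from index sets
.eri_block <- function(df, pset, qset, rset, sset) {
  n <- df$n_mo
  rows1 <- as.vector(outer(qset, pset, function(q, p) (p - 1L) * n + q))
  rows2 <- as.vector(outer(sset, rset, function(s, r) (r - 1L) * n + s))
  tcrossprod(df$J[rows1, , drop = FALSE], df$J[rows2, , drop = FALSE])
}

# J rows for a (pset, qset) block, as matrix (|p|*|q|) x n_Q with q fastest
.J_rows <- function(df, pset, qset) {
  n <- df$n_mo
  rows <- as.vector(outer(qset, pset, function(q, p) (p - 1L) * n + q))
  df$J[rows, , drop = FALSE]
}
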