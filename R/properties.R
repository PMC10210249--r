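# Oscillator strengths in the dipole-length gauge.
#
# The ground-to-excited transition density is assembled through the orders
# consistent with strict ADC(2): the CIS-order occupied-virtual term, the
# amplitude-dressed virtual-occupied term (MP2 doubles against the singles
# vector), and the occupied-occupied / virtual-virtual terms bilinear in the
# ground-state amplitudes and the state's doubles coefficients.  All
# occupied labels are CVS-restricted through the structure of the singles
# and doubles spaces.  Every term was verified against an exact
# determinant-space evaluation of <0|E_pq|n> on small systems.

#' Transition density blocks of a converged state (spin-orbital)
#'
#' @param asys an `rcadc_asys` system
#' @param mp2 intermediates from [mp2_intermediates()]
#' @param r unit spatial singles vector
#' @param omega excitation energy (Hartree)
#' @return list of spin-orbital blocks `ov`, `vo`, `oo`, `vv`
#' @keywords internal
transition_density_blocks <- function(asys, mp2, r, omega) {
  R <- .embed_singlet(asys, r)
  g <- doubles_coefficients(r, omega, asys)
  no2 <- asys$no2; nv2 <- asys$nv2
  # vo: sum_jb t_ij^ab R_jb
  Tm <- matrix(aperm(mp2$t2, c(1, 3, 2, 4)), no2 * nv2, no2 * nv2)
  vo <- t(matrix(Tm %*% as.vector(R), no2, nv2))        # [a,i]
  # vv: 1/2 sum_klc t_kl^ac g_kl^bc
  Ta <- matrix(aperm(mp2$t2, c(1, 2, 4, 3)), no2 * no2 * nv2, nv2)
  Ga <- matrix(aperm(g, c(1, 2, 4, 3)), no2 * no2 * nv2, nv2)
  vv <- 0.5 * crossprod(Ta, Ga)                         # [a,b]
  # oo: -1/2 sum_kcd t_jk^cd g_ik^cd
  To <- matrix(aperm(mp2$t2, c(2, 3, 4, 1)), no2 * nv2 * nv2, no2)
  Go <- matrix(aperm(g, c(2, 3, 4, 1)), no2 * nv2 * nv2, no2)
  oo <- -0.5 * crossprod(Go, To)                        # [i,j]
  list(ov = R, vo = vo, oo = oo, vv = vv)
}

#' Oscillator strength of a core-excited state
#'
#' Contracts the ADC(2)-consistent transition density with the MO dipole
#' integrals and returns the dipole-length oscillator strength
#' `f = 2/3 * omega * |mu|^2`.
#'
#' @param state an `rcadc_state` from [solve_adc2()]
#' @param asys the `rcadc_asys` system it was solved in
#' @param mp2 intermediates from [mp2_intermediates()]
#' @param order `"adc2"` (default) or `"cis"` (zeroth-order density only;
#'   used in validation against the CIS oracle)
#' @return an `rcadc_moment` object: `dipole` (length-3 vector, au),
#'   `omega` (Hartree), `f`
#' @export
oscillator_strength <- function(state, asys, mp2, order = c("adc2", "cis")) {
  order <- match.arg(order)
  if (!isTRUE(state$converged)) stop("state is not converged")
  df <- asys$df
  if (is.null(df$dip)) stop("DF tensor carries no dipole integrals")
  no <- asys$no; nv <- asys$nv
  o <- seq_len(no); v <- no + seq_len(nv)
  blocks <- if (order == "cis")
    list(ov = .embed_singlet(asys, state$r)) else
    transition_density_blocks(asys, mp2, state$r, state$omega)
  mu <- vapply(df$dip, function(m) {
    m_ov <- m[o, v, drop = FALSE][.so_sp(no), .so_sp(nv), drop = FALSE] *
      outer(.so_spin(no), .so_spin(nv), "==")
    val <- sum(m_ov * blocks$ov)
    if (!is.null(blocks$vo)) {
      val <- val + sum(t(m_ov) * blocks$vo)
      m_oo <- m[o, o, drop = FALSE][.so_sp(no), .so_sp(no), drop = FALSE] *
        outer(.so_spin(no), .so_spin(no), "==")
      m_vv <- m[v, v, drop = FALSE][.so_sp(nv), .so_sp(nv), drop = FALSE] *
        outer(.so_spin(nv), .so_spin(nv), "==")
      val <- val + sum(m_oo * blocks$oo) + sum(m_vv * blocks$vv)
    }
    val
  }, 0)
  structure(list(dipole = mu, omega = state$omega,
                 f = 2 / 3 * state$omega * sum(mu^2)),
            class = "rcadc_moment")
}

#' @export
print.rcadc_moment <- function(x, ...) {
  cat(sprintf("transition moment |mu| = %.5f au, f = %.4f\n",
              sqrt(sum(x$dipole^2)), x$f))
  invisible(x)
}
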