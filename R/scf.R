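# Restricted Hartree-Fock reference and the CVS orbital partition.
#
# The SCF uses exact four-center AO integrals (cheap at fixture scale, and it
# keeps the fitting basis a property of the correlation treatment only);
# density fitting enters in the correlated/excited-state stages.

#' Compute a closed-shell Hartree-Fock reference
#'
#' Converges a restricted HF determinant with DIIS acceleration and returns
#' the canonical MO basis that all correlated stages build on.
#'
#' @param molecule a [molecule()] object (closed shell)
#' @param basis orbital basis name (see [build_shells()])
#' @param aux_basis auxiliary basis specification for the correlated stages;
#'   currently `"autoaux"` (see [build_aux_shells()])
#' @param max_iter,conv SCF iteration cap and convergence threshold on the
#'   orbital-gradient (DIIS error) norm
#' @param two_electron_scale scale factor on the electron-electron repulsion
#'   operator (adiabatic-connection-style scaling; the default 1 is the
#'   physical Hamiltonian).  Used by the perturbation-order consistency
#'   oracles in the test-suite.
#' @return an `rcadc_scf` object: MO coefficients `C` (AO x MO), orbital
#'   energies `eps` (Hartree), occupied count `n_occ`, total energy
#'   `energy`, AO integral matrices, and the shell lists
#' @export
compute_reference <- function(molecule, basis = "6-31g",
                              aux_basis = "autoaux",
                              max_iter = 100L, conv = 1e-9,
                              two_electron_scale = 1) {
  shells <- build_shells(molecule, basis)
  ints <- .ao_oneints(shells, molecule$xyz_bohr, molecule$z)
  nao <- nrow(ints$S)
  n_occ <- molecule$n_electrons %/% 2L
  if (n_occ < 1L) stop("no occupied orbitals")
  if (nao <= n_occ)
    stop("basis provides no virtual orbitals (", nao, " AOs, ",
         n_occ, " occupied): correlated stages are impossible")
  eri <- .ao_eri_dense(shells)
  if (two_electron_scale != 1) eri <- eri * two_electron_scale
  n2 <- nao * nao
  eriJ <- matrix(eri, n2, n2)                         # (mn|ls)
  eriK <- matrix(aperm(eri, c(1, 3, 2, 4)), n2, n2)   # (ml|ns)

  Hcore <- ints$T + ints$V
  se <- eigen(ints$S, symmetric = TRUE)
  if (min(se$values) < 1e-10)
    stop("linearly dependent AO basis (min overlap eigenvalue ",
         format(min(se$values)), ")")
  X <- se$vectors %*% diag(1 / sqrt(se$values), nao) %*% t(se$vectors)

  # core guess
  Fm <- Hcore
  C <- NULL
  D <- matrix(0, nao, nao)
  e_old <- Inf
  fock_hist <- list()
  err_hist <- list()
  energy <- NA_real_
  for (it in seq_len(max_iter)) {
    Fo <- X %*% Fm %*% X
    ev <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    eps <- ev$values[ord]
    Cocc <- C[, seq_len(n_occ), drop = FALSE]
    D <- Cocc %*% t(Cocc)
    Jm <- matrix(eriJ %*% as.vector(D), nao, nao)
    Km <- matrix(eriK %*% as.vector(D), nao, nao)
    Fm <- Hcore + 2 * Jm - Km
    energy <- sum(D * (Hcore + Fm)) + nuclear_repulsion(molecule)
    err <- Fm %*% D %*% ints$S - ints$S %*% D %*% Fm
    err <- t(X) %*% err %*% X
    if (max(abs(err)) < conv && abs(energy - e_old) < 1e-10) break
    e_old <- energy
    # DIIS
    fock_hist[[length(fock_hist) + 1L]] <- Fm
    err_hist[[length(err_hist) + 1L]] <- err
    if (length(fock_hist) > 8L) {
      fock_hist <- fock_hist[-1L]
      err_hist <- err_hist[-1L]
    }
    m <- length(fock_hist)
    if (m >= 2L) {
      B <- matrix(0, m + 1L, m + 1L)
      for (i in seq_len(m))
        for (j in seq_len(m))
          B[i, j] <- sum(err_hist[[i]] * err_hist[[j]])
      B[m + 1L, seq_len(m)] <- B[seq_len(m), m + 1L] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf)) {
        Fm <- matrix(0, nao, nao)
        for (i in seq_len(m)) Fm <- Fm + cf[i] * fock_hist[[i]]
      }
    }
    if (it == max_iter)
      stop("SCF failed to converge in ", max_iter,
           " iterations (last |err| = ", format(max(abs(err))),
           ", E = ", format(energy), ")")
  }
  aux_shells <- if (identical(tolower(aux_basis), "autoaux"))
    build_aux_shells(molecule, basis) else
    stop("unknown auxiliary basis: ", aux_basis)
  structure(list(molecule = molecule, basis = tolower(basis),
                 aux_basis = "autoaux",
                 shells = shells, aux_shells = aux_shells,
                 C = C, eps = eps, n_occ = n_occ, n_ao = nao,
                 energy = energy, S = ints$S, hcore = Hcore,
                 eri_scale = two_electron_scale,
                 dipole_ao = list(x = ints$DX, y = ints$DY, z = ints$DZ),
                 eri_ao = eri),
            class = "rcadc_scf")
}

#' @export
print.rcadc_scf <- function(x, ...) {
  cat(sprintf("RHF/%s  E = %.8f Hartree  (%d AOs, %d occupied)\n",
              x$basis, x$energy, x$n_ao, x$n_occ))
  invisible(x)
}

# Mulliken population of MO p on a set of AOs: sum_{mu in set} C_mu,p (S C)_mu,p
.mo_population <- function(ref, ao_set) {
  SC <- ref$S %*% ref$C
  colSums(ref$C[ao_set, , drop = FALSE] * SC[ao_set, , drop = FALSE])
}

#' Partition the canonical MOs into the CVS orbital spaces
#'
#' Identifies the active-core 1s orbitals of the probed element by Mulliken
#' population on that element's tightest s functions (threshold 0.5, robust
#' against accidental energy ordering), freezes the remaining deep-core 1s
#' orbitals of heavy atoms according to `frozen_policy`, and leaves the rest
#' as inactive-occupied and virtual spaces.
#'
#' @param ref an `rcadc_scf` reference
#' @param cvs_element element symbol whose 1s shells define the K-edge, e.g.
#'   `"O"`
#' @param frozen_policy `"other-cores"` (default: freeze 1s orbitals of
#'   B-Ne-row atoms that are not active) or `"none"`
#' @return an `rcadc_space` object with integer MO index vectors
#'   `frozen_core`, `active_core`, `inactive_occupied`, `virtual`, and the
#'   orbital energies `eps`
#' @export
partition_orbitals <- function(ref, cvs_element,
                               frozen_policy = c("other-cores", "none")) {
  frozen_policy <- match.arg(frozen_policy)
  occ <- seq_len(ref$n_occ)
  heavies <- unique(ref$molecule$atoms[ref$molecule$z >= 5 &
                                       ref$molecule$z <= 10])
  if (!cvs_element %in% ref$molecule$atoms)
    stop("cvs element ", cvs_element, " not present in the molecule")
  core_aos <- .core_1s_aos(ref$shells, ref$molecule, cvs_element)
  if (length(core_aos) == 0L)
    stop("no 1s functions found for element ", cvs_element)
  pop <- .mo_population(ref, core_aos)
  active <- occ[pop[occ] >= 0.5]
  if (length(active) == 0L)
    stop("no occupied MO carries >= 0.5 Mulliken population on the ",
         cvs_element, " 1s shells")
  if (any(pop[-occ] >= 0.5 & seq_along(pop)[-occ] %in% active))
    stop("CVS selector matched a virtual orbital")
  frozen <- integer(0)
  if (frozen_policy == "other-cores") {
    for (el in setdiff(heavies, cvs_element)) {
      aos <- .core_1s_aos(ref$shells, ref$molecule, el)
      p <- .mo_population(ref, aos)
      frozen <- c(frozen, occ[p[occ] >= 0.5])
    }
  }
  frozen <- sort(setdiff(unique(frozen), active))
  inact <- sort(setdiff(occ, c(active, frozen)))
  structure(list(frozen_core = frozen, active_core = sort(active),
                 inactive_occupied = inact,
                 virtual = seq.int(ref$n_occ + 1L, ref$n_ao),
                 eps = ref$eps, n_mo = ref$n_ao),
            class = "rcadc_space")
}

#' @export
print.rcadc_space <- function(x, ...) {
  cat(sprintf(
    "CVS partition: %d frozen core / %d active core / %d valence occ / %d virtual\n",
    length(x$frozen_core), length(x$active_core),
    length(x$inactive_occupied), length(x$virtual)))
  invisible(x)
}
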