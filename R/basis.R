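#' @useDynLib rcadc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Built-in Gaussian basis sets (Hartree exponents in bohr^-2, standard
# published contractions).  STO-3G serves the minimal-basis oracles; 6-31G is
# the double-zeta production basis for the fixture suite.  Only H-F are
# shipped: the fixture chemistry (organic K-edges) needs nothing heavier.

.sto3g <- list(
  H = list(list(l = 0L,
                exps = c(3.42525091, 0.62391373, 0.16885540),
                coefs = c(0.15432897, 0.53532814, 0.44463454))),
  He = list(list(l = 0L,
                 exps = c(6.36242139, 1.15892300, 0.31364979),
                 coefs = c(0.15432897, 0.53532814, 0.44463454))),
  C = list(list(l = 0L,
                exps = c(71.6168370, 13.0450960, 3.5305122),
                coefs = c(0.15432897, 0.53532814, 0.44463454)),
           list(l = 0L,
                exps = c(2.9412494, 0.6834831, 0.2222899),
                coefs = c(-0.09996723, 0.39951283, 0.70011547)),
           list(l = 1L,
                exps = c(2.9412494, 0.6834831, 0.2222899),
                coefs = c(0.15591627, 0.60768372, 0.39195739))),
  N = list(list(l = 0L,
                exps = c(99.1061690, 18.0523120, 4.8856602),
                coefs = c(0.15432897, 0.53532814, 0.44463454)),
           list(l = 0L,
                exps = c(3.7804559, 0.8784966, 0.2857144),
                coefs = c(-0.09996723, 0.39951283, 0.70011547)),
           list(l = 1L,
                exps = c(3.7804559, 0.8784966, 0.2857144),
                coefs = c(0.15591627, 0.60768372, 0.39195739))),
  O = list(list(l = 0L,
                exps = c(130.7093200, 23.8088610, 6.4436083),
                coefs = c(0.15432897, 0.53532814, 0.44463454)),
           list(l = 0L,
                exps = c(5.0331513, 1.1695961, 0.3803890),
                coefs = c(-0.09996723, 0.39951283, 0.70011547)),
           list(l = 1L,
                exps = c(5.0331513, 1.1695961, 0.3803890),
                coefs = c(0.15591627, 0.60768372, 0.39195739))),
  F = list(list(l = 0L,
                exps = c(166.6791300, 30.3608120, 8.2168207),
                coefs = c(0.15432897, 0.53532814, 0.44463454)),
           list(l = 0L,
                exps = c(4.4355834, 1.0466228, 0.3380671),
                coefs = c(-0.09996723, 0.39951283, 0.70011547)),
           list(l = 1L,
                exps = c(4.4355834, 1.0466228, 0.3380671),
                coefs = c(0.15591627, 0.60768372, 0.39195739)))
)

.g631 <- list(
  H = list(list(l = 0L,
                exps = c(18.7311370, 2.8253944, 0.6401217),
                coefs = c(0.03349460, 0.23472695, 0.81375733)),
           list(l = 0L, exps = 0.1612778, coefs = 1.0)),
  He = list(list(l = 0L,
                 exps = c(38.4216340, 5.7780300, 1.2417740),
                 coefs = c(0.02376600, 0.15467900, 0.46963000)),
            list(l = 0L, exps = 0.2979640, coefs = 1.0)),
  C = list(list(l = 0L,
                exps = c(3047.5249000, 457.3695100, 103.9486900,
                         29.2101550, 9.2866630, 3.1639270),
                coefs = c(0.0018347, 0.0140373, 0.0688426,
                          0.2321844, 0.4679413, 0.3623120)),
           list(l = 0L,
                exps = c(7.8682724, 1.8812885, 0.5442493),
                coefs = c(-0.1193324, -0.1608542, 1.1434564)),
           list(l = 1L,
                exps = c(7.8682724, 1.8812885, 0.5442493),
                coefs = c(0.0689991, 0.3164240, 0.7443083)),
           list(l = 0L, exps = 0.1687144, coefs = 1.0),
           list(l = 1L, exps = 0.1687144, coefs = 1.0)),
  N = list(list(l = 0L,
                exps = c(4173.5110000, 627.4579000, 142.9021000,
                         40.2343300, 13.0326900, 4.4260430),
                coefs = c(0.0018348, 0.0139950, 0.0685870,
                          0.2322410, 0.4690700, 0.3604550)),
           list(l = 0L,
                exps = c(11.6263580, 2.7162800, 0.7722180),
                coefs = c(-0.1149610, -0.1691180, 1.1458520)),
           list(l = 1L,
                exps = c(11.6263580, 2.7162800, 0.7722180),
                coefs = c(0.0675800, 0.3239070, 0.7408950)),
           list(l = 0L, exps = 0.2120313, coefs = 1.0),
           list(l = 1L, exps = 0.2120313, coefs = 1.0)),
  O = list(list(l = 0L,
                exps = c(5484.6717000, 825.2349500, 188.0469600,
                         52.9645000, 16.8975700, 5.7996353),
                coefs = c(0.0018311, 0.0139501, 0.0684451,
                          0.2327143, 0.4701930, 0.3585209)),
           list(l = 0L,
                exps = c(15.5396160, 3.5999336, 1.0137618),
                coefs = c(-0.1107775, -0.1480263, 1.1307670)),
           list(l = 1L,
                exps = c(15.5396160, 3.5999336, 1.0137618),
                coefs = c(0.0708743, 0.3397528, 0.7271586)),
           list(l = 0L, exps = 0.2700058, coefs = 1.0),
           list(l = 1L, exps = 0.2700058, coefs = 1.0)),
  F = list(list(l = 0L,
                exps = c(7001.7130900, 1051.3660900, 239.2856900,
                         67.3974453, 21.5199573, 7.4031013),
                coefs = c(0.0018196169, 0.0139160796, 0.0684053245,
                          0.2331857260, 0.4712674392, 0.3566185462)),
           list(l = 0L,
                exps = c(20.8479528, 4.8083083, 1.3440699),
                coefs = c(-0.1085069751, -0.1464516581, 1.1286885925)),
           list(l = 1L,
                exps = c(20.8479528, 4.8083083, 1.3440699),
                coefs = c(0.0716287243, 0.3459121027, 0.7224699564)),
           list(l = 0L, exps = 0.3581514, coefs = 1.0),
           list(l = 1L, exps = 0.3581514, coefs = 1.0))
)

.basis_library <- list("sto-3g" = .sto3g, "6-31g" = .g631)

.dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# primitive normalisation for the (l,0,0) Cartesian component
.prim_norm <- function(a, l) {
  (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(.dfact(2 * l - 1))
}

# contracted self-overlap of the (l,0,0) component
.contracted_norm <- function(exps, coefs, l) {
  s <- 0
  for (p in seq_along(exps))
    for (q in seq_along(exps)) {
      ab <- exps[p] + exps[q]
      s <- s + coefs[p] * coefs[q] * (pi / ab)^1.5 *
        .dfact(2 * l - 1) / (2 * ab)^l
    }
  sqrt(s)
}

.normalize_shell <- function(sh) {
  c2 <- sh$coefs * vapply(sh$exps, .prim_norm, 0, l = sh$l)
  sh$coefs <- c2 / .contracted_norm(sh$exps, c2, sh$l)
  sh
}

#' Build the contracted shell list for a molecule
#'
#' Expands a named basis set over the atoms of a molecule into the flat shell
#' list consumed by the integral backend.  Coordinates are converted to bohr
#' and contraction coefficients are normalised.
#'
#' @param molecule a [molecule()] object
#' @param basis basis-set name, `"sto-3g"` or `"6-31g"` (case-insensitive)
#' @return list of shells, each `list(l, center, exps, coefs)`, with an
#'   `ao_atom` attribute mapping every AO to its atom index and `ao_l`
#'   mapping it to its angular momentum
#' @export
build_shells <- function(molecule, basis) {
  key <- tolower(basis)
  if (!key %in% names(.basis_library))
    stop("unknown basis set: ", basis)
  lib <- .basis_library[[key]]
  shells <- list()
  ao_atom <- integer(0)
  ao_l <- integer(0)
  for (ia in seq_along(molecule$atoms)) {
    el <- molecule$atoms[ia]
    if (!el %in% names(lib))
      stop("basis ", basis, " has no data for element ", el)
    for (sh in lib[[el]]) {
      sh <- .normalize_shell(sh)
      sh$center <- molecule$xyz_bohr[ia, ]
      shells[[length(shells) + 1L]] <- sh
      nc <- (sh$l + 1L) * (sh$l + 2L) / 2L
      ao_atom <- c(ao_atom, rep(ia, nc))
      ao_l <- c(ao_l, rep(sh$l, nc))
    }
  }
  attr(shells, "ao_atom") <- ao_atom
  attr(shells, "ao_l") <- ao_l
  attr(shells, "nao") <- length(ao_atom)
  shells
}

#' Generate an automatic auxiliary (fitting) basis
#'
#' Product-style even-tempered auxiliary set: per atom, candidate exponents
#' are sums of orbital-basis primitive exponents and are thinned to a
#' geometric progression with ratio `beta`.  Auxiliary angular momenta run up
#' to twice the atomic orbital-basis maximum (at least l_max + 1), which
#' covers all one-center orbital products.  This is the `"autoaux"` auxiliary
#' basis referred to throughout the package.
#'
#' @param molecule a [molecule()] object
#' @param basis orbital basis name the fit must serve
#' @param beta geometric thinning ratio (> 1); smaller = larger, more
#'   accurate auxiliary sets.  Default 2.2.
#' @return shell list in the same format as [build_shells()]
#' @export
build_aux_shells <- function(molecule, basis, beta = 2.2) {
  key <- tolower(basis)
  if (!key %in% names(.basis_library))
    stop("unknown basis set: ", basis)
  lib <- .basis_library[[key]]
  shells <- list()
  ao_atom <- integer(0)
  for (ia in seq_along(molecule$atoms)) {
    el <- molecule$atoms[ia]
    prims <- do.call(rbind, lapply(lib[[el]], function(sh)
      cbind(sh$exps, sh$l)))
    lmax <- max(prims[, 2])
    laux_max <- max(2L * lmax, lmax + 1L)
    for (L in 0:laux_max) {
      cand <- c()
      for (p in seq_len(nrow(prims)))
        for (q in p:nrow(prims))
          if (prims[p, 2] + prims[q, 2] >= min(L, 2 * lmax))
            cand <- c(cand, prims[p, 1] + prims[q, 1])
      cand <- sort(unique(cand), decreasing = TRUE)
      kept <- cand[1]
      for (x in cand)
        if (kept[length(kept)] / x >= beta) kept <- c(kept, x)
      for (a in kept) {
        sh <- .normalize_shell(list(l = L, exps = a, coefs = 1.0))
        sh$center <- molecule$xyz_bohr[ia, ]
        shells[[length(shells) + 1L]] <- sh
        nc <- (L + 1L) * (L + 2L) / 2L
        ao_atom <- c(ao_atom, rep(ia, nc))
      }
    }
  }
  attr(shells, "ao_atom") <- ao_atom
  attr(shells, "nao") <- length(ao_atom)
  shells
}

# indices (within a shell list) of the 1s-dominated AO functions of a given
# element: the tightest s shell per matching atom
.core_1s_aos <- function(shells, molecule, element) {
  ao_atom <- attr(shells, "ao_atom")
  out <- integer(0)
  ao <- 0L
  best <- list()  # per atom: c(ao_index, leading exponent)
  for (sh in shells) {
    nc <- (sh$l + 1L) * (sh$l + 2L) / 2L
    ia <- ao_atom[ao + 1L]
    if (sh$l == 0L && molecule$atoms[ia] == element) {
      amax <- max(sh$exps)
      key <- as.character(ia)
      if (is.null(best[[key]]) || amax > best[[key]][2])
        best[[key]] <- c(ao + 1L, amax)
    }
    ao <- ao + nc
  }
  sort(vapply(best, function(x) as.integer(x[1]), 0L))
}
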