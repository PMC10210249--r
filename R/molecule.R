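# Molecules, units, fixtures, XYZ I/O

#' Unit conversion constants
#'
#' @format `hartree_to_ev` multiplies Hartree energies into eV;
#'   `angstrom_to_bohr` multiplies Angstrom lengths into bohr.
#' @export
hartree_to_ev <- 27.211386

#' @rdname hartree_to_ev
#' @export
angstrom_to_bohr <- 1 / 0.529177210903

.element_z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
                F = 9, Ne = 10)

#' Construct a molecule
#'
#' @param atoms character vector of element symbols
#' @param xyz numeric matrix (n_atoms x 3) of Cartesian coordinates in
#'   Angstrom
#' @param charge total charge (integer)
#' @param multiplicity spin multiplicity; only closed-shell singlets
#'   (`multiplicity = 1`) are supported
#' @return an object of class `rcadc_molecule` with coordinates kept both in
#'   Angstrom (`xyz`) and bohr (`xyz_bohr`)
#' @export
molecule <- function(atoms, xyz, charge = 0L, multiplicity = 1L) {
  atoms <- as.character(atoms)
  xyz <- matrix(as.numeric(xyz), nrow = length(atoms), ncol = 3)
  if (length(atoms) < 1L) stop("a molecule needs at least one atom")
  if (!all(atoms %in% names(.element_z)))
    stop("unsupported element(s): ",
         paste(setdiff(atoms, names(.element_z)), collapse = ", "))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (multiplicity != 1L)
    stop("only closed-shell (multiplicity 1) references are supported")
  nelec <- sum(.element_z[atoms]) - charge
  if (nelec %% 2 != 0)
    stop("odd electron count (", nelec, ") is not closed shell")
  structure(list(atoms = atoms, xyz = xyz,
                 xyz_bohr = xyz * angstrom_to_bohr,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 z = unname(.element_z[atoms]),
                 n_electrons = as.integer(nelec)),
            class = "rcadc_molecule")
}

#' @export
print.rcadc_molecule <- function(x, ...) {
  cat(sprintf("molecule: %s  (%d electrons, charge %+d)\n",
              paste(x$atoms, collapse = ""), x$n_electrons, x$charge))
  invisible(x)
}

# experimental equilibrium geometries (Angstrom)
.fixture_geometries <- list(
  h2 = list(atoms = c("H", "H"),
            xyz = rbind(c(0, 0, 0), c(0, 0, 0.7414))),
  he = list(atoms = "He", xyz = rbind(c(0, 0, 0))),
  h2o = list(atoms = c("O", "H", "H"),
             xyz = rbind(c(0, 0, 0),
                         c(0.7570, 0, 0.5859),
                         c(-0.7570, 0, 0.5859))),
  nh3 = list(atoms = c("N", "H", "H", "H"),
             xyz = rbind(c(0, 0, 0),
                         c(0.93718, 0, 0.38084),
                         c(-0.46859, 0.81162, 0.38084),
                         c(-0.46859, -0.81162, 0.38084))),
  co = list(atoms = c("C", "O"),
            xyz = rbind(c(0, 0, 0), c(0, 0, 1.1283))),
  hf = list(atoms = c("F", "H"),
            xyz = rbind(c(0, 0, 0), c(0, 0, 0.9168))),
  ch4 = list(atoms = c("C", "H", "H", "H", "H"),
             xyz = rbind(c(0, 0, 0),
                         c(0.6270, 0.6270, 0.6270),
                         c(0.6270, -0.6270, -0.6270),
                         c(-0.6270, 0.6270, -0.6270),
                         c(-0.6270, -0.6270, 0.6270))),
  c2h4 = list(atoms = c("C", "C", "H", "H", "H", "H"),
              xyz = rbind(c(0, 0, 0.6695),
                          c(0, 0, -0.6695),
                          c(0.9280, 0, 1.2337),
                          c(-0.9280, 0, 1.2337),
                          c(0.9280, 0, -1.2337),
                          c(-0.9280, 0, -1.2337))),
  h2co = list(atoms = c("C", "O", "H", "H"),
              xyz = rbind(c(0, 0, 0),
                          c(0, 0, 1.2080),
                          c(0.9490, 0, -0.5871),
                          c(-0.9490, 0, -0.5871)))
)

#' Built-in fixture molecules
#'
#' Small closed-shell molecules at experimental equilibrium geometries, used
#' throughout the test-suite and the benchmark harness.
#'
#' @param name one of `r paste0('"', paste(names(.fixture_geometries),
#'   collapse = '", "'), '"')`
#' @return a [molecule()] object
#' @export
fixture_molecule <- function(name) {
  key <- tolower(name)
  if (!key %in% names(.fixture_geometries))
    stop("unknown fixture: ", name, " (available: ",
         paste(names(.fixture_geometries), collapse = ", "), ")")
  g <- .fixture_geometries[[key]]
  molecule(g$atoms, g$xyz)
}

#' @rdname fixture_molecule
#' @export
fixture_names <- function() names(.fixture_geometries)

#' Read a molecule from an XYZ file
#'
#' Standard XYZ format: atom count, comment line, then `element x y z` in
#' Angstrom.
#'
#' @param path file path
#' @param charge,multiplicity passed to [molecule()]
#' @return a [molecule()] object
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed XYZ file: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ file at line 1: atom count expected")
  if (length(lines) < n + 2L)
    stop("malformed XYZ file: ", n, " atoms declared, ",
         length(lines) - 2L, " coordinate lines present")
  atoms <- character(n)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 2L]), "\\s+")[[1]]
    if (length(tok) < 4L)
      stop("malformed XYZ file at line ", i + 2L)
    atoms[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v))) stop("malformed XYZ file at line ", i + 2L,
                            ": non-numeric coordinate")
    xyz[i, ] <- v
  }
  molecule(atoms, xyz, charge = charge, multiplicity = multiplicity)
}

#' Write a molecule to an XYZ file
#'
#' @param molecule a [molecule()] object
#' @param path output file path
#' @param comment comment line content
#' @export
write_xyz <- function(molecule, path, comment = "") {
  lines <- c(as.character(length(molecule$atoms)), comment,
             sprintf("%-2s %18.10f %18.10f %18.10f", molecule$atoms,
                     molecule$xyz[, 1], molecule$xyz[, 2], molecule$xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Nuclear repulsion energy (Hartree)
#' @param molecule a [molecule()] object
#' @export
nuclear_repulsion <- function(molecule) {
  e <- 0
  n <- length(molecule$atoms)
  if (n < 2) return(0)
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      e <- e + molecule$z[i] * molecule$z[j] /
        sqrt(sum((molecule$xyz_bohr[i, ] - molecule$xyz_bohr[j, ])^2))
  e
}
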