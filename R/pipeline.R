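# End-to-end workflow: configuration, canonical and reduced-cost runs,
# results tables, error statistics.

#' Assemble a run configuration
#'
#' @param molecule a [molecule()] object, a fixture name, or an XYZ path
#' @param basis,aux_basis orbital / auxiliary basis names
#' @param cvs element symbol(s) whose K-edges to compute, or `"auto"` for
#'   every second-row element present (C, N, O, F)
#' @param n_states states per edge
#' @param mode `"canonical"` (no compression) or `"reduced"` (global NAF
#'   truncation + per-state VNO and second NAF truncation)
#' @param eps_naf NAF singular-value threshold (au); default 0.1
#' @param eps_vno VNO occupation threshold; default 7.5e-5
#' @param frozen_policy passed to [partition_orbitals()]
#' @param e_tol,r_tol solver tolerances (Hartree, residual norm)
#' @return an `rcadc_config` list
#' @export
run_config <- function(molecule, basis = "6-31g", aux_basis = "autoaux",
                       cvs = "auto", n_states = 3L,
                       mode = c("canonical", "reduced"),
                       eps_naf = 0.1, eps_vno = 7.5e-5,
                       frozen_policy = "other-cores",
                       e_tol = 1e-6, r_tol = 1e-5) {
  mode <- match.arg(mode)
  if (eps_naf < 0 || eps_vno < 0) stop("thresholds must be >= 0")
  if (is.character(molecule)) molecule <- load_geometry(molecule)
  structure(list(molecule = molecule, basis = basis, aux_basis = aux_basis,
                 cvs = cvs, n_states = as.integer(n_states), mode = mode,
                 eps_naf = eps_naf, eps_vno = eps_vno,
                 frozen_policy = frozen_policy,
                 e_tol = e_tol, r_tol = r_tol),
            class = "rcadc_config")
}

#' Resolve a geometry argument to a molecule
#'
#' Accepts a built-in fixture name or a path to an XYZ file.
#' @param x fixture name or file path
#' @return a [molecule()] object
#' @export
load_geometry <- function(x) {
  if (inherits(x, "rcadc_molecule")) return(x)
  if (tolower(x) %in% fixture_names()) return(fixture_molecule(x))
  if (file.exists(x)) return(read_xyz(x))
  stop("geometry '", x, "' is neither a fixture name nor an existing file")
}

.resolve_edges <- function(molecule, cvs) {
  if (identical(cvs, "auto"))
    cvs <- intersect(c("C", "N", "O", "F"), unique(molecule$atoms))
  if (length(cvs) == 0L)
    stop("no K-edge element found for this molecule; give cvs= explicitly")
  cvs
}

#' Run a CVS-ADC(2) calculation
#'
#' Executes the full workflow for each requested K-edge: Hartree-Fock
#' reference, CVS partition, three-center tensor assembly, (in reduced mode)
#' global NAF truncation, CVS-CIS for all states, and then either the
#' canonical folded CVS-ADC(2) solution or the per-state reduced-subspace
#' loop (state-averaged density, VNOs, second NAF truncation, reduced-space
#' MP2 + CVS-ADC(2)), with dipole-length oscillator strengths throughout.
#'
#' @param config an `rcadc_config` from [run_config()]
#' @param ref optionally a precomputed `rcadc_scf` reference (reused across
#'   canonical/reduced pairs)
#' @return an `rcadc_results` data frame, one row per state: `edge`,
#'   `state`, `omega_ev`, `f`, `vno_pct`, `naf_pct`, `cis_overlap`,
#'   `converged`, `omega_hartree`
#' @export
run_calculation <- function(config, ref = NULL) {
  stopifnot(inherits(config, "rcadc_config"))
  if (is.null(ref))
    ref <- compute_reference(config$molecule, config$basis, config$aux_basis)
  edges <- .resolve_edges(config$molecule, config$cvs)
  rows <- list()
  for (el in edges) {
    stage <- paste0(el, " K-edge")
    space <- partition_orbitals(ref, el, config$frozen_policy)
    df <- assemble_J(ref, space)
    n_Q_full <- df$n_Q
    if (config$mode == "reduced") {
      naf1 <- build_naf(df, config$eps_naf)
      df <- apply_naf(df, naf1)
    }
    asys <- adc_system(df, "cvs")
    mp2 <- mp2_intermediates(asys)
    cis <- tryCatch(solve_cis(asys, config$n_states),
                    error = function(e)
                      stop(stage, " / CVS-CIS: ", conditionMessage(e)))
    if (config$mode == "canonical") {
      states <- tryCatch(solve_adc2(asys, mp2, cis, e_tol = config$e_tol,
                                    r_tol = config$r_tol),
                         error = function(e)
                           stop(stage, " / CVS-ADC(2): ", conditionMessage(e)))
      for (k in seq_along(states)) {
        st <- states[[k]]
        mom <- oscillator_strength(st, asys, mp2)
        rows[[length(rows) + 1L]] <- data.frame(
          edge = el, state = k, omega_ev = st$omega_ev, f = mom$f,
          vno_pct = 100, naf_pct = 100, cis_overlap = st$cis_overlap,
          converged = st$converged, omega_hartree = st$omega)
      }
    } else {
      d_mp2 <- mp2_vv_density(asys, mp2)
      for (k in seq_len(config$n_states)) {
        red <- tryCatch(
          reduce_state(df, asys, mp2, d_mp2, cis$vectors[, k],
                       cis$omega[k], config$eps_vno, config$eps_naf),
          error = function(e)
            stop(stage, " state ", k, " / reduction: ", conditionMessage(e)))
        asys_r <- adc_system(red$df, "cvs")
        mp2_r <- mp2_intermediates(asys_r)
        guess <- list(omega = cis$omega[k],
                      vectors = matrix(as.vector(red$r), ncol = 1))
        st <- tryCatch(
          solve_adc2(asys_r, mp2_r, guess, e_tol = config$e_tol,
                     r_tol = config$r_tol)[[1]],
          error = function(e)
            stop(stage, " state ", k, " / CVS-ADC(2): ",
                 conditionMessage(e)))
        mom <- oscillator_strength(st, asys_r, mp2_r)
        rows[[length(rows) + 1L]] <- data.frame(
          edge = el, state = k, omega_ev = st$omega_ev, f = mom$f,
          vno_pct = red$vno_pct,
          naf_pct = 100 * red$naf_pct / 100 * df$n_Q / n_Q_full,
          cis_overlap = st$cis_overlap, converged = st$converged,
          omega_hartree = st$omega)
      }
    }
  }
  out <- do.call(rbind, rows)
  # report each edge as a spectrum: ascending energies, state = rank
  out <- do.call(rbind, lapply(split(out, out$edge), function(b) {
    b <- b[order(b$omega_ev), , drop = FALSE]
    b$state <- seq_len(nrow(b))
    b
  }))
  out <- out[order(match(out$edge, edges)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- config$mode
  attr(out, "basis") <- config$basis
  attr(out, "molecule") <- paste(config$molecule$atoms, collapse = "")
  class(out) <- c("rcadc_results", class(out))
  out
}

#' @export
print.rcadc_results <- function(x, ...) {
  cat(sprintf("CVS-ADC(2) results (%s mode, %s)\n",
              attr(x, "mode") %||% "?", attr(x, "basis") %||% "?"))
  cat(sprintf("%-6s %5s %10s %8s %13s %13s\n",
              "edge", "state", "omega(eV)", "f", "retained VNO%",
              "retained NAF%"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-6s %5d %10.2f %8.4f %13.1f %13.1f\n",
                x$edge[i], x$state[i], x$omega_ev[i], x$f[i],
                x$vno_pct[i], x$naf_pct[i]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a results table
#'
#' Writes the fixed-format text table (eV to 2 decimals, f to 4) and/or a
#' full-precision JSON record.
#'
#' @param table an `rcadc_results` table
#' @param path output path (extension `.json` selects JSON)
#' @export
write_results <- function(table, path) {
  if (nrow(table) == 0L) stop("empty results table")
  if (grepl("\\.json$", path)) {
    payload <- list(mode = attr(table, "mode"), basis = attr(table, "basis"),
                    molecule = attr(table, "molecule"),
                    rows = as.data.frame(unclass(table)[
                      c("edge", "state", "omega_ev", "f", "vno_pct",
                        "naf_pct", "cis_overlap", "converged",
                        "omega_hartree")]))
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  } else {
    con <- file(path, "w")
    sink(con); print(table); sink()
    close(con)
  }
  invisible(path)
}

#' @rdname write_results
#' @param path JSON file written by [write_results()]
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- payload$rows
  attr(out, "mode") <- payload$mode
  attr(out, "basis") <- payload$basis
  attr(out, "molecule") <- payload$molecule
  class(out) <- c("rcadc_results", class(out))
  out
}

#' Error statistics between a canonical and a reduced results table
#'
#' Mean/maximum absolute error and standard deviation on excitation
#' energies, and mean/maximum relative error on oscillator strengths
#' restricted to transitions with canonical `f >` `f_threshold`.
#'
#' @param canonical,reduced `rcadc_results` tables over the same states
#' @param f_threshold intensity cutoff for the relative-f statistics
#' @param exclude_degenerate drop one partner of each degenerate pair
#'   (energies within `degeneracy_window` eV on the same edge) from the
#'   statistics
#' @param degeneracy_window eV window defining degeneracy
#' @return list: `n`, `mae`, `max_abs`, `sd`, `mean_error` (eV);
#'   `n_f`, `mre_f`, `max_rel_f`
#' @export
error_stats <- function(canonical, reduced, f_threshold = 0.015,
                        exclude_degenerate = FALSE,
                        degeneracy_window = 1e-3) {
  key <- function(t) paste(attr(t, "molecule") %||% "", t$edge, t$state)
  if (!identical(key(canonical), key(reduced)))
    stop("tables do not cover the same states")
  keep <- rep(TRUE, nrow(canonical))
  if (exclude_degenerate && nrow(canonical) > 1) {
    grp <- paste(canonical$edge)
    for (i in seq.int(2L, nrow(canonical)))
      for (j in seq_len(i - 1L))
        if (keep[j] && grp[i] == grp[j] &&
            abs(canonical$omega_ev[i] - canonical$omega_ev[j]) <
              degeneracy_window)
          keep[i] <- FALSE
  }
  dw <- reduced$omega_ev[keep] - canonical$omega_ev[keep]
  fc <- canonical$f[keep]; fr <- reduced$f[keep]
  sel <- fc > f_threshold
  rel <- abs(fr[sel] - fc[sel]) / fc[sel]
  list(n = length(dw), mae = mean(abs(dw)), max_abs = max(abs(dw)),
       sd = stats::sd(dw), mean_error = mean(dw),
       n_f = sum(sel), mre_f = if (any(sel)) mean(rel) else NA_real_,
       max_rel_f = if (any(sel)) max(rel) else NA_real_)
}

#' Canonical-vs-reduced K-edge benchmark over the fixture suite
#'
#' Runs canonical and reduced (default thresholds) CVS-ADC(2) for the three
#' lowest K-edge states of every second-row element in each fixture, and
#' returns both tables plus the error statistics.  This is the package's
#' scaled-down analogue of a full benchmark campaign.
#'
#' @param molecules fixture names
#' @param basis orbital basis
#' @param n_states states per edge
#' @param eps_naf,eps_vno reduced-mode thresholds
#' @param verbose print progress
#' @return list: `canonical`, `reduced` (row-bound `rcadc_results`),
#'   `stats` from [error_stats()]
#' @export
kedge_benchmark <- function(molecules = c("h2o", "nh3", "co", "hf",
                                          "c2h4", "h2co"),
                            basis = "6-31g", n_states = 3L,
                            eps_naf = 0.1, eps_vno = 7.5e-5,
                            verbose = FALSE) {
  can_all <- list(); red_all <- list()
  for (mname in molecules) {
    mol <- load_geometry(mname)
    ref <- compute_reference(mol, basis)
    cfg_c <- run_config(mol, basis = basis, n_states = n_states,
                        mode = "canonical")
    cfg_r <- run_config(mol, basis = basis, n_states = n_states,
                        mode = "reduced", eps_naf = eps_naf,
                        eps_vno = eps_vno)
    if (verbose) message("running ", mname, " (canonical) ...")
    tc <- run_calculation(cfg_c, ref = ref)
    if (verbose) message("running ", mname, " (reduced) ...")
    tr <- run_calculation(cfg_r, ref = ref)
    tc$molecule <- mname; tr$molecule <- mname
    can_all[[mname]] <- tc; red_all[[mname]] <- tr
  }
  canonical <- do.call(rbind, can_all)
  reduced <- do.call(rbind, red_all)
  attr(canonical, "mode") <- "canonical"; attr(reduced, "mode") <- "reduced"
  attr(canonical, "basis") <- basis; attr(reduced, "basis") <- basis
  class(canonical) <- c("rcadc_results", class(canonical))
  class(reduced) <- c("rcadc_results", class(reduced))
  key <- function(t) paste(t$molecule, t$edge, t$state)
  stopifnot(identical(key(canonical), key(reduced)))
  dw <- reduced$omega_ev - canonical$omega_ev
  sel <- canonical$f > 0.015
  rel <- abs(reduced$f[sel] - canonical$f[sel]) / canonical$f[sel]
  stats <- list(n = length(dw), mae = mean(abs(dw)), max_abs = max(abs(dw)),
                sd = stats::sd(dw), n_f = sum(sel), mre_f = mean(rel),
                max_rel_f = if (any(sel)) max(rel) else NA_real_)
  list(canonical = canonical, reduced = reduced, stats = stats)
}
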