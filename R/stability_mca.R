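# Linearization of sampled steady-state models, stability classification from
# Jacobian eigenvalues, elasticities, control coefficients, and ensemble
# aggregation into median/MAD summaries and variant comparisons.

#' Reduced Jacobian of a kinetic model at steady state
#'
#' `J = N_R (dv/dS) L` over the independent internal species (units 1/min),
#' with conservation relations removed through the link matrix. Derivatives
#' `dv/dS` are analytic for every supported rate law; a central
#' finite-difference evaluation is available through `method = "fd"` as a
#' cross-check.
#'
#' @param model A `kinetic_model`.
#' @param state Named steady-state concentration vector (mM).
#' @param params Completed parameter set (Vmax filled in).
#' @param thermo A [thermo_config()].
#' @param method `"analytic"` (default) or `"fd"` (central differences,
#'   relative step 1e-6).
#' @param check_steady If `TRUE`, error when `||N v||` exceeds
#'   `1e-6 * max|v|`.
#' @return List with `J` (reduced Jacobian), `E` (unscaled dv/dS over internal
#'   species), `v` (rates), and the moiety decomposition (`L`, `N_R`,
#'   `independent`).
#' @export
jacobian_matrix <- function(model, state, params, thermo = thermo_config(),
                            method = c("analytic", "fd"),
                            check_steady = TRUE) {
  method <- match.arg(method)
  mo <- conserved_moieties(model)
  if (method == "analytic") {
    rg <- rate_gradients(model, state, params, thermo)
    v <- rg$v; E <- rg$E
  } else {
    v <- evaluate_rates(model, state, params, thermo)
    E <- fd_gradients(model, state, params, thermo)
  }
  if (check_steady) {
    res <- max(abs(model$N_internal %*% v))
    if (res > 1e-6 * max(abs(v), 1e-300)) {
      stop(sprintf("state is not a steady state (residual %.3g)", res))
    }
  }
  J <- mo$N_R %*% E %*% mo$L
  list(J = J, E = E, v = v, L = mo$L, N_R = mo$N_R,
       independent = mo$independent)
}

# central finite-difference dv/dS over internal species
fd_gradients <- function(model, state, params, thermo = thermo_config(),
                         rel_step = 1e-6, species = model$internal) {
  E <- matrix(0, nrow = length(model$reactions), ncol = length(species),
              dimnames = list(names(model$reactions), species))
  for (s in species) {
    h <- rel_step * state[[s]]
    up <- state; up[s] <- up[s] + h
    dn <- state; dn[s] <- dn[s] - h
    E[, s] <- (evaluate_rates(model, up, params, thermo) -
                 evaluate_rates(model, dn, params, thermo)) / (2 * h)
  }
  E
}

#' Classify Jacobian stability
#'
#' A model is stable when the largest real part of the Jacobian eigenvalues
#' is strictly below `-tol * ||J||` (spectral abscissa with a relative
#' tolerance). Eigenvalues within the tolerance band around zero are
#' classified unstable and flagged as boundary cases.
#'
#' @param J Square numeric Jacobian (1/min).
#' @param tol Relative tolerance on the real part.
#' @return List with `stable`, `max_re_eig`, and `boundary`.
#' @export
classify_stability <- function(J, tol = 1e-9) {
  if (!is.matrix(J) || nrow(J) != ncol(J)) stop("J must be square")
  if (any(!is.finite(J))) stop("J contains non-finite entries")
  ev <- eigen(J, only.values = TRUE)$values
  mre <- max(Re(ev))
  thr <- tol * max(norm(J, "F"), .Machine$double.xmin)
  list(stable = mre < -thr, max_re_eig = mre, boundary = abs(mre) <= thr)
}

#' Scaled elasticity matrix
#'
#' Scaled local sensitivities `eps_ij = (dv_i/dS_j) S_j / v_i` of every rate
#' to every internal metabolite at a state. Rows of zero-flux reactions cannot
#' be scaled and are returned unscaled with a flag.
#'
#' @param model A `kinetic_model`.
#' @param state Named concentration vector.
#' @param params Completed parameter set.
#' @param thermo A [thermo_config()].
#' @return List with `scaled` (reactions x internal species), `unscaled`
#'   (dv/dS), `v`, and `zero_flux` (logical per reaction).
#' @export
elasticity_matrix <- function(model, state, params,
                              thermo = thermo_config()) {
  rg <- rate_gradients(model, state, params, thermo)
  v <- rg$v
  E <- rg$E
  S <- state[colnames(E)]
  zero <- abs(v) < 1e-300
  sc <- E * rep(S, each = nrow(E))
  sc[!zero, ] <- sc[!zero, , drop = FALSE] / v[!zero]
  list(scaled = sc, unscaled = E, v = v, zero_flux = zero)
}

#' Control coefficients from elasticities
#'
#' Metabolic control analysis at a stable steady state. With `E = dv/dS`
#' (unscaled), `N_R` and `L` from the moiety decomposition,
#' `C_S = -L (N_R E L)^(-1) N_R` (unscaled concentration control) and
#' `C_J = I + E C_S` (unscaled flux control). Scaled coefficients divide by
#' steady-state fluxes/concentrations; rows of scaled `C_J` sum to 1 and rows
#' of scaled `C_S` sum to 0 (summation theorems). Rows of `C_J` for zero-flux
#' reactions are returned unscaled and flagged.
#'
#' @param model A `kinetic_model`.
#' @param state Named steady-state concentration vector.
#' @param params Completed parameter set.
#' @param thermo A [thermo_config()].
#' @param jac Optional output of [jacobian_matrix()] to avoid recomputation.
#' @return List with `fcc` (scaled flux control, reactions x reactions),
#'   `ccc` (scaled concentration control, internal species x reactions),
#'   their unscaled forms, `v`, and `zero_flux`.
#' @export
control_coefficients <- function(model, state, params,
                                 thermo = thermo_config(), jac = NULL) {
  if (is.null(jac)) jac <- jacobian_matrix(model, state, params, thermo)
  M <- jac$N_R %*% jac$E %*% jac$L
  Minv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Minv)) {
    stop("singular reduced Jacobian; model is degenerate, no coefficients")
  }
  CS_u <- -jac$L %*% Minv %*% jac$N_R            # species x reactions
  CJ_u <- diag(nrow(jac$E)) + jac$E %*% CS_u     # reactions x reactions
  dimnames(CJ_u) <- list(names(model$reactions), names(model$reactions))
  v <- jac$v
  S <- state[rownames(CS_u)]
  zero <- abs(v) < 1e-300
  fcc <- CJ_u * rep(v, each = nrow(CJ_u))        # multiply columns by v_j
  fcc[!zero, ] <- fcc[!zero, , drop = FALSE] / v[!zero]
  ccc <- CS_u * rep(v, each = nrow(CS_u)) / S
  list(fcc = fcc, ccc = ccc, fcc_unscaled = CJ_u, ccc_unscaled = CS_u,
       v = v, zero_flux = zero)
}

#' Run an ensemble of sampled kinetic models
#'
#' For each feasible concentration set, draws `cfg$n_param_sets_per_conc`
#' parameter sets, back-calculates Vmax against the reference flux
#' distribution, classifies Jacobian stability, and computes flux control
#' coefficients for the stable models. Individual model failures are logged
#' and counted, never abort the ensemble. Fully reproducible given the
#' config seed.
#'
#' @param model A `kinetic_model`.
#' @param flux Named steady-state flux vector (mM/min).
#' @param thermo A [thermo_config()].
#' @param cfg A [sampling_config()].
#' @param conc_sets Optional list of concentration states (as returned in
#'   `sample_concentrations()$states`); sampled when `NULL`.
#' @param keep_fcc Keep per-model FCC matrices for aggregation (default TRUE).
#' @return List of class `ensemble_result`: `records` (data frame with
#'   conc_set, param_set, stable, max_re_eig, failed), `summary` (see
#'   [summarize_ensemble()]), `fcc` (3-d array stable models x flux x
#'   reaction, when kept), and `n_failed`.
#' @export
run_ensemble <- function(model, flux, thermo = thermo_config(),
                         cfg = sampling_config(), conc_sets = NULL,
                         keep_fcc = TRUE) {
  if (is.null(conc_sets)) {
    conc_sets <- sample_concentrations(model, flux, thermo, cfg)$states
  }
  nc <- length(conc_sets)
  np <- cfg$n_param_sets_per_conc
  rxn <- names(model$reactions)
  nr <- length(rxn)
  records <- data.frame(conc_set = rep(seq_len(nc), each = np),
                        param_set = rep(seq_len(np), nc),
                        stable = FALSE, max_re_eig = NA_real_,
                        failed = FALSE)
  fcc_store <- if (keep_fcc) array(NA_real_, c(nc * np, nr, nr),
                                   dimnames = list(NULL, rxn, rxn)) else NULL
  n_stable <- 0L
  for (ic in seq_len(nc)) {
    state <- conc_sets[[ic]]
    for (ip in seq_len(np)) {
      row <- (ic - 1L) * np + ip
      seed <- child_seed(cfg$seed, "param", row)
      ok <- tryCatch({
        params <- sample_parameters(model, state, cfg, seed = seed)
        params <- back_calculate_vmax(model, state, params, flux, thermo)
        jac <- jacobian_matrix(model, state, params, thermo)
        st <- classify_stability(jac$J)
        records$stable[row] <- st$stable
        records$max_re_eig[row] <- st$max_re_eig
        if (st$stable && keep_fcc) {
          cc <- control_coefficients(model, state, params, thermo, jac = jac)
          n_stable <- n_stable + 1L
          fcc_store[row, , ] <- cc$fcc
        }
        TRUE
      }, error = function(e) FALSE)
      if (!ok) records$failed[row] <- TRUE
    }
  }
  if (keep_fcc) {
    keep <- which(records$stable & !records$failed)
    fcc_store <- fcc_store[keep, , , drop = FALSE]
    fcc_conc <- records$conc_set[keep]
  } else {
    fcc_store <- NULL; fcc_conc <- integer(0)
  }
  res <- structure(list(records = records, fcc = fcc_store,
                        fcc_conc_set = fcc_conc,
                        n_failed = sum(records$failed), variant = model$variant,
                        reactions = rxn),
                   class = "ensemble_result")
  res$summary <- summarize_ensemble(res)
  res
}

#' Summarize an ensemble
#'
#' Computes the stable fraction per concentration set and its median across
#' sets (the headline stability statistic), the pooled stable fraction, and
#' median/MAD flux control coefficients over all stable models (pooled), plus
#' the median across concentration sets of per-set FCC medians.
#'
#' @param ens An `ensemble_result`.
#' @return List with `stable_fraction_per_conc`, `median_stable_fraction`,
#'   `pooled_stable_fraction`, `fcc_median`, `fcc_mad`,
#'   `fcc_median_stratified`, and `n_stable`.
#' @export
summarize_ensemble <- function(ens) {
  rec <- ens$records
  ok <- !rec$failed
  frac <- tapply(rec$stable[ok], rec$conc_set[ok], mean)
  out <- list(stable_fraction_per_conc = as.numeric(frac),
              median_stable_fraction = stats::median(as.numeric(frac)),
              pooled_stable_fraction = mean(rec$stable[ok]),
              n_stable = sum(rec$stable[ok]))
  if (!is.null(ens$fcc) && dim(ens$fcc)[1] > 0) {
    out$fcc_median <- apply(ens$fcc, c(2, 3), stats::median)
    # raw median absolute deviation (no consistency constant)
    out$fcc_mad <- apply(ens$fcc, c(2, 3), stats::mad, constant = 1)
    concs <- unique(ens$fcc_conc_set)
    per_conc <- lapply(concs, function(ic)
      apply(ens$fcc[ens$fcc_conc_set == ic, , , drop = FALSE], c(2, 3),
            stats::median))
    out$fcc_median_stratified <-
      apply(simplify2array(per_conc), c(1, 2), stats::median)
  } else {
    out$fcc_median <- out$fcc_mad <- out$fcc_median_stratified <- NULL
  }
  out
}

#' Compare two ensemble summaries
#'
#' Differences between a regulated-variant and a base-variant ensemble run on
#' identical concentration sets: per (flux, reaction) change in median FCC,
#' its sign table, and the change in median stability.
#'
#' @param summary_base,summary_reg Summaries from [summarize_ensemble()] (or
#'   `ensemble_result` objects).
#' @return List with `delta_fcc` (median_reg - median_base), `sign`
#'   (sign table), and `delta_median_stability`.
#' @export
compare_variants <- function(summary_base, summary_reg) {
  if (inherits(summary_base, "ensemble_result")) summary_base <- summary_base$summary
  if (inherits(summary_reg, "ensemble_result")) summary_reg <- summary_reg$summary
  mb <- summary_base$fcc_median
  mr <- summary_reg$fcc_median
  if (is.null(mb) || is.null(mr)) stop("both summaries need FCC medians")
  if (!identical(dimnames(mb), dimnames(mr))) {
    stop("reaction sets of the two summaries do not align")
  }
  d <- mr - mb
  list(delta_fcc = d, sign = sign(d),
       delta_median_stability = summary_reg$median_stable_fraction -
         summary_base$median_stable_fraction)
}
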