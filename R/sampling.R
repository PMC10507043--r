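# Thermodynamically constrained sampling of metabolite concentrations and
# kinetic parameters, and back-calculation of Vmax so every sampled model
# reproduces the reference steady-state flux distribution.

#' Sampling configuration
#'
#' Ranges and counts controlling the ensemble construction. K_M values are
#' drawn log-uniformly between 0.1x and 10x the sampled concentration of the
#' corresponding metabolite; regulation constants (K_i, K_a) log-uniformly
#' between 0.5x and 2x the effector concentration used in the enzyme assays;
#' the F/SBPase Hill exponent uniformly between 1 and 1.5.
#'
#' @param n_conc_sets Number of feasible concentration sets to draw.
#' @param n_param_sets_per_conc Parameter sets per concentration set.
#' @param km_fold_range Fold range around metabolite concentration for K_M.
#' @param effector_fold_range Fold range around assay concentration for
#'   K_i/K_a.
#' @param hill_range Range of the F/SBPase Hill exponent.
#' @param assay_concs Named vector of effector assay concentrations in mM
#'   (defaults: GAP 0.5 mM, NADPH 3 mM).
#' @param seed Root seed; per-stage child seeds are derived from it.
#' @return A list of class `sampling_config`.
#' @export
sampling_config <- function(n_conc_sets = 10, n_param_sets_per_conc = 10,
                            km_fold_range = c(0.1, 10),
                            effector_fold_range = c(0.5, 2),
                            hill_range = c(1, 1.5),
                            assay_concs = c(GAP = 0.5, NADPH = 3),
                            seed = 1L) {
  stopifnot(n_conc_sets >= 1, n_param_sets_per_conc >= 1,
            all(km_fold_range > 0), km_fold_range[1] < km_fold_range[2],
            all(effector_fold_range > 0),
            effector_fold_range[1] < effector_fold_range[2],
            hill_range[1] <= hill_range[2], hill_range[1] >= 1)
  structure(list(n_conc_sets = as.integer(n_conc_sets),
                 n_param_sets_per_conc = as.integer(n_param_sets_per_conc),
                 km_fold_range = km_fold_range,
                 effector_fold_range = effector_fold_range,
                 hill_range = hill_range, assay_concs = assay_concs,
                 seed = as.integer(seed)), class = "sampling_config")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# deterministic child seed below 2^31
child_seed <- function(root, stage, i = 0L) {
  (as.integer(root) * 1009L + match(stage, c("conc", "param", "synth",
                                             "ensemble", "misc")) * 7919L +
     as.integer(i)) %% 2147483647L
}

#' Thermodynamic feasibility of a concentration state
#'
#' Computes `dG = dG0' + RT ln Q` for every reaction carrying a standard
#' transformed Gibbs energy and checks the second-law condition that every
#' flux-carrying reaction dissipates energy: `dG * sign(v) < 0` (strict;
#' equilibrium states are infeasible).
#'
#' @param model A `kinetic_model`.
#' @param state Named concentration vector (mM), all positive.
#' @param flux Named flux vector (mM/min) over the model's reactions.
#' @param thermo A [thermo_config()].
#' @return List with `dg` (named vector, NA where no dG0' is defined) and
#'   `feasible` (logical scalar).
#' @export
check_thermo_feasible <- function(model, state, flux,
                                  thermo = thermo_config()) {
  if (any(!is.finite(state)) || any(state <= 0)) {
    stop("concentrations must be positive and finite")
  }
  RT <- thermo$gas_constant * thermo$temperature
  dg <- rep(NA_real_, length(model$reactions))
  names(dg) <- names(model$reactions)
  for (r in model$reactions) {
    if (is.na(r$delta_g0)) next
    st <- kinetic_species(model, r)
    lnQ <- sum(st * log(state[names(st)]))
    dg[r$id] <- r$delta_g0 + RT * lnQ
  }
  v <- flux[names(dg)]
  active <- !is.na(dg) & !is.na(v) & v != 0
  feasible <- all(dg[active] * sign(v[active]) < 0)
  list(dg = dg, feasible = feasible)
}

#' Sample thermodynamically feasible concentration sets
#'
#' Draws internal metabolite concentrations log-uniformly within their
#' declared ranges (external metabolites stay clamped at their reference
#' values) and rejects states failing [check_thermo_feasible()] for the given
#' flux directions, until `cfg$n_conc_sets` feasible sets are collected.
#'
#' @param model A `kinetic_model`.
#' @param flux Named steady-state flux vector (mM/min).
#' @param thermo A [thermo_config()].
#' @param cfg A [sampling_config()].
#' @param seed Seed (defaults to the config's conc-stage child seed).
#' @return List with `states` (list of named concentration vectors), `dg`
#'   (list of per-reaction dG vectors), `acceptance_rate`, and `n_proposed`.
#' @export
sample_concentrations <- function(model, flux, thermo = thermo_config(),
                                  cfg = sampling_config(), seed = NULL) {
  if (is.null(seed)) seed <- child_seed(cfg$seed, "conc")
  m <- model$metabolites
  im <- m[m$role == "internal", ]
  with_seed(seed, {
    states <- vector("list", cfg$n_conc_sets)
    dgs <- vector("list", cfg$n_conc_sets)
    got <- 0L; proposed <- 0L
    viol_count <- stats::setNames(numeric(length(model$reactions)),
                                  names(model$reactions))
    while (got < cfg$n_conc_sets) {
      proposed <- proposed + 1L
      conc <- exp(stats::runif(nrow(im), log(im$lower), log(im$upper)))
      names(conc) <- im$id
      state <- c(conc, model$external_conc)
      chk <- check_thermo_feasible(model, state, flux, thermo)
      if (chk$feasible) {
        got <- got + 1L
        states[[got]] <- state
        dgs[[got]] <- chk$dg
      } else {
        v <- flux[names(chk$dg)]
        bad <- !is.na(chk$dg) & !is.na(v) & v != 0 & chk$dg * sign(v) >= 0
        viol_count[bad] <- viol_count[bad] + 1
      }
      if (proposed >= 1e6 && got / proposed < 1e-4) {
        stop(sprintf(paste0("thermodynamic sampling acceptance below 1e-4 ",
                            "after %d proposals; most-violated reaction: %s"),
                     proposed, names(which.max(viol_count))))
      }
    }
    list(states = states, dg = dgs, acceptance_rate = got / proposed,
         n_proposed = proposed)
  })
}

#' Sample a kinetic parameter set (without Vmax)
#'
#' K_M values are drawn log-uniformly in `km_fold_range` (default 0.1x-10x)
#' around the corresponding metabolite's concentration in `state`; regulation
#' constants K_i/K_a log-uniformly in `effector_fold_range` (default 0.5x-2x)
#' around the effector's assay concentration; the Hill exponent of reactions
#' declaring a Hill substrate uniformly within `hill_range` (default 1-1.5).
#' Vmax entries are left `NA`; see [back_calculate_vmax()].
#'
#' @param model A `kinetic_model`.
#' @param state Named concentration vector (mM).
#' @param cfg A [sampling_config()].
#' @param seed Optional seed.
#' @return A list of class `parameter_set` with elements `km`, `ki`, `ka`,
#'   `hill`, `vmax` (named numeric vectors).
#' @export
sample_parameters <- function(model, state, cfg = sampling_config(),
                              seed = NULL) {
  with_seed(seed, {
    km <- numeric(0); ki <- numeric(0); ka <- numeric(0)
    hill <- stats::setNames(rep(1, length(model$reactions)),
                            names(model$reactions))
    vmax <- stats::setNames(rep(NA_real_, length(model$reactions)),
                            names(model$reactions))
    for (r in model$reactions) {
      for (met in need_km(model, r)) {
        cme <- state[[met]]
        if (is.null(cme) || is.na(cme)) {
          stop(sprintf("state lacks concentration of '%s' (reaction '%s')",
                       met, r$id))
        }
        km[km_key(r$id, met)] <-
          exp(stats::runif(1, log(cfg$km_fold_range[1] * cme),
                           log(cfg$km_fold_range[2] * cme)))
      }
      for (term in r$regulations) {
        a <- cfg$assay_concs[[term$effector]]
        if (is.null(a) || is.na(a)) {
          stop(sprintf("no assay concentration configured for effector '%s'",
                       term$effector))
        }
        val <- exp(stats::runif(1, log(cfg$effector_fold_range[1] * a),
                                log(cfg$effector_fold_range[2] * a)))
        key <- km_key(r$id, term$effector)
        if (term$kind == "noncompetitive_inhibition") ki[key] <- val
        else ka[key] <- val
      }
      if (!is.na(r$hill_substrate)) {
        hill[r$id] <- stats::runif(1, cfg$hill_range[1], cfg$hill_range[2])
      }
    }
    structure(list(km = km, ki = ki, ka = ka, hill = hill, vmax = vmax),
              class = "parameter_set")
  })
}

#' Back-calculate Vmax from the steady-state flux distribution
#'
#' With all other constants fixed, every rate law is linear in Vmax, so
#' setting Vmax = 1 yields a normalized rate `vtilde` and
#' `Vmax = v / vtilde` makes the sampled model reproduce the reference flux
#' exactly. Reactions with zero flux get Vmax = 0. A sign mismatch between
#' `vtilde` and the target flux indicates a thermodynamically infeasible
#' state and raises an error.
#'
#' @param model A `kinetic_model`.
#' @param state Named concentration vector.
#' @param params Parameter set from [sample_parameters()].
#' @param flux Named target flux vector (mM/min).
#' @param thermo A [thermo_config()].
#' @return The completed `parameter_set` (Vmax filled in).
#' @export
back_calculate_vmax <- function(model, state, params, flux,
                                thermo = thermo_config()) {
  p1 <- params
  p1$vmax <- stats::setNames(rep(1, length(model$reactions)),
                             names(model$reactions))
  vt <- evaluate_rates(model, state, p1, thermo)
  v <- flux[names(vt)]
  vmax <- numeric(length(vt))
  names(vmax) <- names(vt)
  for (j in names(vt)) {
    if (is.na(v[j])) stop("flux distribution lacks reaction '", j, "'")
    if (v[j] == 0) { vmax[j] <- 0; next }
    if (abs(vt[j]) < 1e-12) {
      stop(sprintf("degenerate normalized rate for reaction '%s'", j))
    }
    if (sign(vt[j]) != sign(v[j])) {
      stop(sprintf("normalized rate of '%s' opposes the target flux (state infeasible)", j))
    }
    vmax[j] <- v[j] / vt[j]
  }
  params$vmax <- vmax
  params
}
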