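# Synthetic data generators with recorded ground truth: toy kinetic networks
# with exact steady states, peptide tables with planted interactions, assay
# plates generated through the forward Malachite-Green model, and melt curves.

#' Generate a toy kinetic network at an exact steady state
#'
#' Builds a small open network (supply -> chain or branch -> sinks) as a
#' `kinetic_model`, samples a positive concentration state and Michaelis
#' constants, chooses a consistent flux distribution, and back-calculates
#' Vmax so the returned tuple is an exact steady state. Chain topology:
#' `X0 -> S1 -> ... -> Sn -> Xout`. Branched topology adds a second drain at
#' the interior branch species.
#'
#' @param n_species Number of internal species (>= 1).
#' @param topology `"chain"` or `"branched"` (branched needs n_species >= 2).
#' @param seed Seed for reproducibility.
#' @param reversible Use reversible Michaelis-Menten laws for interior
#'   conversions (default FALSE: irreversible).
#' @return List with `model`, `state`, `params` (Vmax filled in), `flux`,
#'   and `truth` (the generating choices).
#' @export
gen_toy_network <- function(n_species, topology = c("chain", "branched"),
                            seed = 1L, reversible = FALSE) {
  topology <- match.arg(topology)
  stopifnot(n_species >= 1)
  if (topology == "branched" && n_species < 2) {
    stop("branched topology needs at least 2 internal species")
  }
  with_seed(seed, {
    ids <- paste0("S", seq_len(n_species))
    mets <- data.frame(id = c("X0", ids, "XOUT",
                              if (topology == "branched") "XBR"),
                       stringsAsFactors = FALSE)
    mets$name <- mets$id
    mets$role <- ifelse(mets$id %in% ids, "internal", "external")
    mets$lower <- 0.1; mets$upper <- 10
    eqs <- c(paste("X0 ->", ids[1]))
    laws <- c("mass_action")
    nodes <- c(ids, "XOUT")
    for (i in seq_len(n_species)) {
      interior <- i < n_species && reversible
      laws <- c(laws, if (interior) "reversible_mm" else "irreversible_mm")
      eqs <- c(eqs, paste(nodes[i], if (interior) "<->" else "->",
                          nodes[i + 1]))
    }
    rid <- c("SUPPLY", paste0("R", seq_len(n_species)))
    if (topology == "branched") {
      br <- max(1L, floor(n_species / 2))
      eqs <- c(eqs, paste(ids[br], "->", "XBR"))
      laws <- c(laws, "irreversible_mm")
      rid <- c(rid, "BRANCH")
    }
    dg0 <- ifelse(laws == "reversible_mm", 0, NA)
    # steady flux: supply splits at the branch point
    v <- stats::setNames(rep(1, length(rid)), rid)
    if (topology == "branched") {
      v["BRANCH"] <- 0.4
      v[paste0("R", br:n_species)] <- 0.6
    }
    tmp <- tempfile(fileext = ".txt")
    on.exit(unlink(tmp), add = TRUE)
    con <- file(tmp, "w")
    writeLines("[metabolites]", con)
    writeLines("id\tname\trole\tlower_mM\tupper_mM", con)
    for (i in seq_len(nrow(mets))) {
      writeLines(paste(mets$id[i], mets$name[i], mets$role[i],
                       mets$lower[i], mets$upper[i], sep = "\t"), con)
    }
    writeLines("[reactions]", con)
    writeLines("id\trate_law\tdg0_kJ_mol\thill_substrate\tequation", con)
    for (i in seq_along(rid)) {
      writeLines(paste(rid[i], laws[i], ifelse(is.na(dg0[i]), "NA", dg0[i]),
                       "NA", eqs[i], sep = "\t"), con)
    }
    writeLines("[regulations]", con)
    writeLines("reaction\tkind\teffector\tconstant_mM\tmax_km_reduction\tvariant",
               con)
    close(con)
    model <- build_calvin_model("base", model_file = tmp)

    # sample a state; for reversible interior steps enforce a downhill
    # concentration gradient so the flux direction is thermodynamically valid
    conc <- exp(stats::runif(n_species, log(0.5), log(5)))
    if (reversible && n_species > 1) conc <- sort(conc, decreasing = TRUE)
    state <- c(stats::setNames(conc, ids), model$external_conc)
    cfg <- sampling_config(assay_concs = c())
    params <- sample_parameters(model, state, cfg,
                                seed = child_seed(seed, "param"))
    params <- back_calculate_vmax(model, state, params, v)
    list(model = model, state = state, params = params, flux = v,
         truth = list(topology = topology, n_species = n_species,
                      seed = seed, flux = v, state = state))
  })
}

#' Generate a synthetic peptide table with planted interactions
#'
#' Log2 intensities are Gaussian (sd `sigma`) around log-normal
#' protein/peptide baselines spanning about four orders of magnitude. A
#' fraction of proteins is planted as interacting: a random subset (>= 1,
#' at least `min_affected`) of their peptides is shifted by `effect_log2` in
#' the treated groups (the `high` group receives the full effect, `low`
#' receives `low_fraction` of it). Each peptide-replicate record is observed
#' with probability `p_obs` to exercise the replicate-coverage filter.
#'
#' @param n_proteins Number of proteins (default 2000).
#' @param peptides_per_protein Mean peptides per protein (Poisson, >= 1;
#'   default 5).
#' @param frac_interacting Fraction of proteins with a planted effect.
#' @param effect_log2 Planted shift in log2 units.
#' @param sigma Within-group sd of log2 intensities.
#' @param n_reps Replicates per group (default 4).
#' @param groups Group labels (default control/low/high).
#' @param low_fraction Fraction of the effect applied in the `low` group.
#' @param min_affected Minimum planted peptides per interacting protein.
#' @param p_obs Per-record observation probability (default 0.9).
#' @param seed Seed.
#' @return List with `table` (peptide table) and `truth` (data frame of
#'   planted proteins, affected peptides, and effect sizes).
#' @export
gen_peptide_table <- function(n_proteins = 2000, peptides_per_protein = 5,
                              frac_interacting = 0.05, effect_log2 = 1,
                              sigma = 0.25, n_reps = 4,
                              groups = c("control", "low", "high"),
                              low_fraction = 0.5, min_affected = 1,
                              p_obs = 0.9, seed = 1L) {
  stopifnot(n_proteins >= 1, peptides_per_protein >= 1,
            frac_interacting >= 0, frac_interacting <= 1, sigma >= 0)
  with_seed(seed, {
    prot <- sprintf("P%04d", seq_len(n_proteins))
    npep <- pmax(1L, stats::rpois(n_proteins, peptides_per_protein))
    prot_base <- stats::rnorm(n_proteins, mean = 20, sd = 2) # ~4 logs dynamic
    interacting <- sort(sample(n_proteins, round(frac_interacting * n_proteins)))
    rows <- vector("list", n_proteins)
    truth_rows <- list()
    for (i in seq_len(n_proteins)) {
      peps <- sprintf("%s_pep%02d", prot[i], seq_len(npep[i]))
      pep_base <- prot_base[i] + stats::rnorm(npep[i], 0, 1)
      n_aff <- 0L; aff <- integer(0)
      if (i %in% interacting) {
        n_aff <- sample(seq.int(min(min_affected, npep[i]), npep[i]), 1)
        aff <- sample(npep[i], n_aff)
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(protein = prot[i], peptide = peps[aff],
                     effect_log2 = effect_log2, stringsAsFactors = FALSE)
      }
      g <- rep(groups, each = n_reps)
      shift <- stats::setNames(c(0, low_fraction * effect_log2, effect_log2),
                               groups)
      n_obs_rows <- npep[i] * length(g)
      l2 <- rep(pep_base, each = length(g)) + shift[g] *
        rep(seq_len(npep[i]) %in% aff, each = length(g)) +
        stats::rnorm(n_obs_rows, 0, sigma)
      rows[[i]] <- data.frame(protein = prot[i],
                              peptide = rep(peps, each = length(g)),
                              group = rep(g, npep[i]),
                              replicate = rep(rep(seq_len(n_reps),
                                                  length(groups)), npep[i]),
                              intensity = 2^l2, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    if (p_obs < 1) tab <- tab[stats::runif(nrow(tab)) < p_obs, ]
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
             else data.frame(protein = character(0), peptide = character(0),
                             effect_log2 = numeric(0))
    list(table = tab,
         truth = list(planted = truth, interacting_proteins = prot[interacting],
                      effect_log2 = effect_log2, sigma = sigma, seed = seed))
  })
}

#' Generate a synthetic Malachite-Green assay plate
#'
#' Generates absorbances through the forward model the analysis inverts:
#' Hill rates at the eight design substrate concentrations, linear phosphate
#' accumulation over the 10/20/30-min sampling times, conversion to A620 via
#' a standard curve, plus Gaussian absorbance noise. Per-condition true
#' parameters allow planting effector effects (e.g. a K_half reduced by a
#' saturating activator).
#'
#' @param true_hill Named list/vector with `Vmax` (uM/min), `K` (uM), `h` for
#'   the `-M` condition.
#' @param conditions Named list of parameter overrides per condition, e.g.
#'   `list(minusM = list(), plusM = list(K = 25))`.
#' @param noise_sd Absorbance noise sd (A620 units).
#' @param substrate_uM Design substrate concentrations.
#' @param times_min Sampling times (time zero added automatically).
#' @param slope,intercept True standard-curve parameters (A620 per uM).
#' @param seed Seed.
#' @return List with `plate` (long-format data frame), `standards`
#'   (triplicate 0-100 uM series), and `truth`.
#' @export
gen_assay_plate <- function(true_hill = c(Vmax = 2, K = 100, h = 1.3),
                            conditions = list(minusM = list()),
                            noise_sd = 0,
                            substrate_uM = c(0, 30, 55, 80, 110, 150, 220, 300),
                            times_min = c(10, 20, 30),
                            slope = 0.005, intercept = 0.05, seed = 1L) {
  th <- as.list(true_hill)
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (cond in names(conditions)) {
      pars <- utils::modifyList(th, conditions[[cond]])
      truth[[cond]] <- pars
      for (s in substrate_uM) {
        rate <- if (s > 0) hill_rate(s, pars$Vmax, pars$K, pars$h) else 0
        w <- sprintf("%s_S%g", cond, s)
        for (t in c(0, times_min)) {
          pi_uM <- rate * t
          a <- intercept + slope * pi_uM +
            if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
          rows[[length(rows) + 1L]] <-
            data.frame(well = w, substrate_uM = s, condition = cond,
                       time_min = t, A620 = a, stringsAsFactors = FALSE)
        }
      }
    }
    plate <- do.call(rbind, rows)
    sc <- expand.grid(conc_uM = seq(0, 100, by = 20), rep = 1:3)
    sc$A620 <- intercept + slope * sc$conc_uM +
      if (noise_sd > 0) stats::rnorm(nrow(sc), 0, noise_sd) else 0
    list(plate = plate, standards = sc[, c("conc_uM", "A620")],
         truth = list(hill = truth, slope = slope, intercept = intercept,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a synthetic nanoDSF melt curve
#'
#' Sum of sigmoidal transitions on the instrument's 20-95 degree C grid
#' (1 degree per minute), with Gaussian noise. The scattering trace carries
#' the same transitions so multi-population samples produce multiple
#' first-derivative peaks.
#'
#' @param tm_list True melting temperatures (each within 20-95).
#' @param amplitudes Transition amplitudes (recycled).
#' @param noise_sd Noise sd on the ratio.
#' @param width Transition width in degrees C (logistic scale).
#' @param seed Seed.
#' @return List with `curve` (data frame temp_C, ratio, scattering) and
#'   `truth`.
#' @export
gen_melt_curve <- function(tm_list = 55, amplitudes = 0.2, noise_sd = 0,
                           width = 2.5, seed = 1L) {
  stopifnot(all(tm_list > 20), all(tm_list < 95))
  amplitudes <- rep_len(amplitudes, length(tm_list))
  with_seed(seed, {
    tt <- seq(20, 95, by = 1)
    ratio <- 0.8
    for (i in seq_along(tm_list)) {
      ratio <- ratio + amplitudes[i] / (1 + exp(-(tt - tm_list[i]) / width))
    }
    if (noise_sd > 0) ratio <- ratio + stats::rnorm(length(tt), 0, noise_sd)
    scat <- 1
    for (i in seq_along(tm_list)) {
      scat <- scat + 10 * amplitudes[i] / (1 + exp(-(tt - tm_list[i]) / width))
    }
    if (noise_sd > 0) scat <- scat + stats::rnorm(length(tt), 0, 10 * noise_sd)
    list(curve = data.frame(temp_C = tt, ratio = ratio, scattering = scat),
         truth = list(tm = tm_list, amplitudes = amplitudes,
                      noise_sd = noise_sd, seed = seed))
  })
}
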