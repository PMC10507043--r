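# Orchestration of the analysis stages behind one entry point with a run
# configuration, deterministic seeding, and a manifest of outputs.

#' Run configuration for the analysis pipeline
#'
#' Validates stage selection, thresholds, and input paths before any stage
#' runs. Thresholds default to the study's rules: q < 0.01 for peptide
#' significance, p < 0.05 plus a >20% maximum rate change for kinetic
#' effects, and |dT_m| > 2 degrees C for thermal shifts.
#'
#' @param stages Character vector of stages to run, a subset of
#'   `c("synth", "lipsmap", "assay", "melt", "ensemble")`; dependency order
#'   is enforced internally.
#' @param out_dir Output run directory (created if absent).
#' @param seed Root seed for every stochastic stage.
#' @param q_threshold,p_threshold Significance thresholds in (0, 1].
#' @param effect_threshold Minimum relative rate change (0, inf).
#' @param delta_tm_threshold T_m shift rule in degrees C.
#' @param sampling A [sampling_config()] for the ensemble stage.
#' @param peptide_table Optional path to a peptide TSV (otherwise the synth
#'   stage's table is used).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(stages = c("synth", "lipsmap", "assay", "melt",
                                  "ensemble"),
                       out_dir = tempfile("calvinreg_run_"), seed = 1L,
                       q_threshold = 0.01, p_threshold = 0.05,
                       effect_threshold = 0.2, delta_tm_threshold = 2,
                       sampling = sampling_config(n_conc_sets = 5,
                                                  n_param_sets_per_conc = 20,
                                                  seed = seed),
                       peptide_table = NULL) {
  known <- c("synth", "lipsmap", "assay", "melt", "ensemble")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (th in c(q_threshold = q_threshold, p_threshold = p_threshold)) {
    if (!is.finite(th) || th <= 0 || th > 1) {
      stop("significance thresholds must lie in (0, 1]")
    }
  }
  if (effect_threshold < 0 || delta_tm_threshold < 0) {
    stop("effect and delta-Tm thresholds must be non-negative")
  }
  if (!is.null(peptide_table) && !file.exists(peptide_table)) {
    stop("peptide_table path does not exist: ", peptide_table)
  }
  structure(list(stages = known[known %in% stages], out_dir = out_dir,
                 seed = as.integer(seed), q_threshold = q_threshold,
                 p_threshold = p_threshold,
                 effect_threshold = effect_threshold,
                 delta_tm_threshold = delta_tm_threshold,
                 sampling = sampling, peptide_table = peptide_table),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order inside `config$out_dir`,
#' writing tab-separated outputs per stage and a JSON manifest recording the
#' package version, root seed, per-stage row counts and output digests.
#' Re-running with an identical configuration reproduces identical outputs.
#' A stage failure stops the run with partial outputs preserved and the
#' manifest marking the failure point.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "calvinreg",
                   version = as.character(utils::packageVersion("calvinreg")),
                   seed = config$seed, stages = list())
  outputs <- character(0)
  finish <- function() {
    manifest$digests <- as.list(tools::md5sum(outputs))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      finish()
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[name]] <<- c(list(status = "ok"), res)
  }
  od <- config$out_dir
  paths <- list(
    peptides = file.path(od, "peptide_table.tsv"),
    plate = file.path(od, "assay_plate.tsv"),
    standards = file.path(od, "assay_standards.tsv"),
    melt = file.path(od, "melt_curve.tsv"))

  run_stage("synth", function() {
    pep <- gen_peptide_table(n_proteins = 300, seed = child_seed(config$seed,
                                                                 "synth", 1))
    plate <- gen_assay_plate(conditions = list(minusM = list(),
                                               plusM = list(K = 25)),
                             noise_sd = 0.002,
                             seed = child_seed(config$seed, "synth", 2))
    melt <- gen_melt_curve(tm_list = 55, noise_sd = 0.002,
                           seed = child_seed(config$seed, "synth", 3))
    outputs <<- c(outputs,
                  write_tsv(pep$table, paths$peptides),
                  write_tsv(pep$truth$planted,
                            file.path(od, "peptide_truth.tsv")),
                  write_tsv(plate$plate, paths$plate),
                  write_tsv(plate$standards, paths$standards),
                  write_tsv(melt$curve, paths$melt))
    list(n_peptide_rows = nrow(pep$table), n_plate_rows = nrow(plate$plate))
  })

  run_stage("lipsmap", function() {
    src <- if (!is.null(config$peptide_table)) config$peptide_table
           else paths$peptides
    if (!file.exists(src)) stop("no peptide table available; run synth first")
    tab <- utils::read.delim(src, stringsAsFactors = FALSE)
    tab <- filter_peptides(tab)
    res <- differential_abundance(tab)
    calls <- call_interactions(res, q_threshold = config$q_threshold)
    outputs <<- c(outputs,
                  write_tsv(res, file.path(od, "differential.tsv")),
                  write_tsv(calls, file.path(od, "interaction_calls.tsv")))
    list(n_peptides_tested = length(unique(paste(res$protein, res$peptide))),
         n_interacting = sum(calls$interacting))
  })

  run_stage("assay", function() {
    if (!file.exists(paths$plate)) stop("no plate data; run synth first")
    plate <- utils::read.delim(paths$plate, stringsAsFactors = FALSE)
    standards <- utils::read.delim(paths$standards, stringsAsFactors = FALSE)
    curve <- fit_standard_curve(standards)
    rates <- compute_rates(plate, curve)
    fits <- lapply(split(rates, rates$condition), fit_hill)
    fit_tab <- do.call(rbind, lapply(names(fits), function(cn)
      data.frame(condition = cn, Vmax = fits[[cn]]$Vmax,
                 K_half = fits[[cn]]$K_half, h = fits[[cn]]$h,
                 sse = fits[[cn]]$sse)))
    verdict <- if (all(c("plusM", "minusM") %in% names(fits))) {
      et <- effector_test(rates[rates$condition == "plusM", ],
                          rates[rates$condition == "minusM", ],
                          p_threshold = config$p_threshold,
                          effect_threshold = config$effect_threshold)
      data.frame(significant = et$significant,
                 max_rate_change = et$max_rate_change,
                 direction = et$direction)
    } else NULL
    outputs <<- c(outputs,
                  write_tsv(rates, file.path(od, "rates.tsv")),
                  write_tsv(fit_tab, file.path(od, "hill_fits.tsv")))
    if (!is.null(verdict)) {
      outputs <<- c(outputs,
                    write_tsv(verdict, file.path(od, "effector_verdict.tsv")))
    }
    list(n_rates = sum(is.finite(rates$rate_uM_min)))
  })

  run_stage("melt", function() {
    if (!file.exists(paths$melt)) stop("no melt curve; run synth first")
    curve <- utils::read.delim(paths$melt, stringsAsFactors = FALSE)
    mt <- melt_tm(curve, delta_threshold = config$delta_tm_threshold)
    outputs <<- c(outputs,
                  write_tsv(data.frame(tm = mt$tm, defined = mt$defined),
                            file.path(od, "melting.tsv")))
    list(tm = mt$tm)
  })

  run_stage("ensemble", function() {
    flux <- calvin_flux()
    cfg <- config$sampling
    conc <- sample_concentrations(build_calvin_model("base"), flux,
                                  cfg = cfg,
                                  seed = child_seed(config$seed, "conc"))
    ens <- lapply(c("base", "fsbpase"), function(vv)
      run_ensemble(build_calvin_model(vv), flux, cfg = cfg,
                   conc_sets = conc$states))
    names(ens) <- c("base", "fsbpase")
    cmp <- compare_variants(ens$base, ens$fsbpase)
    rec <- rbind(cbind(variant = "base", ens$base$records),
                 cbind(variant = "fsbpase", ens$fsbpase$records))
    fcc_long <- do.call(rbind, lapply(names(ens), function(vv) {
      m <- ens[[vv]]$summary$fcc_median
      md <- ens[[vv]]$summary$fcc_mad
      if (is.null(m)) return(NULL)
      data.frame(variant = vv, flux = rep(rownames(m), ncol(m)),
                 reaction = rep(colnames(m), each = nrow(m)),
                 median_fcc = as.vector(m), mad_fcc = as.vector(md),
                 n_stable = ens[[vv]]$summary$n_stable)
    }))
    outputs <<- c(outputs,
                  write_tsv(rec, file.path(od, "ensemble_records.tsv")),
                  write_tsv(fcc_long, file.path(od, "fcc_summary.tsv")))
    list(median_stable_base = ens$base$summary$median_stable_fraction,
         median_stable_fsbpase = ens$fsbpase$summary$median_stable_fraction,
         delta_median_stability = cmp$delta_median_stability)
  })

  invisible(finish())
}

#' Packaged steady-state flux distribution
#'
#' Reads the synthetic steady-state flux distribution packaged with the
#' Calvin-cycle model (mM/min, consistent with `N_internal v = 0`).
#'
#' @param path Optional path to a flux TSV (`reaction`, `v_mM_min`).
#' @return Named numeric vector of fluxes.
#' @export
calvin_flux <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "calvin_flux_synthetic.tsv",
                        package = "calvinreg", mustWork = TRUE)
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$v_mM_min, d$reaction)
}
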