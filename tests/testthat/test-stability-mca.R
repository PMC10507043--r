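test_that("reduced Jacobian matches closed forms on minimal systems", {
  # single species, mass-action sink dS/dt = -k S
  mf <- write_model_file(
    rbind(met_row("S"), met_row("XOUT", "external")),
    rxn_row("R1", "mass_action", "S -> XOUT"))
  m <- build_calvin_model("base", mf)
  p <- make_params(m, vmax = c(R1 = 3))  # k = 3
  jac <- jacobian_matrix(m, c(S = 1, m$external_conc), p,
                         check_steady = FALSE)
  expect_equal(unname(jac$J), matrix(-3, 1, 1))

  # two-species irreversible MM chain: entries match symbolic derivatives
  mf2 <- write_model_file(
    rbind(met_row("X0", "external"), met_row("S1"), met_row("S2"),
          met_row("XOUT", "external")),
    rbind(rxn_row("SUPPLY", "mass_action", "X0 -> S1"),
          rxn_row("R1", "irreversible_mm", "S1 -> S2"),
          rxn_row("R2", "irreversible_mm", "S2 -> XOUT")))
  m2 <- build_calvin_model("base", mf2)
  km <- c(R1.S1 = 0.8, R2.S2 = 1.7)
  p2 <- make_params(m2, km = km, vmax = c(SUPPLY = 1, R1 = 2, R2 = 3))
  st <- c(S1 = 0.5, S2 = 1.2, m2$external_conc)
  jac2 <- jacobian_matrix(m2, st, p2, check_steady = FALSE)
  d1 <- 2 * 0.8 / (0.8 + 0.5)^2   # dv1/dS1 = Vmax K/(K+S)^2
  d2 <- 3 * 1.7 / (1.7 + 1.2)^2
  expect_equal(jac2$J, matrix(c(-d1, d1, 0, -d2), 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)

  # conserved pair A <-> B reduces to a 1x1 Jacobian
  mf3 <- write_model_file(
    rbind(met_row("A"), met_row("B")),
    rxn_row("R", "reversible_mm", "A <-> B", dg0 = 0))
  m3 <- build_calvin_model("base", mf3)
  p3 <- make_params(m3, km = c(R.A = 1, R.B = 1))
  jac3 <- jacobian_matrix(m3, c(A = 2, B = 2), p3, check_steady = FALSE)
  expect_equal(dim(jac3$J), c(1L, 1L))
  expect_lt(jac3$J[1, 1], 0)
})

test_that("analytic and finite-difference derivatives agree on the Calvin model", {
  m <- build_calvin_model("fsbpase")
  flux <- calvin_flux()
  cfg <- sampling_config(n_conc_sets = 1, seed = 23)
  st <- sample_concentrations(m, flux, cfg = cfg)$states[[1]]
  p <- sample_parameters(m, st, cfg, seed = 24)
  p <- back_calculate_vmax(m, st, p, flux)
  Ea <- jacobian_matrix(m, st, p)$E
  Ef <- calvinreg:::fd_gradients(m, st, p)
  scale <- max(abs(Ea))
  expect_lt(max(abs(Ea - Ef)) / scale, 1e-4)
})

test_that("non-steady input is rejected by the Jacobian contract", {
  toy <- gen_toy_network(3, seed = 2)
  bad_state <- toy$state
  bad_state[toy$model$internal[1]] <- bad_state[toy$model$internal[1]] * 3
  expect_error(jacobian_matrix(toy$model, bad_state, toy$params),
               "not a steady state")
})

test_that("stability classification matches constructed spectra and dynamics", {
  expect_true(classify_stability(matrix(-1, 1, 1))$stable)
  expect_false(classify_stability(matrix(1, 1, 1))$stable)
  expect_error(classify_stability(matrix(NaN, 1, 1)), "non-finite")

  # random 4x4 with a known spectrum via similarity transform
  set.seed(7)
  for (i in 1:10) {
    lam <- -stats::runif(4, 0.1, 5)
    if (i %% 2 == 0) lam[1] <- +stats::runif(1, 0.1, 2)
    Q <- matrix(stats::rnorm(16), 4)
    J <- Q %*% diag(lam) %*% solve(Q)
    cls <- classify_stability(J)
    expect_identical(cls$stable, all(lam < 0))
    expect_equal(cls$max_re_eig, max(lam), tolerance = 1e-8)
    # linearized dynamics (matrix exponential via the known eigensystem)
    # decay exactly when classified stable
    x <- stats::rnorm(4)
    xt <- as.numeric(Q %*% diag(exp(lam * 10)) %*% solve(Q) %*% x)
    if (cls$stable) expect_lt(sum(xt^2), sum(x^2))
  }
})

test_that("scaled elasticities equal their closed forms", {
  # irreversible MM at S = K: eps = K/(K+S) = 1/2
  m <- single_mm_model()
  p <- make_params(m, km = c(R1.S = 2), vmax = c(SUPPLY = 1, R1 = 1))
  el <- elasticity_matrix(m, c(S = 2, m$external_conc), p)
  expect_equal(el$scaled["R1", "S"], 0.5, ignore_attr = TRUE)
  # mass action v = k S: unit elasticity at any S
  expect_equal(el$scaled["SUPPLY", "S"], 0, ignore_attr = TRUE)
  mf <- write_model_file(
    rbind(met_row("S"), met_row("XOUT", "external")),
    rxn_row("R1", "mass_action", "S -> XOUT"))
  mm <- build_calvin_model("base", mf)
  elm <- elasticity_matrix(mm, c(S = 3.7, mm$external_conc),
                           make_params(mm))
  expect_equal(elm$scaled["R1", "S"], 1, ignore_attr = TRUE)

  # Hill law with h = 1.5 at S = K: eps = h K^h/(K^h + S^h) = 0.75
  mfh <- write_model_file(
    rbind(met_row("S"), met_row("XOUT", "external")),
    rxn_row("R1", "irreversible_mm", "S -> XOUT", hill = "S"))
  mh <- build_calvin_model("base", mfh)
  ph <- make_params(mh, km = c(R1.S = 1.2), hill = c(R1 = 1.5))
  elh <- elasticity_matrix(mh, c(S = 1.2, mh$external_conc), ph)
  expect_equal(elh$scaled["R1", "S"], 0.75, ignore_attr = TRUE)
})

test_that("control coefficients obey the theorems and a zero-order supply", {
  # two-step pathway with zero-order supply: supply has all flux control
  toy1 <- gen_toy_network(1, seed = 4)
  cc1 <- control_coefficients(toy1$model, toy1$state, toy1$params)
  expect_equal(cc1$fcc["R1", "SUPPLY"], 1, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(cc1$fcc["R1", "R1"], 0, tolerance = 1e-10, ignore_attr = TRUE)

  # summation theorems on random branched toys
  for (s in 1:5) {
    toy <- gen_toy_network(4, "branched", seed = s)
    cc <- control_coefficients(toy$model, toy$state, toy$params)
    expect_lt(max(abs(rowSums(cc$fcc) - 1)), 1e-6)
    expect_lt(max(abs(rowSums(cc$ccc))), 1e-6)
    # connectivity theorem: C_J eps_scaled = 0 column-wise over species
    el <- elasticity_matrix(toy$model, toy$state, toy$params)
    conn <- cc$fcc %*% el$scaled
    expect_lt(max(abs(conn)), 1e-6)
  }
})

test_that("flux control matches the +1% Vmax perturbation oracle on 3-step toys", {
  for (s in c(1, 3)) {
    toy <- gen_toy_network(3, "branched", seed = s)
    cc <- control_coefficients(toy$model, toy$state, toy$params)
    oracle <- fcc_oracle(toy$model, toy$state, toy$params)
    big <- abs(oracle) > 0.05
    expect_gt(sum(big), 4)
    expect_lt(max(abs(cc$fcc[big] - oracle[big]) / abs(oracle[big])), 0.02)
    # near-zero coefficients agree absolutely
    expect_lt(max(abs(cc$fcc[!big] - oracle[!big])), 0.01)
  }
})

test_that("ensembles aggregate correctly and are reproducible", {
  toy <- gen_toy_network(2, seed = 6)
  cfg <- sampling_config(n_conc_sets = 4, n_param_sets_per_conc = 5,
                         seed = 2, assay_concs = c())
  ens <- run_ensemble(toy$model, toy$flux, cfg = cfg)
  expect_equal(nrow(ens$records), 20)
  expect_equal(ens$n_failed, 0)
  # a simple supply/chain toy is globally stable
  expect_equal(ens$summary$median_stable_fraction, 1)
  # summary equals an independent re-aggregation of the record dump
  frac <- tapply(ens$records$stable, ens$records$conc_set, mean)
  expect_equal(ens$summary$stable_fraction_per_conc, as.numeric(frac))
  expect_equal(ens$summary$fcc_median,
               apply(ens$fcc, c(2, 3), stats::median))
  ens2 <- run_ensemble(toy$model, toy$flux, cfg = cfg)
  expect_identical(ens$records, ens2$records)

  # median of stable fractions {0.8, 0.9, 1.0} is 0.9
  fake <- structure(list(records = data.frame(
    conc_set = rep(1:3, each = 10), param_set = rep(1:10, 3),
    stable = c(rep(c(TRUE, FALSE), c(8, 2)), rep(c(TRUE, FALSE), c(9, 1)),
               rep(TRUE, 10)),
    max_re_eig = -1, failed = FALSE), fcc = NULL),
    class = "ensemble_result")
  expect_equal(summarize_ensemble(fake)$median_stable_fraction, 0.9)
})

test_that("variant comparison is null for identical ensembles and signs match an oracle", {
  toy <- gen_toy_network(3, "branched", seed = 12)
  cfg <- sampling_config(n_conc_sets = 3, n_param_sets_per_conc = 5,
                         seed = 9, assay_concs = c())
  conc <- sample_concentrations(toy$model, toy$flux, cfg = cfg)
  ens <- run_ensemble(toy$model, toy$flux, cfg = cfg, conc_sets = conc$states)
  cmp0 <- compare_variants(ens, ens)
  expect_true(all(cmp0$delta_fcc == 0))
  expect_equal(cmp0$delta_median_stability, 0)

  # adding an activation to one enzyme: the analytic change in its
  # self-control matches the finite-difference oracle in sign; the branch
  # enzyme is activated by the downstream pool it competes with, so it can
  # influence its own effector
  mets <- rbind(met_row("X0", "external"), met_row("S1"), met_row("S2"),
                met_row("XBR", "external"), met_row("XOUT", "external"))
  rxns <- rbind(rxn_row("SUPPLY", "mass_action", "X0 -> S1"),
                rxn_row("R1", "irreversible_mm", "S1 -> S2"),
                rxn_row("BRANCH", "irreversible_mm", "S1 -> XBR"),
                rxn_row("R2", "irreversible_mm", "S2 -> XOUT"))
  regs <- data.frame(reaction = "BRANCH", kind = "km_activation",
                     effector = "S2", constant = 1, fmax = 0.75,
                     variant = "fsbpase")
  base <- build_calvin_model("base", write_model_file(mets, rxns, regs))
  reg <- build_calvin_model("fsbpase", write_model_file(mets, rxns, regs))
  st <- c(S1 = 1.5, S2 = 0.8, base$external_conc)
  flux <- c(SUPPLY = 1, R1 = 0.6, BRANCH = 0.4, R2 = 0.6)
  km <- c(R1.S1 = 1, BRANCH.S1 = 2, R2.S2 = 1)
  pb <- back_calculate_vmax(base, st, make_params(base, km = km), flux)
  pr0 <- make_params(reg, km = km, ka = c(BRANCH.S2 = 1))
  pr <- back_calculate_vmax(reg, st, pr0, flux)
  dfcc <- control_coefficients(reg, st, pr)$fcc["BRANCH", "BRANCH"] -
    control_coefficients(base, st, pb)$fcc["BRANCH", "BRANCH"]
  dora <- fcc_oracle(reg, st, pr)["BRANCH", "BRANCH"] -
    fcc_oracle(base, st, pb)["BRANCH", "BRANCH"]
  expect_gt(abs(dfcc), 1e-3)
  expect_identical(sign(dfcc), sign(dora))
  expect_equal(dfcc, dora, tolerance = 0.05)
})
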