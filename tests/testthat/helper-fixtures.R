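# Shared fixtures: tiny model-definition files written on the fly, an
# independent brute-force BH implementation, and an ODE relaxation oracle.

write_model_file <- function(mets, rxns, regs = NULL) {
  # mets: data frame id, role, lower, upper; rxns: data frame id, law, dg0,
  # hill, eq; regs: data frame reaction, kind, effector, constant, fmax,
  # variant
  path <- tempfile(fileext = ".txt")
  con <- file(path, "w")
  writeLines(c("[metabolites]", "id\tname\trole\tlower_mM\tupper_mM"), con)
  for (i in seq_len(nrow(mets))) {
    writeLines(paste(mets$id[i], mets$id[i], mets$role[i], mets$lower[i],
                     mets$upper[i], sep = "\t"), con)
  }
  writeLines(c("[reactions]",
               "id\trate_law\tdg0_kJ_mol\thill_substrate\tequation"), con)
  for (i in seq_len(nrow(rxns))) {
    writeLines(paste(rxns$id[i], rxns$law[i],
                     ifelse(is.na(rxns$dg0[i]), "NA", rxns$dg0[i]),
                     ifelse(is.na(rxns$hill[i]), "NA", rxns$hill[i]),
                     rxns$eq[i], sep = "\t"), con)
  }
  writeLines(c("[regulations]",
               "reaction\tkind\teffector\tconstant_mM\tmax_km_reduction\tvariant"),
             con)
  if (!is.null(regs)) {
    for (i in seq_len(nrow(regs))) {
      writeLines(paste(regs$reaction[i], regs$kind[i], regs$effector[i],
                       regs$constant[i],
                       ifelse(is.na(regs$fmax[i]), "NA", regs$fmax[i]),
                       regs$variant[i], sep = "\t"), con)
    }
  }
  close(con)
  path
}

met_row <- function(id, role = "internal", lower = 0.1, upper = 10) {
  data.frame(id = id, role = role, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

rxn_row <- function(id, law, eq, dg0 = NA, hill = NA) {
  data.frame(id = id, law = law, dg0 = dg0, hill = hill, eq = eq,
              stringsAsFactors = FALSE)
}

# one irreversible MM reaction S -> P with external supply; minimal model
single_mm_model <- function() {
  mf <- write_model_file(
    rbind(met_row("X0", "external"), met_row("S"), met_row("XOUT", "external")),
    rbind(rxn_row("SUPPLY", "mass_action", "X0 -> S"),
          rxn_row("R1", "irreversible_mm", "S -> XOUT")))
  build_calvin_model("base", model_file = mf)
}

make_params <- function(model, km = numeric(0), vmax = NULL, hill = NULL,
                        ki = numeric(0), ka = numeric(0)) {
  rxn <- names(model$reactions)
  if (is.null(vmax)) vmax <- stats::setNames(rep(1, length(rxn)), rxn)
  h <- stats::setNames(rep(1, length(rxn)), rxn)
  if (!is.null(hill)) h[names(hill)] <- hill
  structure(list(km = km, ki = ki, ka = ka, hill = h, vmax = vmax),
            class = "parameter_set")
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  # step-up monotonicity from the largest rank down
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# relax a model to steady state by ODE integration; returns final state
ode_relax <- function(model, state, params, t_end = 500, n = 60) {
  ids <- model$internal
  f <- function(t, y, parms) {
    st <- c(stats::setNames(pmax(y, 1e-12), ids), model$external_conc)
    list(as.numeric(model$N_internal %*% evaluate_rates(model, st, params)))
  }
  out <- deSolve::ode(state[ids], seq(0, t_end, length.out = n), f, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  stats::setNames(as.numeric(out[nrow(out), -1]), ids)
}

# does a 0.1%-perturbed trajectory return toward the steady state?
ode_returns <- function(model, state, params, t_end = 50) {
  ids <- model$internal
  y0 <- state[ids] * (1 + 0.001 * rep_len(c(1, -1), length(ids)))
  f <- function(t, y, parms) {
    st <- c(stats::setNames(pmax(y, 1e-12), ids), model$external_conc)
    list(as.numeric(model$N_internal %*% evaluate_rates(model, st, params)))
  }
  out <- tryCatch(deSolve::ode(y0, c(0, t_end / 2, t_end), f, NULL,
                               method = "lsoda", rtol = 1e-10, atol = 1e-12),
                  warning = function(w) NULL, error = function(e) NULL)
  if (is.null(out) || nrow(out) < 3) return(FALSE)  # integrator blew up
  yf <- out[nrow(out), -1]
  d0 <- max(abs(y0 - state[ids]) / state[ids])
  df <- max(abs(yf - state[ids]) / state[ids])
  is.finite(df) && df < d0
}

# finite-difference flux-control oracle: perturb one Vmax by +1%, relax to
# the new steady state by ODE integration, measure the flux response
fcc_oracle <- function(model, state, params, eps = 0.01, t_end = 2000) {
  v0 <- evaluate_rates(model, state, params)
  nr <- length(v0)
  C <- matrix(NA_real_, nr, nr, dimnames = list(names(v0), names(v0)))
  for (j in names(v0)) {
    pj <- params
    pj$vmax[j] <- pj$vmax[j] * (1 + eps)
    st_new <- ode_relax(model, state, pj, t_end = t_end)
    v_new <- evaluate_rates(model, c(st_new, model$external_conc), pj)
    C[, j] <- (log(abs(v_new)) - log(abs(v0))) / log(1 + eps)
  }
  C
}

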