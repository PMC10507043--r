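# Kinetic network data model: metabolites, reactions, rate laws, regulation
# terms, and the two Calvin-cycle model variants.

#' Thermodynamic configuration
#'
#' Constants used for Gibbs-energy computations (`dG = dG0' + RT ln Q`) and
#' for converting genome-scale fluxes (mmol gDW^-1 h^-1) into the kinetic
#' model's concentration units (mM/min).
#'
#' @param temperature Temperature in Kelvin. Defaults to 303.15 K (30 degrees
#'   C, the cultivation and assay temperature).
#' @param gas_constant Gas constant in kJ/(mol K).
#' @param cell_density Cell density in g dry weight per litre cell volume,
#'   used for flux unit conversion.
#' @return A list of class `thermo_config`.
#' @export
thermo_config <- function(temperature = 303.15, gas_constant = 8.314e-3,
                          cell_density = 434.78) {
  stopifnot(temperature > 0, gas_constant > 0, cell_density > 0)
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 cell_density = cell_density), class = "thermo_config")
}

#' Convert a flux from mmol/gDW/h to mM/min
#'
#' Multiplies by the cell density (g/L) and divides by 60 min/h. Signs are
#' preserved.
#'
#' @param v Numeric flux(es) in mmol gDW^-1 h^-1.
#' @param config A [thermo_config()].
#' @return Flux(es) in mM/min.
#' @export
convert_flux_units <- function(v, config = thermo_config()) {
  stopifnot(inherits(config, "thermo_config"))
  v * config$cell_density / 60
}

# metabolite ids excluded from rate laws and mass-action ratios (solvent and
# protons are folded into transformed Gibbs energies at pH 7)
KINETICS_IGNORE <- c("H2O", "H")

#' Regulation multiplier for an effector
#'
#' Two regulation kinds are supported. `noncompetitive_inhibition` returns the
#' rate multiplier `1 / (1 + c/Ki)`, in (0, 1]. `km_activation` returns the
#' factor by which the substrate Michaelis constant is scaled,
#' `1 - f_max * c / (c + Ka)`, in [1 - f_max, 1]; with the default ceiling
#' `f_max = 0.75` a saturating activator reduces K_M by at most 75%.
#'
#' @param kind `"noncompetitive_inhibition"` or `"km_activation"`.
#' @param effector_conc Effector concentration in mM (>= 0).
#' @param constant K_i or K_a in mM (> 0).
#' @param max_km_reduction Ceiling f_max in (0, 1]; `km_activation` only.
#' @return Dimensionless multiplier.
#' @export
regulation_factor <- function(kind, effector_conc, constant,
                              max_km_reduction = 0.75) {
  kind <- match.arg(kind, c("noncompetitive_inhibition", "km_activation"))
  if (any(effector_conc < 0)) stop("effector concentration must be >= 0")
  if (any(constant <= 0)) stop("regulation constant must be > 0")
  if (kind == "noncompetitive_inhibition") {
    1 / (1 + effector_conc / constant)
  } else {
    if (any(max_km_reduction <= 0) || any(max_km_reduction > 1)) {
      stop("max_km_reduction must be in (0, 1]")
    }
    1 - max_km_reduction * effector_conc / (effector_conc + constant)
  }
}

## ---- model definition file -------------------------------------------------

parse_equation <- function(eq, line_no) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else "->"
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    stop(sprintf("line %d: malformed reaction equation '%s'", line_no, eq))
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "" || side == "0") return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1) {
        coef <- 1; id <- parts[1]
      } else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1])); id <- parts[2]
        if (is.na(coef)) {
          stop(sprintf("line %d: bad coefficient in term '%s'", line_no, tm))
        }
      } else {
        stop(sprintf("line %d: bad term '%s'", line_no, tm))
      }
      out[id] <- (if (is.na(out[id])) 0 else out[id]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (id in names(rhs)) st[id] <- (if (id %in% names(st)) st[id] else 0) + rhs[id]
  st <- st[st != 0]
  if (length(st) == 0) {
    stop(sprintf("line %d: empty stoichiometry in '%s'", line_no, eq))
  }
  list(stoich = st, reversible = arrow == "<->")
}

parse_model_file <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  section <- NA_character_
  rows <- list(metabolites = list(), reactions = list(), regulations = list())
  headers <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(rows)) {
        stop(sprintf("line %d: unknown section '%s'", i, section))
      }
      next
    }
    if (is.na(section)) stop(sprintf("line %d: content before any section", i))
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (is.null(headers[[section]])) {
      headers[[section]] <- fields
      next
    }
    h <- headers[[section]]
    if (length(fields) != length(h)) {
      stop(sprintf("line %d: expected %d tab-separated fields, got %d",
                   i, length(h), length(fields)))
    }
    rec <- as.list(fields)
    names(rec) <- h
    rec$.line <- i
    rows[[section]] <- c(rows[[section]], list(rec))
  }
  rows
}

num_or_na <- function(x) {
  if (is.null(x) || x %in% c("NA", "", ".")) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("not a number: '", x, "'")
  v
}

#' Build a Calvin-cycle kinetic model variant
#'
#' Reads a structured model-definition file (sections `[metabolites]`,
#' `[reactions]`, `[regulations]`) and assembles a `kinetic_model`. The
#' packaged file is a synthetic reconstruction of a Synechocystis central
#' carbon metabolism network with 29 reactions connecting 36 metabolites (22
#' internal). Two variants are defined: `"base"` carries no regulation on the
#' F/SBPase reactions, `"fsbpase"` adds one K_M activation by GAP and one
#' noncompetitive inhibition by NADPH to each F/SBPase-catalysed reaction;
#' the variants share stoichiometry exactly.
#'
#' @param variant `"base"` or `"fsbpase"`.
#' @param model_file Path to a model-definition file; defaults to the
#'   packaged synthetic Calvin-cycle model.
#' @return An object of class `kinetic_model` with elements `variant`,
#'   `metabolites` (data frame with id, name, role, lower/upper ranges in mM),
#'   `reactions` (list), `N` (full stoichiometric matrix), `N_internal`,
#'   `internal` (ids), and `external_conc` (clamped concentrations, mM).
#' @export
build_calvin_model <- function(variant = c("base", "fsbpase"),
                               model_file = NULL) {
  variant <- match.arg(variant)
  if (is.null(model_file)) {
    model_file <- system.file("extdata", "calvin_model_synthetic.txt",
                              package = "calvinreg", mustWork = TRUE)
  }
  raw <- parse_model_file(model_file)

  mets <- do.call(rbind, lapply(raw$metabolites, function(r) {
    data.frame(id = r$id, name = r$name, role = r$role,
               lower = num_or_na(r$lower_mM), upper = num_or_na(r$upper_mM),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids in model file")
  if (!all(mets$role %in% c("internal", "external"))) {
    stop("metabolite role must be 'internal' or 'external'")
  }
  if (any(!(mets$lower > 0) | !(mets$lower < mets$upper))) {
    stop("metabolite ranges must satisfy 0 < lower < upper")
  }

  reactions <- lapply(raw$reactions, function(r) {
    pe <- parse_equation(r$equation, r$.line)
    law <- r$rate_law
    if (!law %in% c("reversible_mm", "irreversible_mm", "mass_action")) {
      stop(sprintf("line %d: unknown rate law '%s'", r$.line, law))
    }
    if (pe$reversible != (law == "reversible_mm")) {
      stop(sprintf("line %d: arrow does not match rate law for '%s'",
                   r$.line, r$id))
    }
    dg0 <- num_or_na(r$dg0_kJ_mol)
    if (law == "reversible_mm" && is.na(dg0)) {
      stop(sprintf("line %d: reversible reaction '%s' requires dg0",
                   r$.line, r$id))
    }
    unknown <- setdiff(names(pe$stoich), mets$id)
    if (length(unknown)) {
      stop(sprintf("line %d: unknown metabolite(s) %s in reaction '%s'",
                   r$.line, paste(unknown, collapse = ", "), r$id))
    }
    hs <- r$hill_substrate
    hs <- if (hs %in% c("NA", "", ".")) NA_character_ else hs
    if (!is.na(hs)) {
      if (!hs %in% names(pe$stoich) || pe$stoich[hs] >= 0) {
        stop(sprintf("line %d: hill substrate '%s' must be a substrate of '%s'",
                     r$.line, hs, r$id))
      }
    }
    list(id = r$id, stoich = pe$stoich, rate_law = law, delta_g0 = dg0,
         hill_substrate = hs, regulations = list())
  })
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids in model file")
  names(reactions) <- rids

  for (g in raw$regulations) {
    gv <- g$variant
    if (!gv %in% c("base", "fsbpase", "both")) {
      stop(sprintf("line %d: regulation variant must be base/fsbpase/both",
                   g$.line))
    }
    if (gv != "both" && gv != variant) next
    if (!g$reaction %in% rids) {
      stop(sprintf("line %d: regulation on unknown reaction '%s'",
                   g$.line, g$reaction))
    }
    if (!g$effector %in% mets$id) {
      stop(sprintf("line %d: unknown effector '%s'", g$.line, g$effector))
    }
    kind <- match.arg(g$kind, c("noncompetitive_inhibition", "km_activation"))
    const <- num_or_na(g$constant_mM)
    if (is.na(const) || const <= 0) {
      stop(sprintf("line %d: regulation constant must be positive", g$.line))
    }
    fmax <- num_or_na(g$max_km_reduction)
    if (kind == "km_activation" && (is.na(fmax) || fmax <= 0 || fmax > 1)) {
      stop(sprintf("line %d: km_activation needs max_km_reduction in (0,1]",
                   g$.line))
    }
    term <- list(kind = kind, effector = g$effector, constant = const,
                 max_km_reduction = if (kind == "km_activation") fmax else NA_real_)
    reactions[[g$reaction]]$regulations <-
      c(reactions[[g$reaction]]$regulations, list(term))
  }

  N <- matrix(0, nrow = nrow(mets), ncol = length(reactions),
              dimnames = list(mets$id, rids))
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoich
    N[names(st), j] <- st
  }
  internal <- mets$id[mets$role == "internal"]
  ext <- mets$id[mets$role == "external"]
  external_conc <- sqrt(mets$lower * mets$upper)[match(ext, mets$id)]
  names(external_conc) <- ext

  structure(list(variant = variant, metabolites = mets, reactions = reactions,
                 N = N, N_internal = N[internal, , drop = FALSE],
                 internal = internal, external_conc = external_conc,
                 kinetics_ignore = KINETICS_IGNORE),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("kinetic_model: variant '%s', %d reactions, %d metabolites (%d internal)\n",
              x$variant, length(x$reactions), nrow(x$metabolites),
              length(x$internal)))
  nreg <- sum(lengths(lapply(x$reactions, `[[`, "regulations")))
  cat(sprintf("  regulation terms: %d\n", nreg))
  invisible(x)
}

#' Reference concentration state of a model
#'
#' Geometric midpoint of each metabolite's concentration range; external
#' metabolites are clamped at this value in all sampled states.
#'
#' @param model A `kinetic_model`.
#' @return Named numeric vector of concentrations in mM.
#' @export
reference_state <- function(model) {
  m <- model$metabolites
  stats::setNames(sqrt(m$lower * m$upper), m$id)
}

## ---- parameter sets --------------------------------------------------------

km_key <- function(rxn, met) paste(rxn, met, sep = ".")

# species of a reaction that participate in the rate law
kinetic_species <- function(model, rxn) {
  st <- rxn$stoich
  st[!(names(st) %in% model$kinetics_ignore)]
}

need_km <- function(model, rxn) {
  st <- kinetic_species(model, rxn)
  switch(rxn$rate_law,
         mass_action = character(0),
         irreversible_mm = names(st)[st < 0],
         reversible_mm = names(st))
}

fetch_param <- function(vec, key, what, rxn_id) {
  if (is.null(vec) || !(key %in% names(vec))) {
    stop(sprintf("missing %s parameter '%s' for reaction '%s'",
                 what, key, rxn_id))
  }
  v <- vec[[key]]
  if (!is.finite(v)) {
    stop(sprintf("non-finite %s parameter '%s' for reaction '%s'",
                 what, key, rxn_id))
  }
  v
}

## ---- rate evaluation -------------------------------------------------------

# rate (and optionally its gradient wrt concentrations) for a single reaction
reaction_rate <- function(model, rxn, conc, params, thermo, grad = FALSE) {
  st <- kinetic_species(model, rxn)
  subs <- names(st)[st < 0]
  prods <- names(st)[st > 0]
  vmax <- fetch_param(params$vmax, rxn$id, "vmax", rxn$id)
  dlog <- numeric(0)   # d log(v) / d conc, named
  dabs <- numeric(0)   # absolute derivative additions (finite at v = 0)

  # regulation: inhibition multiplies rate; activation scales substrate Km
  inh_factor <- 1
  act_factor <- 1
  act_dfdc <- NULL  # list(effector=, deriv=) of d act_factor/dc
  inh_dlog <- numeric(0)
  for (term in rxn$regulations) {
    ce <- conc[[term$effector]]
    if (is.null(ce) || is.na(ce)) {
      stop(sprintf("state lacks effector '%s' of reaction '%s'",
                   term$effector, rxn$id))
    }
    # a sampled K_i/K_a in the parameter set overrides the file's default
    key <- paste(rxn$id, term$effector, sep = ".")
    const <- term$constant
    pool <- if (term$kind == "noncompetitive_inhibition") params$ki else params$ka
    if (!is.null(pool) && key %in% names(pool) && is.finite(pool[[key]])) {
      const <- pool[[key]]
    }
    if (term$kind == "noncompetitive_inhibition") {
      inh_factor <- inh_factor * regulation_factor("noncompetitive_inhibition",
                                                   ce, const)
      inh_dlog[term$effector] <- (if (term$effector %in% names(inh_dlog))
        inh_dlog[term$effector] else 0) - 1 / (const + ce)
    } else {
      f <- regulation_factor("km_activation", ce, const,
                             term$max_km_reduction)
      act_factor <- act_factor * f
      dd <- -term$max_km_reduction * const / (const + ce)^2
      act_dfdc <- c(act_dfdc, list(list(effector = term$effector,
                                        dlogf = dd / f)))
    }
  }

  add_dlog <- function(id, val) {
    cur <- if (id %in% names(dlog)) dlog[[id]] else 0
    dlog[[id]] <<- cur + val
  }

  if (rxn$rate_law == "mass_action") {
    v <- vmax
    for (s in subs) {
      cs <- conc[[s]]
      v <- v * cs^(-st[[s]])
      if (grad) add_dlog(s, -st[[s]] / cs)
    }
    v <- v * inh_factor
  } else if (rxn$rate_law == "irreversible_mm") {
    # activation scales the hill substrate's Km, or every substrate Km when
    # no primary substrate is declared
    v <- vmax * inh_factor
    for (s in subs) {
      cs <- conc[[s]]
      km <- fetch_param(params$km, km_key(rxn$id, s), "Km", rxn$id)
      is_primary <- !is.na(rxn$hill_substrate) && s == rxn$hill_substrate
      scale_km <- if (is.na(rxn$hill_substrate) || is_primary) act_factor else 1
      km_eff <- km * scale_km
      h <- if (is_primary) {
        hv <- params$hill[[rxn$id]]
        if (is.null(hv) || is.na(hv)) 1 else hv
      } else 1
      n <- -st[[s]]
      sat <- (cs^h / (km_eff^h + cs^h))^n
      v <- v * sat
      if (grad) {
        add_dlog(s, n * h * km_eff^h / (cs * (km_eff^h + cs^h)))
        if (scale_km != 1 || length(act_dfdc) > 0) {
          if (is.na(rxn$hill_substrate) || is_primary) {
            dlogsat_dkm <- -n * h * km_eff^(h - 1) / (km_eff^h + cs^h)
            for (ad in act_dfdc) {
              add_dlog(ad$effector, dlogsat_dkm * km_eff * ad$dlogf)
            }
          }
        }
      }
    }
  } else { # reversible_mm
    if (length(act_dfdc) > 0) {
      stop(sprintf("km_activation is not supported on reversible reaction '%s'",
                   rxn$id))
    }
    keq <- exp(-rxn$delta_g0 / (thermo$gas_constant * thermo$temperature))
    lnQ <- sum(st * log(unlist(conc[names(st)])))
    gamma <- exp(lnQ) / keq            # Q / Keq
    theta_s <- 1; Ds <- 1; Dp <- 1
    for (s in subs) {
      cs <- conc[[s]]
      km <- fetch_param(params$km, km_key(rxn$id, s), "Km", rxn$id)
      n <- -st[[s]]
      theta_s <- theta_s * (cs / km)^n
      Ds <- Ds * (1 + cs / km)^n
      if (grad) add_dlog(s, n / cs)    # theta_s part
    }
    for (p in prods) {
      cp <- conc[[p]]
      km <- fetch_param(params$km, km_key(rxn$id, p), "Km", rxn$id)
      Dp <- Dp * (1 + cp / km)^st[[p]]
    }
    D <- Ds + Dp - 1
    pre <- vmax * inh_factor * theta_s / D   # v = pre * (1 - gamma)
    v <- pre * (1 - gamma)
    if (grad) {
      # the thermodynamic factor (1 - Q/Keq) contributes an absolute term
      # that stays finite at equilibrium (v = 0, gradient nonzero)
      for (i in names(st)) {
        dabs[i] <- (if (i %in% names(dabs)) dabs[[i]] else 0) -
          pre * gamma * st[[i]] / conc[[i]]
      }
      for (s in subs) {
        km <- params$km[[km_key(rxn$id, s)]]
        add_dlog(s, -(Ds * (-st[[s]]) / (km + conc[[s]])) / D)
      }
      for (p in prods) {
        km <- params$km[[km_key(rxn$id, p)]]
        add_dlog(p, -(Dp * st[[p]] / (km + conc[[p]])) / D)
      }
    }
  }

  if (grad) {
    for (e in names(inh_dlog)) add_dlog(e, inh_dlog[[e]])
    ids <- union(names(dlog), names(dabs))
    dvdc <- stats::setNames(numeric(length(ids)), ids)
    if (length(dlog) && v != 0) dvdc[names(dlog)] <- unlist(dlog) * v
    if (length(dabs)) dvdc[names(dabs)] <- dvdc[names(dabs)] + unlist(dabs)
    list(v = v, dvdc = dvdc)
  } else {
    list(v = v)
  }
}

#' Evaluate reaction rates
#'
#' Computes the rate of every reaction of a model at a concentration state
#' under a parameter set. Irreversible reactions follow (multi-substrate)
#' Michaelis-Menten kinetics with an optional Hill exponent on the declared
#' primary substrate; reversible reactions follow a thermodynamically
#' consistent law `v = Vmax * theta_S * (1 - Q/Keq) / D` whose sign equals
#' the sign of the driving force and which vanishes at equilibrium
#' (`Q = Keq = exp(-dG0'/RT)`); supply reactions follow mass action.
#' Noncompetitive inhibition multiplies the rate by `1/(1 + c/Ki)`;
#' K_M activation scales the primary substrate's Michaelis constant by
#' `1 - f_max c/(c + Ka)`.
#'
#' @param model A `kinetic_model`.
#' @param state Named numeric vector of concentrations (mM) covering every
#'   species that appears in a rate law (internal and clamped external).
#' @param params Parameter set (see [sample_parameters()]), with `vmax` filled
#'   in (see [back_calculate_vmax()]).
#' @param thermo A [thermo_config()].
#' @return Named numeric vector of rates (mM/min), one per reaction.
#' @export
evaluate_rates <- function(model, state, params, thermo = thermo_config()) {
  conc <- as.list(state)
  needed <- setdiff(unique(unlist(lapply(model$reactions, function(r)
    c(names(kinetic_species(model, r)),
      vapply(r$regulations, `[[`, "", "effector"))))), names(conc))
  if (length(needed)) {
    stop("state lacks concentrations for: ", paste(needed, collapse = ", "))
  }
  bad <- names(conc)[!vapply(conc, function(x) is.finite(x) && x > 0, TRUE)]
  bad <- intersect(bad, setdiff(rownames(model$N), model$kinetics_ignore))
  if (length(bad)) stop("non-positive concentration(s): ",
                        paste(bad, collapse = ", "))
  vapply(model$reactions, function(r)
    reaction_rate(model, r, conc, params, thermo)$v, numeric(1))
}

# unscaled derivative matrix dv/dS over the given species (analytic)
rate_gradients <- function(model, state, params, thermo = thermo_config(),
                           species = model$internal) {
  conc <- as.list(state)
  E <- matrix(0, nrow = length(model$reactions), ncol = length(species),
              dimnames = list(names(model$reactions), species))
  v <- numeric(length(model$reactions))
  names(v) <- names(model$reactions)
  for (r in model$reactions) {
    rr <- reaction_rate(model, r, conc, params, thermo, grad = TRUE)
    v[r$id] <- rr$v
    common <- intersect(names(rr$dvdc), species)
    E[r$id, common] <- rr$dvdc[common]
  }
  list(v = v, E = E)
}

## ---- structural analysis ---------------------------------------------------

nullspace_left <- function(N, tol = 1e-10) {
  sv <- svd(N, nu = nrow(N))
  d <- c(sv$d, rep(0, nrow(N) - length(sv$d)))
  r <- sum(sv$d > tol * max(sv$d, 1))
  if (r == nrow(N)) {
    return(matrix(0, nrow = nrow(N), ncol = 0))
  }
  sv$u[, (r + 1):nrow(N), drop = FALSE]
}

#' Conserved moieties and the link matrix
#'
#' Finds a basis of the left null space of the internal stoichiometric matrix
#' (conservation relations such as ATP + ADP = const) and the link matrix `L`
#' mapping independent internal species to the full internal set
#' (`N_internal = L %*% N_R`). Removing conservations before linearization
#' prevents spurious zero Jacobian eigenvalues.
#'
#' @param model A `kinetic_model`, or a bare stoichiometric matrix.
#' @param tol Relative rank tolerance.
#' @return List with `basis` (matrix, one conservation per column),
#'   `independent` (row indices of independent species), `L` (link matrix),
#'   and `N_R` (rows of `N_internal` for the independent species).
#' @export
conserved_moieties <- function(model, tol = 1e-10) {
  N <- if (inherits(model, "kinetic_model")) model$N_internal else model
  basis <- nullspace_left(N, tol)
  qrN <- qr(t(N), tol = 1e-9)
  r <- qrN$rank
  ind <- sort(qrN$pivot[seq_len(r)])
  N_R <- N[ind, , drop = FALSE]
  # rows of N are linear combinations of rows of N_R: L = N t(N_R) (N_R t(N_R))^-1
  L <- t(solve(tcrossprod(N_R), N_R %*% t(N))) # (m x r)
  rownames(L) <- rownames(N)
  colnames(L) <- rownames(N)[ind]
  list(basis = basis, independent = ind, L = L, N_R = N_R)
}
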