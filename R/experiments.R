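#' @title Computational experiments
#' @description Drivers for the model's standard numerical experiments:
#'   temperature sweeps, metabolic-switch detection, warm-adaptation
#'   scenarios, parameter sensitivity scans and directional trait-response
#'   reports.
#' @name experiments
NULL

#' Sweep the model across temperature
#'
#' Solves the growth-maximization problem at every temperature on a regular
#' grid, in ascending order, optionally chaining each solution as a warm
#' start for the next point. Individual solver failures are recorded
#' per-row rather than aborting the sweep. Deterministic given the seed in
#' `opts`.
#'
#' @param params A `phyto_params`.
#' @param T_start,T_end,step Temperature grid in degrees Celsius
#'   (`step > 0`, `T_start <= T_end`).
#' @param mode Solve mode (see [solve_options()]).
#' @param opts Solver options; `opts$mode` is overridden by `mode`.
#' @param env_template Environment whose non-temperature fields (irradiance,
#'   nutrient saturation) are used at every grid point.
#' @param chain_warm_start Use each optimum as the warm start for the next
#'   temperature.
#' @return A `thermal_sweep` data.frame: one trait record per temperature.
#' @export
temperature_sweep <- function(params, T_start = 5, T_end = 45, step = 1,
                              mode = "free", opts = solve_options(),
                              env_template = phyto_env(),
                              chain_warm_start = TRUE, two_pass = TRUE) {
  if (step <= 0) stop("'step' must be positive", call. = FALSE)
  if (T_start > T_end) stop("need T_start <= T_end", call. = FALSE)
  temps <- seq(T_start, T_end, by = step)
  opts$mode <- mode
  env_at <- function(Tc)
    phyto_env(T_celsius = Tc, I = env_template$I,
              DIN = env_template$DIN, DIC = env_template$DIC,
              saturating_N = env_template$saturating_N,
              saturating_C = env_template$saturating_C)
  solve_at <- function(Tc, o) {
    tryCatch(solve_optimal_cell(params, env_at(Tc), o),
             error = function(e) {
               structure(list(status = "failed", state = NULL,
                              mu_per_day = 0, tie = FALSE,
                              active_respiratory_pathway = "none",
                              diagnostics = list(error = conditionMessage(e))),
                         class = "optimal_cell")
             })
  }
  # Each restricted configuration is swept as its own warm-started chain
  # (ascending, then a descending pass keeping the pointwise best); the free
  # mode is the pointwise best over the chains. Chaining within a pathway
  # keeps warm starts structurally compatible and irons out basin-hopping.
  chain_sweep <- function(submode) {
    o <- opts
    o$mode <- submode
    fits <- vector("list", length(temps))
    warm <- opts$warm_start
    for (i in seq_along(temps)) {        # ascending pass
      o$warm_start <- if (chain_warm_start) warm else opts$warm_start
      fits[[i]] <- solve_at(temps[i], o)
      if (chain_warm_start && fits[[i]]$status == "optimal")
        warm <- fits[[i]]$state
    }
    if (two_pass && chain_warm_start && length(temps) > 1) {
      # the descending pass only propagates known-good optima; random
      # restarts would duplicate the ascending pass, so trim them
      o$multistart_count <- min(o$multistart_count, 2L)
      warm <- NULL
      for (i in rev(seq_along(temps))) {
        if (!is.null(warm)) {
          o$warm_start <- warm
          refit <- solve_at(temps[i], o)
          if (refit$status == "optimal" &&
              (fits[[i]]$status != "optimal" ||
                 refit$mu_per_day > fits[[i]]$mu_per_day))
            fits[[i]] <- refit
        }
        if (fits[[i]]$status == "optimal") warm <- fits[[i]]$state
      }
    }
    fits
  }
  submodes <- if (mode == "free") {
    if (params$lipids_enabled)
      c("glycolysis_only", "lipid_only", "unrestricted")
    else "glycolysis_only"
  } else mode
  chains <- lapply(submodes, chain_sweep)
  combine <- function() {
    fits <- vector("list", length(temps))
    for (i in seq_along(temps)) {
      cand <- lapply(chains, `[[`, i)
      mus <- vapply(cand, function(r)
        if (r$status == "optimal") r$mu_per_day else -Inf, numeric(1))
      best <- cand[[if (all(!is.finite(mus))) 1L else which.max(mus)]]
      if (mode == "free") {
        best$mode <- "free"
        if (length(mus) >= 2 && all(is.finite(mus[1:2])) &&
            abs(mus[1] - mus[2]) < opts$mu_tolerance)
          best$tie <- TRUE
      }
      fits[[i]] <- best
    }
    fits
  }
  fits <- combine()
  if (mode == "free" && length(temps) > 2) {
    # a single grid point whose winning pathway differs from two agreeing
    # neighbors is almost always an under-converged solve of the neighbors'
    # pathway; re-solve that pathway warm-started from both neighbors
    pw <- vapply(fits, function(r) r$active_respiratory_pathway, character(1))
    sm_of <- c(glycolysis = "glycolysis_only",
               lipid_degradation = "lipid_only")
    for (i in 2:(length(temps) - 1)) {
      if (pw[i] == "none" || pw[i - 1] != pw[i + 1] || pw[i] == pw[i - 1])
        next
      target <- pw[i - 1]
      ci <- match(sm_of[[target]], submodes)
      if (is.na(ci)) next
      o <- opts
      o$mode <- sm_of[[target]]
      o$multistart_count <- 2L
      for (nb in c(i - 1L, i + 1L)) {
        if (fits[[nb]]$status != "optimal") next
        o$warm_start <- fits[[nb]]$state
        refit <- solve_at(temps[i], o)
        if (refit$status == "optimal" &&
            refit$mu_per_day > chains[[ci]][[i]]$mu_per_day)
          chains[[ci]][[i]] <- refit
      }
    }
    fits <- combine()
  }
  rows <- lapply(seq_along(temps), function(i)
    assemble_trait_record(fits[[i]], params, env_at(temps[i])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "seed") <- opts$random_seed
  attr(out, "label") <- "baseline"
  class(out) <- c("thermal_sweep", "data.frame")
  out
}

#' Detect metabolic switches along a sweep
#'
#' Scans the sweep (sorted by temperature) for consecutive viable rows whose
#' active dark respiratory pathway differs, returning one row per switch.
#'
#' @param sweep A `thermal_sweep` (or data.frame with `temperature` and
#'   `respiratory_mode` columns).
#' @return data.frame with `temperature` (of the row after the switch),
#'   `from_pathway`, `to_pathway`; zero rows when no switch occurs.
#' @export
detect_metabolic_switch <- function(sweep) {
  if (is.unsorted(sweep$temperature))
    stop("sweep must be sorted by temperature", call. = FALSE)
  viable <- sweep[sweep$respiratory_mode != "none", , drop = FALSE]
  if (nrow(viable) < 2)
    return(data.frame(temperature = numeric(0), from_pathway = character(0),
                      to_pathway = character(0), stringsAsFactors = FALSE))
  m <- viable$respiratory_mode
  idx <- which(m[-1] != m[-length(m)])
  data.frame(temperature = viable$temperature[idx + 1],
             from_pathway = m[idx], to_pathway = m[idx + 1],
             stringsAsFactors = FALSE)
}

#' Define an adaptation scenario
#'
#' A named bundle of parameter modifications representing evolved
#' (mutation-like) changes: scaling of activation energies (optionally per
#' reaction class), an override of the maximum stored-lipid content, a
#' global scaling of maximum turnover rates, overrides of the damage
#' kinetics, and arbitrary `set` assignments by parameter name.
#'
#' @param label Scenario label used in output tables.
#' @param E_a_multiplier Scalar, or named vector over pools, multiplying the
#'   activation energies (> 0).
#' @param c_tag_max Optional override of the maximum stored-lipid content.
#' @param k_ref_multiplier Scalar multiplying every maximum turnover (> 0).
#' @param E_d,T_d Optional overrides of the damage kinetics.
#' @param set Named list of direct parameter assignments.
#' @return An `adaptation_scenario` list.
#' @export
adaptation_scenario <- function(label, E_a_multiplier = 1, c_tag_max = NULL,
                                k_ref_multiplier = 1, E_d = NULL, T_d = NULL,
                                set = list()) {
  if (any(E_a_multiplier <= 0) || any(k_ref_multiplier <= 0))
    stop("multipliers must be positive", call. = FALSE)
  structure(list(label = label, E_a_multiplier = E_a_multiplier,
                 c_tag_max = c_tag_max, k_ref_multiplier = k_ref_multiplier,
                 E_d = E_d, T_d = T_d, set = set),
            class = "adaptation_scenario")
}

#' Apply an adaptation scenario to a parameter set
#'
#' Returns a modified copy; the base parameters are never mutated. Unknown
#' parameter names in `set` raise before any computation.
#'
#' @param params A `phyto_params`.
#' @param scenario An [adaptation_scenario()].
#' @return A new `phyto_params`.
#' @export
apply_scenario <- function(params, scenario) {
  p <- unclass(params)
  m <- scenario$E_a_multiplier
  if (!is.null(names(m))) {
    bad <- setdiff(names(m), POOLS)
    if (length(bad))
      stop("unknown pool(s) in E_a_multiplier: ",
           paste(bad, collapse = ", "), call. = FALSE)
    p$E_a[names(m)] <- p$E_a[names(m)] * m
  } else {
    p$E_a <- p$E_a * m
  }
  p$k_ref <- p$k_ref * scenario$k_ref_multiplier
  if (!is.null(scenario$c_tag_max)) p$c_tag_max <- scenario$c_tag_max
  if (!is.null(scenario$E_d)) p$E_d <- scenario$E_d
  if (!is.null(scenario$T_d)) p$T_d <- scenario$T_d
  if (length(scenario$set)) {
    unknown <- setdiff(names(scenario$set), names(p))
    if (length(unknown))
      stop("unknown parameter(s) in scenario: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (nm in names(scenario$set)) {
      v <- scenario$set[[nm]]
      if (nm %in% c("k_ref", "eta", "q", "E_a") && !is.null(names(v)))
        p[[nm]][names(v)] <- v
      else p[[nm]] <- v
    }
  }
  validate_params(p)
}

#' Run an adaptation scenario sweep
#'
#' Applies the scenario to a copy of the base parameters, runs the
#' temperature sweep, and labels the output.
#'
#' @param params Base `phyto_params` (never mutated).
#' @param scenario An [adaptation_scenario()].
#' @param ... Passed to [temperature_sweep()].
#' @return A labeled `thermal_sweep`.
#' @export
run_adaptation_scenario <- function(params, scenario, ...) {
  p <- apply_scenario(params, scenario)
  sweep <- temperature_sweep(p, ...)
  sweep$label <- scenario$label
  attr(sweep, "label") <- scenario$label
  sweep
}

#' Named adaptation presets
#'
#' Loads the preset parameter modifications shipped with the package
#' (`inst/extdata/adaptation_presets_synthetic.json`). The shipped values
#' are synthetic stand-ins constructed on the package's default parameter
#' set (moderate-warming: higher activation energies and lipid content;
#' severe-warming: additionally slowed turnover; a lipid-content-only
#' variant); they encode the direction of each evolved change, not any
#' published magnitudes.
#'
#' @param name Preset name; see `names(adaptation_presets())`.
#' @return An `adaptation_scenario` (or, with no arguments, the named list
#'   of all presets).
#' @export
adaptation_presets <- function(name = NULL) {
  path <- system.file("extdata", "adaptation_presets_synthetic.json",
                      package = "phytoalloc")
  if (path == "")
    stop("preset file not installed", call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  presets <- lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    adaptation_scenario(
      label = nm,
      E_a_multiplier = if (!is.null(x$E_a_multiplier)) x$E_a_multiplier else 1,
      c_tag_max = x$c_tag_max,
      k_ref_multiplier = if (!is.null(x$k_ref_multiplier))
        x$k_ref_multiplier else 1,
      E_d = x$E_d, T_d = x$T_d)
  })
  names(presets) <- names(raw)
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[name]]
}

#' Parameter sensitivity scan
#'
#' Runs one labeled sweep per candidate value of a single parameter.
#' Per-pool parameters are addressed as `"E_a.tr"` (pool-qualified names).
#'
#' @param params Base `phyto_params`.
#' @param parameter Parameter name (optionally pool-qualified).
#' @param values Vector (or list) of values to scan.
#' @param ... Passed to [temperature_sweep()].
#' @return A stacked `thermal_sweep` with a `label` column
#'   `parameter=value`.
#' @export
sensitivity_scan <- function(params, parameter, values, ...) {
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  base <- unclass(params)
  if (!parts[1] %in% names(base))
    stop("unknown parameter '", parts[1], "'", call. = FALSE)
  if (length(parts) == 2 && !parts[2] %in% POOLS)
    stop("unknown pool '", parts[2], "'", call. = FALSE)
  out <- lapply(values, function(v) {
    p <- unclass(params)
    if (length(parts) == 2) p[[parts[1]]][[parts[2]]] <- v
    else p[[parts[1]]] <- v
    sweep <- temperature_sweep(validate_params(p), ...)
    sweep$label <- paste0(parameter, "=", format(v))
    sweep
  })
  res <- do.call(rbind, out)
  class(res) <- c("thermal_sweep", "data.frame")
  res
}

#' Directional trait responses between two temperatures
#'
#' Sign of the change, from `T_low` to `T_high`, of the proteome
#' investments (photosystems, rubisco, transporters, repair, ribosomes,
#' glycolysis, lipid degradation), the ribosome concentration and the
#' stored-lipid pool. Used to compare the model's acclimation directions
#' with reported transcriptomic/proteomic shifts.
#'
#' @param sweep A `thermal_sweep` containing both temperatures as viable
#'   rows.
#' @param T_low,T_high The two temperatures (degrees Celsius).
#' @return data.frame with `variable`, `delta`, `sign` (-1, 0, 1).
#' @export
directional_response_report <- function(sweep, T_low, T_high) {
  pick <- function(Tc) {
    row <- sweep[sweep$temperature == Tc, , drop = FALSE]
    if (nrow(row) != 1 || row$status != "optimal")
      stop(sprintf("temperature %g C is not a viable sweep row", Tc),
           call. = FALSE)
    row
  }
  lo <- pick(T_low); hi <- pick(T_high)
  vars <- c(phi_p = "phi_p", phi_ru = "phi_ru", phi_tr = "phi_tr",
            phi_re = "phi_re", phi_ri = "phi_ri", phi_gl = "phi_gl",
            phi_ld = "phi_ld", ribosome_concentration = "p_ri",
            stored_lipids = "c_tag")
  delta <- vapply(vars, function(v) hi[[v]] - lo[[v]], numeric(1))
  data.frame(variable = names(vars), delta = unname(delta),
             sign = sign(unname(delta)), stringsAsFactors = FALSE)
}
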