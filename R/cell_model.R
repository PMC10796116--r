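#' @title Cell state, fluxes, balances and constraints
#' @description Every mass balance, energy constraint and space constraint of
#'   the allocation model as individually callable functions. A `cell_state`
#'   holds the decision variables of the optimization (pool concentrations,
#'   proteome fractions, lipid-flux splits, geometry, growth rate); a
#'   `phyto_fluxes` object holds the reaction and energy fluxes it implies.
#' @name cell_model
NULL

NONPS_POOLS <- c("ru", "tr", "ri", "re", "lb", "gl", "ld")

#' Construct a cell state
#'
#' @param p Named concentrations (molecules um^-3) of the non-photosystem
#'   protein pools `ru, tr, ri, re, lb, gl, ld`.
#' @param p_p,p_dp Functional and damaged photosystem concentrations.
#' @param c_ic,c_in Internal carbon and nitrogen pools.
#' @param c_lm Membrane lipids; `c_tag` stored (stress-mitigation) lipids.
#' @param c_tag Stored lipids (molecules um^-3).
#' @param c_gu,c_li Dark-respiration glucose and lipid stores.
#' @param phi Named proteome investment fractions over all 8 pools
#'   (`ru, tr, ri, p, re, lb, gl, ld`).
#' @param alpha Lipid-flux split `c(lm, tag, ld)`, summing to 1.
#' @param beta Volume-to-surface ratio (um).
#' @param mu Growth rate (min^-1).
#' @param eta_aan Nitrogen atoms per amino acid implied by `phi` (Eq. N:C
#'   demand); computed with [nitrogen_per_amino_acid()] if omitted.
#' @param params Parameter set used to derive `eta_aan` when omitted.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(p, p_p, p_dp, c_ic, c_in, c_lm, c_tag, c_gu, c_li,
                       phi, alpha, beta, mu, eta_aan = NULL, params = NULL) {
  p <- p[NONPS_POOLS]
  if (any(is.na(p))) stop("'p' must name every pool: ",
                          paste(NONPS_POOLS, collapse = ", "), call. = FALSE)
  phi <- phi[POOLS]
  if (any(is.na(phi))) stop("'phi' must name every pool: ",
                            paste(POOLS, collapse = ", "), call. = FALSE)
  if (length(alpha) != 3) stop("'alpha' must have 3 entries (lm, tag, ld)",
                               call. = FALSE)
  names(alpha) <- c("lm", "tag", "ld")
  if (beta <= 0) stop("'beta' must be positive", call. = FALSE)
  if (mu < 0) stop("'mu' must be non-negative", call. = FALSE)
  if (is.null(eta_aan)) {
    if (is.null(params))
      stop("supply 'eta_aan' or 'params' to derive it", call. = FALSE)
    eta_aan <- nitrogen_per_amino_acid(phi, params$q, params$eta_aac,
                                       params$phi_other, params$q_other)
  }
  structure(list(p = p, p_p = p_p, p_dp = p_dp, c_ic = c_ic, c_in = c_in,
                 c_lm = c_lm, c_tag = c_tag, c_gu = c_gu, c_li = c_li,
                 phi = phi, alpha = alpha, beta = beta, mu = mu,
                 eta_aan = eta_aan),
            class = "cell_state")
}

#' Nitrogen demand per amino acid
#'
#' The proteome-wide N:C demand is the investment-weighted mean N:C of the
#' protein pools; multiplying by the carbon content per amino acid gives the
#' nitrogen content per amino acid used by the nitrogen balance. The
#' unmodeled proteome fraction contributes with its own N:C ratio
#' (`q_other`), so the demand describes the whole synthesized proteome.
#'
#' @param phi Named investment fractions (any subset of pools).
#' @param q Named per-pool N:C ratios.
#' @param eta_aac Carbon atoms per amino acid.
#' @param phi_other Investment fraction of the unmodeled proteome (default 0).
#' @param q_other N:C ratio of the unmodeled proteome (default 0).
#' @return `eta_aan`, nitrogen atoms per amino acid.
#' @export
nitrogen_per_amino_acid <- function(phi, q, eta_aac, phi_other = 0,
                                    q_other = 0) {
  if (any(phi < 0)) stop("'phi' entries must be non-negative", call. = FALSE)
  q <- q[names(phi)]
  eta_aac * (sum(phi * q) + phi_other * q_other)
}

#' Quasi-steady-state damaged photosystem fraction
#'
#' Damage and repair of photosystems are fast relative to growth, so the
#' damaged fraction settles at the value where repair balances damage:
#' `k_d * p_p * (c_tag_max / c_tag) / (k_re * p_re)`. Stored lipids quench
#' reactive oxygen species, so a full lipid store (`c_tag = c_tag_max`)
#' yields the minimum damage rate. A value above 1 signals an infeasible
#' state (damage exceeding what the repair pool can balance); it is returned
#' as-is rather than raising.
#'
#' @param state A `cell_state` (uses `p_p`, `p$re`, `c_tag`).
#' @param params A `phyto_params`.
#' @param T Absolute temperature (K).
#' @return Damaged fraction (may exceed 1 for infeasible states).
#' @export
damaged_fraction_qss <- function(state, params, T) {
  k_d <- if (params$damage_enabled)
    damage_rate(params$k_ref_d, params$E_d, T, params$T_d) else 0
  if (k_d == 0) return(0)
  if (state$c_tag <= 0)
    stop("degenerate state: c_tag must be positive when damage is active",
         call. = FALSE)
  k_re <- rate_at_temperature(params$k_ref["re"], params$E_a[["re"]], T,
                              params$T_ref)[[1]]
  if (state$p["re"] <= 0)
    stop("p_re must be positive when damage is active", call. = FALSE)
  gamma_tag <- params$c_tag_max / state$c_tag
  unname(k_d * state$p_p * gamma_tag / (k_re * state$p["re"]))
}

#' Compute all fluxes implied by a cell state
#'
#' Michaelis-Menten kinetics on internal substrates, with the saturated
#' simplifications for carbon fixation and nitrogen uptake when the
#' environment flags external substrates as saturating, linear kinetics for
#' the respiratory pathways (their entire store is consumed every night),
#' photon capture at its temperature-independent rate, and the
#' damage/repair pair.
#'
#' @param state A `cell_state`.
#' @param params A `phyto_params`.
#' @param env A `phyto_env`.
#' @return An object of class `phyto_fluxes`: `v_ri` (aa um^-3 min^-1),
#'   `v_ru`, `v_lb`, `v_gl`, `v_ld` (C um^-3 min^-1), `v_tr` (N um^-3
#'   min^-1), `v_p` (photons um^-3 min^-1), `v_ep` (ATP um^-3 min^-1),
#'   `v_d`, `v_re` (photosystems um^-3 min^-1), `e_cost` (ATP um^-3 min^-1).
#' @export
compute_fluxes <- function(state, params, env) {
  rt <- rates_at(params, env$T)
  k <- rt$k
  f_c <- if (params$track_carbon) state$c_ic / (state$c_ic + params$K_ic) else 1
  f_n <- state$c_in / (state$c_in + params$K_in)
  f_lb <- if (params$track_carbon) state$c_ic / (state$c_ic + params$K_lb) else 1
  f_I <- env$I / (env$I + params$K_p)
  f_DIC <- if (env$saturating_C) 1 else env$DIC / (env$DIC + params$K_ru)
  f_DIN <- if (env$saturating_N) 1 else env$DIN / (env$DIN + params$K_tr)

  v_ri <- k[["ri"]] * state$p[["ri"]] * f_c * f_n
  v_ru <- k[["ru"]] * state$p[["ru"]] * f_DIC
  v_lb <- k[["lb"]] * state$p[["lb"]] * f_lb
  v_gl <- k[["gl"]] * state$p[["gl"]]
  v_ld <- k[["ld"]] * state$p[["ld"]]
  v_tr <- k[["tr"]] * state$p[["tr"]] * f_DIN
  v_p  <- k[["p"]] * state$p_p * f_I
  v_ep <- params$e_p * v_p

  k_d <- rt$k_d
  if (k_d > 0 && state$p_p > 0 && state$c_tag <= 0)
    stop("degenerate state: c_tag must be positive when damage is active",
         call. = FALSE)
  v_d <- if (k_d > 0 && state$p_p > 0)
    k_d * state$p_p * params$c_tag_max / state$c_tag else 0
  ps_tot <- state$p_p + state$p_dp
  v_re <- if (ps_tot > 0)
    k[["re"]] * state$p[["re"]] * state$p_dp / ps_tot else 0

  e_cost <- params$e_ri * v_ri + params$e_tr * v_tr + params$e_lb * v_lb +
    params$e_re * v_re

  structure(list(v_ri = v_ri, v_ru = v_ru, v_lb = v_lb, v_gl = v_gl,
                 v_ld = v_ld, v_tr = v_tr, v_p = v_p, v_ep = v_ep,
                 v_d = v_d, v_re = v_re, e_cost = e_cost),
            class = "phyto_fluxes")
}

#' Steady-state equality residuals
#'
#' Signed residual of every balance of the exponentially growing cell: each
#' protein pool (synthesis share minus growth dilution), the combined
#' functional-plus-damaged photosystem pool, internal carbon and nitrogen,
#' membrane and stored lipids, the lipid-split consistency
#' (`v_ld = alpha_ld * v_lb`), the dark storage requirements, the surface
#' identity, the damage-repair quasi-steady state, and the proteome N:C
#' demand. Residuals are informative for infeasible states too.
#'
#' @param state A `cell_state`.
#' @param fluxes The matching `phyto_fluxes` (from [compute_fluxes()]).
#' @param params A `phyto_params`.
#' @return Named numeric vector of signed residuals.
#' @export
steady_state_residuals <- function(state, fluxes, params) {
  mu <- state$mu
  res <- c(
    vapply(NONPS_POOLS, function(i)
      state$phi[[i]] * fluxes$v_ri / params$eta[[i]] - mu * state$p[[i]],
      numeric(1)),
    p_ps = state$phi[["p"]] * fluxes$v_ri / params$eta[["p"]] -
      mu * (state$p_p + state$p_dp),
    c_in = fluxes$v_tr - fluxes$v_ri * state$eta_aan - mu * state$c_in,
    c_lm = state$alpha[["lm"]] * fluxes$v_lb / params$eta_lic - mu * state$c_lm,
    c_tag = state$alpha[["tag"]] * fluxes$v_lb / params$eta_lic -
      mu * state$c_tag,
    lipid_split = fluxes$v_ld - state$alpha[["ld"]] * fluxes$v_lb,
    c_gu = fluxes$v_gl * params$t_d / params$n_guc - state$c_gu,
    c_li = fluxes$v_ld * params$t_d / params$eta_lic - state$c_li,
    surface = 1 - (state$p[["tr"]] * params$s_tr +
                     state$c_lm * params$s_lm) * state$beta,
    qss = fluxes$v_re - fluxes$v_d,
    n_demand = state$eta_aan - nitrogen_per_amino_acid(
      state$phi, params$q, params$eta_aac, params$phi_other, params$q_other)
  )
  names(res)[seq_along(NONPS_POOLS)] <- paste0("p_", NONPS_POOLS)
  if (params$track_carbon)
    res <- c(res, c_ic = fluxes$v_ru - fluxes$v_ri * params$eta_aac -
               fluxes$v_lb - fluxes$v_gl - mu * state$c_ic)
  res
}

#' Energy balance and slacks
#'
#' The cell's ATP books: `e_cost` is the cost-weighted sum of all
#' non-rubisco metabolic fluxes (protein synthesis, transport, lipid
#' synthesis, repair). Photochemistry must first pay carbon fixation
#' (`rubisco_slack = e_p v_p - e_ru v_ru >= 0`), the remainder must cover
#' `e_cost` during the day (`day_slack`), and the dark share `f_dr e_cost`
#' must be met by glycolysis plus lipid degradation (`dark_slack`).
#'
#' @param state A `cell_state` (unused fields tolerated; kept for symmetry).
#' @param fluxes A `phyto_fluxes`.
#' @param params A `phyto_params`.
#' @return List with `e_cost`, `rubisco_slack`, `day_slack`, `dark_slack`;
#'   all slacks must be non-negative at a feasible state.
#' @export
energy_balance <- function(state, fluxes, params) {
  e_cost <- params$e_ri * fluxes$v_ri + params$e_tr * fluxes$v_tr +
    params$e_lb * fluxes$v_lb + params$e_re * fluxes$v_re
  rubisco_slack <- params$e_p * fluxes$v_p - params$e_ru * fluxes$v_ru
  day_slack <- rubisco_slack - e_cost
  dark_slack <- params$e_gl * fluxes$v_gl + params$e_ld * fluxes$v_ld -
    params$f_dr * e_cost
  list(e_cost = e_cost, rubisco_slack = rubisco_slack,
       day_slack = day_slack, dark_slack = dark_slack)
}

#' Dark storage requirements
#'
#' Glucose and lipid stores needed to sustain the respiratory fluxes through
#' a dark period of `t_d` minutes; both scale linearly with the dark-period
#' length.
#'
#' @param v_gl,v_ld Daytime-committed respiratory fluxes (C um^-3 min^-1).
#' @param params A `phyto_params` (uses `t_d`, `n_guc`, `eta_lic`).
#' @return Named vector `c(c_gu, c_li)` in molecules um^-3.
#' @export
dark_storage_requirements <- function(v_gl, v_ld, params) {
  if (v_gl < 0 || v_ld < 0)
    stop("respiratory fluxes must be non-negative", call. = FALSE)
  c(c_gu = v_gl * params$t_d / params$n_guc,
    c_li = v_ld * params$t_d / params$eta_lic)
}

#' Space and density constraints
#'
#' Surface identity (`1 = (p_tr s_tr + c_lm s_lm) beta`), the fraction of
#' cell volume left after photosystems and lipid droplets, the
#' macromolecular density slack (`D_max * V/V_tot` minus the mass of the
#' density-counted pools), and the membrane transporter-to-lipid slack at
#' the environment's temperature.
#'
#' @param state A `cell_state`.
#' @param params A `phyto_params`.
#' @param env A `phyto_env` (for the temperature-dependent membrane bound).
#' @return List with `surface_residual`, `available_volume_fraction`,
#'   `density_slack`, `membrane_ratio_slack`.
#' @export
geometry_constraints <- function(state, params, env) {
  surface_residual <- 1 - (state$p[["tr"]] * params$s_tr +
                             state$c_lm * params$s_lm) * state$beta
  vf <- 1 - (state$p_p + state$p_dp) * params$V_p -
    (state$c_li + state$c_tag) * params$V_li
  dens <- density_load(state, params)
  density_slack <- params$D_max * vf - dens
  M_bound <- rates_at(params, env$T)$M_bound
  membrane_ratio_slack <- if (state$c_lm > 0) {
    M_bound - state$p[["tr"]] / state$c_lm
  } else if (state$p[["tr"]] > 0 && params$lipids_enabled) {
    -Inf  # transporters with no membrane lipid: infeasible
  } else {
    Inf   # membrane constraint not applicable (reduced configurations)
  }
  list(surface_residual = surface_residual,
       available_volume_fraction = vf,
       density_slack = density_slack,
       membrane_ratio_slack = membrane_ratio_slack)
}

#' Macromolecular density load (Da um^-3)
#'
#' Mass per biovolume of the pools that crowd the aqueous interior: the
#' density-counted protein pools (all except photosystems and membrane
#' lipids, configurable via `density_pools`) plus internal carbon, internal
#' nitrogen and the glucose store, each with its effective molecular weight.
#' Lipid droplets and photosystems are excluded; they act through the
#' available-volume term instead.
#'
#' @param state A `cell_state`.
#' @param params A `phyto_params`.
#' @return Scalar mass density (Da um^-3).
#' @export
density_load <- function(state, params) {
  pools <- intersect(params$density_pools, NONPS_POOLS)
  sum(state$p[pools] * params$eta[pools] * params$eta_aa) +
    state$c_ic * params$w_ic + state$c_in * params$w_in +
    state$c_gu * params$w_gu
}

#' Full residual report for a cell state
#'
#' Assembles every equality residual and inequality slack, a
#' relative-scaled maximum equality residual, and a feasibility verdict.
#'
#' @param state A `cell_state`.
#' @param params A `phyto_params`.
#' @param env A `phyto_env`.
#' @param tol Feasibility tolerance on the relative residuals and slacks.
#' @return An object of class `residual_report`: `equalities` (signed),
#'   `equalities_rel` (scaled), `slacks`, `max_abs_residual` (relative),
#'   `feasible`.
#' @export
residual_report <- function(state, params, env, tol = 1e-8) {
  fl <- compute_fluxes(state, params, env)
  eq <- steady_state_residuals(state, fl, params)
  scales <- residual_scales(state, fl, params)
  eq_rel <- eq / scales[names(eq)]
  en <- energy_balance(state, fl, params)
  geo <- geometry_constraints(state, params, env)
  e_scale <- max(abs(en$rubisco_slack) + en$e_cost,
                 params$e_p * fl$v_p, 1e-300)
  slacks <- c(
    rubisco = en$rubisco_slack / e_scale,
    day = en$day_slack / e_scale,
    dark = en$dark_slack / max(params$f_dr * en$e_cost, e_scale * 1e-3),
    c_tag_upper = (params$c_tag_min + params$c_tag_max - state$c_tag) /
      params$c_tag_max,
    membrane = geo$membrane_ratio_slack /
      max(rates_at(params, env$T)$M_bound, 1e-300),
    volume_fraction = geo$available_volume_fraction,
    density = geo$density_slack / params$D_max,
    alpha_nonneg = min(state$alpha)
  )
  # surface equality is reported among equalities; drop it from slacks
  max_abs <- max(abs(eq_rel))
  structure(list(equalities = eq, equalities_rel = eq_rel, slacks = slacks,
                 max_abs_residual = max_abs,
                 feasible = max_abs <= tol && all(slacks >= -tol)),
            class = "residual_report")
}

# Characteristic magnitude of each balance, for relative scaling.
residual_scales <- function(state, fl, params) {
  mu <- state$mu
  s <- c(
    vapply(NONPS_POOLS, function(i)
      max(abs(state$phi[[i]] * fl$v_ri / params$eta[[i]]),
          abs(mu * state$p[[i]]), 1e-300), numeric(1)),
    p_ps = max(abs(state$phi[["p"]] * fl$v_ri / params$eta[["p"]]),
               abs(mu * (state$p_p + state$p_dp)), 1e-300),
    c_in = max(fl$v_tr, fl$v_ri * state$eta_aan, mu * state$c_in, 1e-300),
    c_lm = max(abs(state$alpha[["lm"]] * fl$v_lb / params$eta_lic),
               mu * state$c_lm, 1e-300),
    c_tag = max(abs(state$alpha[["tag"]] * fl$v_lb / params$eta_lic),
                mu * state$c_tag, 1e-300),
    lipid_split = max(fl$v_ld, abs(state$alpha[["ld"]] * fl$v_lb), 1e-300),
    c_gu = max(fl$v_gl * params$t_d / params$n_guc, state$c_gu, 1e-300),
    c_li = max(fl$v_ld * params$t_d / params$eta_lic, state$c_li, 1e-300),
    surface = 1,
    qss = max(fl$v_re, fl$v_d, 1e-300),
    n_demand = max(abs(state$eta_aan), 1e-300)
  )
  names(s)[seq_along(NONPS_POOLS)] <- paste0("p_", NONPS_POOLS)
  if (params$track_carbon)
    s <- c(s, c_ic = max(fl$v_ru, fl$v_ri * params$eta_aac + fl$v_lb +
                           fl$v_gl + state$mu * state$c_ic, 1e-300))
  s
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("Residual report: max |equality| (relative) = %.3g; %s\n",
              x$max_abs_residual,
              if (x$feasible) "feasible" else "NOT feasible"))
  worst <- sort(abs(x$equalities_rel), decreasing = TRUE)[1:3]
  cat("  worst equalities:",
      paste(sprintf("%s=%.2g", names(worst), worst), collapse = ", "), "\n")
  neg <- x$slacks[x$slacks < 0]
  if (length(neg))
    cat("  negative slacks:",
        paste(sprintf("%s=%.2g", names(neg), neg), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("Cell state: mu = %.4g min^-1 (%.3f day^-1), beta = %.3g um\n",
              x$mu, x$mu * 1440, x$beta))
  cat("  phi:", paste(sprintf("%s=%.3f", names(x$phi), x$phi),
                      collapse = " "), "\n")
  cat(sprintf("  alpha: lm=%.3f tag=%.3f ld=%.3f\n",
              x$alpha[["lm"]], x$alpha[["tag"]], x$alpha[["ld"]]))
  invisible(x)
}
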