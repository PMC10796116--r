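#' @title Model parameters and environment
#' @name parameters
NULL

POOLS <- c("ru", "tr", "ri", "p", "re", "lb", "gl", "ld")

POOL_LABELS <- c(
  ru = "rubisco", tr = "N transporter", ri = "ribosome", p = "photosystem",
  re = "repair protein", lb = "lipid synthesis", gl = "glycolysis",
  ld = "lipid degradation")

# Default parameter values. Every constant fixed by the model description is
# encoded here (phi_other, f_dr, t_d, the chlorophyll conversion constants,
# halved transporter activation energy, Boltzmann's constant); the remaining
# turnover rates, molecular sizes, energy stoichiometries and geometry are
# literature-scale defaults for a generic diatom-like cell (see the methods
# vignette for each choice and its rationale).
.default_params <- function() {
  list(
    # per-pool maximum turnover at T_ref (min^-1 per catalyst molecule):
    # ru: C fixed per rubisco; tr: N imported per transporter; ri: amino acids
    # polymerized per ribosome; p: photons absorbed per photosystem (T-indep);
    # re: photosystems repaired per protease; lb/gl/ld: C processed per enzyme
    k_ref = c(ru = 1500, tr = 40, ri = 33, p = 18000,
              re = 5, lb = 100, gl = 400, ld = 400),
    # protein size (amino acids per protein complex)
    eta = c(ru = 4800, tr = 500, ri = 7459, p = 20000,
            re = 1000, lb = 2500, gl = 3000, ld = 3000),
    # N:C ratio of each protein pool (ribosomes are N-rich ribonucleoproteins,
    # photosystems carry pigments and lipids and are N-poor)
    q = c(ru = 0.31, tr = 0.31, ri = 0.38, p = 0.28,
          re = 0.31, lb = 0.31, gl = 0.31, ld = 0.31),
    # activation energy (eV) per pool; transporters have half the generic
    # value, photon capture is temperature independent (flag below)
    E_a = c(ru = 0.85, tr = 0.425, ri = 0.85, p = 0, re = 0.85,
            lb = 0.85, gl = 0.85, ld = 0.85),
    temperature_independent = "p",
    T_ref = 293.15,                   # K (20 C)

    # photosystem heat damage
    k_ref_d = 0.4,                    # min^-1 at T_d
    E_d = 2.5,                        # eV
    T_d = 304.15,                     # K (31 C)

    # half-saturation constants
    K_ic = 6e6,                       # internal C, molecules um^-3 (~10 mM)
    K_in = 3e5,                       # internal N, molecules um^-3 (~0.5 mM)
    K_lb = 6e6,                       # lipid synthesis on internal C
    K_ru = 10,                        # DIC (external units), unused if saturating
    K_tr = 1,                         # DIN (external units), unused if saturating
    K_p  = 50,                        # irradiance half-saturation (same units as I)

    # stoichiometry
    eta_aac = 5,                      # C atoms per amino acid
    eta_aa  = 110,                    # Da per amino acid
    eta_lic = 50,                     # C atoms per stored lipid (TAG)
    n_guc   = 6,                      # C atoms per glucose
    q_other = NULL,                   # N:C of the unmodeled proteome (NULL = mean q)

    # energy stoichiometry (ATP-equivalents)
    e_p  = 1,                         # per photon absorbed
    e_ru = 8,                         # per C fixed (Calvin cycle ATP + NADPH)
    e_ri = 4.5,                       # per amino acid polymerized
    e_tr = 0.5,                       # per N imported
    e_lb = 5.5,                       # per C of lipid synthesized
    e_re = 1000,                      # per photosystem repaired
    e_gl = 5,                         # recovered per C respired via glycolysis
    e_ld = 7,                         # recovered per C respired via lipid degradation
    f_dr = 0.25,                      # fraction of e_cost paid in the dark
    t_d  = 720,                       # dark period (min; 12 h)

    # geometry and density
    s_tr = 1e-4,                      # um^2 per transporter complex
    s_lm = 4e-7,                      # um^2 per membrane lipid
    V_p  = 2.4e-6,                    # um^3 per photosystem
    V_li = 1.6e-8,                    # um^3 per stored lipid (droplet incl. packing)
    D_max = 1.2e10,                   # Da um^-3 max macromolecular density
    w_ic = 30,                        # Da per internal-C molecule (CH2O)
    w_in = 17,                        # Da per internal-N molecule
    w_gu = 180,                       # Da per glucose
    density_pools = c("ru", "ri", "re", "lb", "gl", "ld"),

    # stored lipid bounds
    c_tag_min = 3e4,                  # molecules um^-3
    c_tag_max = 3e7,                  # molecules um^-3

    # membrane transporter-to-lipid bound
    M_min = 0.002,
    M_max = 0.035,
    T_min = 278.15,                   # K (5 C)
    T_max = 318.15,                   # K (45 C)
    membrane_saturation = TRUE,       # FALSE: bound fixed at M_max (no T effect)
    membrane_clamp = FALSE,

    # proteome
    phi_other = 0.5,

    # trait conversion constants
    chl_per_ps = 140,                 # chlorophyll molecules per photosystem
    chl_mw = 893.5,                   # g per mol chlorophyll
    chl_include_damaged = TRUE,

    # structural switches (toy/reduced configurations)
    lipids_enabled = TRUE,
    damage_enabled = TRUE,
    track_carbon = TRUE
  )
}

#' Construct a model parameter set
#'
#' Returns the full set of constants of the allocation model: per-pool
#' turnover rates, protein sizes and N:C ratios, activation energies, damage
#' kinetics, half-saturations, energy stoichiometry, geometry and density
#' limits, stored-lipid and membrane bounds, and trait conversion constants.
#' Any field can be overridden by name; per-pool vectors may be overridden
#' partially (e.g. `k_ref = c(ri = 200)`).
#'
#' @param ... Named overrides of default fields.
#' @return An object of class `phyto_params` (a validated named list).
#' @examples
#' p <- phyto_params()
#' p$f_dr
#' phyto_params(k_ref = c(ri = 200))$k_ref[["ri"]]
#' @export
phyto_params <- function(...) {
  p <- .default_params()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (nm in names(dots)) {
      if (nm %in% c("k_ref", "eta", "q", "E_a") && !is.null(names(dots[[nm]]))) {
        bad <- setdiff(names(dots[[nm]]), POOLS)
        if (length(bad))
          stop("unknown pool(s) in '", nm, "': ", paste(bad, collapse = ", "),
               call. = FALSE)
        p[[nm]][names(dots[[nm]])] <- dots[[nm]]
      } else {
        p[[nm]] <- dots[[nm]]
      }
    }
  }
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks completeness, pool naming, positivity and range constraints of all
#' model constants, fills the derived default for `q_other`, and stamps the
#' `phyto_params` class.
#'
#' @param p A named list of parameter values.
#' @return The validated `phyto_params` object.
#' @export
validate_params <- function(p) {
  required <- names(.default_params())
  missing <- setdiff(required, names(p))
  if (length(missing))
    stop("missing required parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in c("k_ref", "eta", "q", "E_a")) {
    v <- p[[nm]]
    if (!is.numeric(v) || !all(POOLS %in% names(v)))
      stop(sprintf("'%s' must be a numeric vector naming every pool (%s)",
                   nm, paste(POOLS, collapse = ", ")), call. = FALSE)
    p[[nm]] <- v[POOLS]
    if (any(!is.finite(p[[nm]])) || any(p[[nm]] < 0))
      stop(sprintf("'%s' entries must be finite and non-negative: check %s",
                   nm, paste0(nm, ".", POOLS[!is.finite(v[POOLS]) | v[POOLS] < 0],
                              collapse = ", ")), call. = FALSE)
  }
  scalar_pos <- c("T_ref", "T_d", "K_ic", "K_in", "K_lb", "K_ru", "K_tr", "K_p",
                  "eta_aac", "eta_aa", "eta_lic", "n_guc", "t_d",
                  "s_tr", "s_lm", "V_p", "V_li", "D_max",
                  "w_ic", "w_in", "w_gu", "c_tag_min", "c_tag_max",
                  "chl_per_ps", "chl_mw")
  for (nm in scalar_pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  scalar_nonneg <- c("k_ref_d", "E_d", "e_p", "e_ru", "e_ri", "e_tr",
                     "e_lb", "e_re", "e_gl", "e_ld")
  for (nm in scalar_nonneg)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm),
           call. = FALSE)
  if (p$f_dr < 0 || p$f_dr >= 1) stop("'f_dr' must lie in [0, 1)", call. = FALSE)
  if (p$phi_other < 0 || p$phi_other >= 1)
    stop("'phi_other' must lie in [0, 1)", call. = FALSE)
  if (p$M_min < 0 || p$M_max < p$M_min)
    stop("need 0 <= M_min <= M_max", call. = FALSE)
  if (p$T_min >= p$T_max) stop("need T_min < T_max", call. = FALSE)
  if (is.null(p$q_other)) p$q_other <- mean(p$q)
  if (!all(p$density_pools %in% POOLS))
    stop("'density_pools' must be a subset of the pool names", call. = FALSE)
  structure(p, class = "phyto_params")
}

#' Construct an environment (external forcing)
#'
#' @param T_celsius Temperature in degrees Celsius (stored internally in K).
#' @param I Irradiance, in the same units as the photosystem half-saturation
#'   `K_p`; `I = 0` leaves the cell without an energy source.
#' @param DIN,DIC External dissolved inorganic nitrogen / carbon
#'   concentrations; ignored when the corresponding saturating flag is set.
#' @param saturating_N,saturating_C If `TRUE` (the default) uptake and carbon
#'   fixation run at their temperature-corrected maxima, i.e. the external
#'   substrate is far above its half-saturation.
#' @return An object of class `phyto_env`.
#' @export
phyto_env <- function(T_celsius = 20, I = 200, DIN = Inf, DIC = Inf,
                      saturating_N = TRUE, saturating_C = TRUE) {
  T <- celsius_to_kelvin(T_celsius)
  .check_temperature(T)
  if (!is.numeric(I) || I < 0) stop("'I' must be non-negative", call. = FALSE)
  structure(list(T = T, T_celsius = T_celsius, I = I, DIN = DIN, DIC = DIC,
                 saturating_N = isTRUE(saturating_N),
                 saturating_C = isTRUE(saturating_C)),
            class = "phyto_env")
}

# Temperature-corrected turnover rates for every pool plus the damage rate.
# Computed once per (params, T); the optimizer's inner loop reuses the result.
#' Temperature-corrected rates for all pools
#'
#' Applies Arrhenius scaling to every pool's reference turnover (photon
#' capture exempt) and evaluates the damage rate and membrane bound at `T`.
#'
#' @param params A `phyto_params` object.
#' @param T Absolute temperature (K).
#' @return List with `k` (named rate vector, min^-1), `k_d` (damage rate),
#'   and `M_bound` (membrane transporter-to-lipid bound).
#' @export
rates_at <- function(params, T) {
  gamma <- arrhenius_factor(params$E_a, T, params$T_ref)
  gamma[params$temperature_independent] <- 1
  k <- params$k_ref * gamma
  k_d <- if (params$damage_enabled)
    damage_rate(params$k_ref_d, params$E_d, T, params$T_d) else 0
  M_bound <- if (params$membrane_saturation)
    membrane_ratio_bound(T, params$M_min, params$M_max, params$T_min,
                         params$T_max, clamp = params$membrane_clamp)
  else params$M_max
  list(k = k, k_d = k_d, M_bound = M_bound)
}

#' @export
print.phyto_params <- function(x, ...) {
  cat("Phytoplankton proteome-allocation model parameters\n")
  cat(sprintf("  pools: %s\n", paste(POOLS, collapse = ", ")))
  cat(sprintf("  T_ref = %.2f K; E_a (generic) = %.2f eV; transporter E_a = %.2f eV\n",
              x$T_ref, x$E_a[["ri"]], x$E_a[["tr"]]))
  cat(sprintf("  damage: k_ref_d = %.3g min^-1 at T_d = %.2f K, E_d = %.2f eV\n",
              x$k_ref_d, x$T_d, x$E_d))
  cat(sprintf("  phi_other = %.2f; f_dr = %.2f; t_d = %g min\n",
              x$phi_other, x$f_dr, x$t_d))
  cat(sprintf("  lipids %s, damage %s, carbon tracking %s\n",
              if (x$lipids_enabled) "on" else "off",
              if (x$damage_enabled) "on" else "off",
              if (x$track_carbon) "on" else "off"))
  invisible(x)
}

#' @export
print.phyto_env <- function(x, ...) {
  cat(sprintf("Environment: T = %.2f C (%.2f K), I = %g, DIN %s, DIC %s\n",
              x$T_celsius, x$T, x$I,
              if (x$saturating_N) "saturating" else format(x$DIN),
              if (x$saturating_C) "saturating" else format(x$DIC)))
  invisible(x)
}

#' Reduced three-pool parameter set
#'
#' A stripped configuration with only photosystems, ribosomes and
#' transporters active: lipid metabolism, photosystem damage, dark
#' respiration and carbon tracking are all disabled. The growth-maximization
#' problem then has a low-dimensional decision space (two free proteome
#' fractions, the internal-N saturation and cell geometry), small enough for
#' an exhaustive grid search, which serves as an independent check on the
#' nonlinear solver.
#'
#' @param ... Overrides forwarded to [phyto_params()].
#' @return A `phyto_params` object.
#' @export
toy_params <- function(...) {
  phyto_params(
    lipids_enabled = FALSE,
    damage_enabled = FALSE,
    track_carbon = FALSE,
    f_dr = 0,
    ...
  )
}
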