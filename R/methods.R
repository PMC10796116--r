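#' @title Methods for fitted objects
#' @name methods
NULL

#' @export
print.optimal_cell <- function(x, ...) {
  cat(sprintf("Optimal cell (%s mode): status %s\n", x$mode, x$status))
  if (x$status == "optimal") {
    cat(sprintf("  growth rate: %.4f day^-1; respiratory pathway: %s%s\n",
                x$mu_per_day, x$active_respiratory_pathway,
                if (isTRUE(x$tie)) " (pathway tie)" else ""))
    cat(sprintf("  radius %.3f um; damaged photosystem fraction %.3f\n",
                3 * x$state$beta,
                x$state$p_dp / max(x$state$p_p + x$state$p_dp, 1e-300)))
  }
  invisible(x)
}

#' @export
summary.optimal_cell <- function(object, ...) {
  x <- object
  cat(sprintf("Growth-optimal cell at %.1f C (%s mode)\n",
              x$env$T_celsius, x$mode))
  cat(sprintf("  status: %s\n", x$status))
  if (x$status != "optimal") return(invisible(x))
  rec <- assemble_trait_record(x, x$params, x$env)
  cat(sprintf("  mu: %.4f day^-1   CUE: %.3f   q_cell: %.3f\n",
              rec$mu_per_day, rec$CUE, rec$q_cell))
  cat(sprintf("  C fixation: %.3g fmol C um^-3 day^-1   chl: %.3g g um^-3\n",
              rec$carbon_fixation, rec$chlorophyll_density))
  cat(sprintf("  radius: %.3f um   volume: %.3f um^3   pathway: %s\n",
              rec$radius, rec$volume, rec$respiratory_mode))
  cat("  proteome investments:\n")
  phi <- x$state$phi
  for (pool in POOLS)
    cat(sprintf("    %-18s phi = %.4f\n", POOL_LABELS[[pool]], phi[[pool]]))
  cat(sprintf("  feasibility: max |equality| = %.2g, min slack = %.2g\n",
              x$residual_report$max_abs_residual,
              min(x$residual_report$slacks)))
  invisible(x)
}

#' @export
coef.optimal_cell <- function(object, ...) {
  if (object$status != "optimal") return(numeric(0))
  st <- object$state
  c(stats::setNames(st$phi, paste0("phi_", names(st$phi))),
    stats::setNames(st$alpha, paste0("alpha_", names(st$alpha))),
    beta = st$beta, mu = st$mu)
}

#' @export
residuals.optimal_cell <- function(object, type = c("relative", "raw"), ...) {
  type <- match.arg(type)
  if (is.null(object$residual_report)) return(numeric(0))
  if (type == "relative") object$residual_report$equalities_rel
  else object$residual_report$equalities
}

#' @export
plot.optimal_cell <- function(x, ...) {
  if (x$status != "optimal") {
    graphics::plot.new()
    graphics::title(main = sprintf("no optimal state (%s)", x$status))
    return(invisible(x))
  }
  phi <- x$state$phi
  graphics::barplot(phi, names.arg = names(phi),
                    ylab = "proteome investment fraction",
                    main = sprintf("mu = %.3f / day at %.1f C",
                                   x$mu_per_day, x$env$T_celsius), ...)
  invisible(x)
}

#' @export
print.thermal_sweep <- function(x, ...) {
  v <- x$status == "optimal"
  cat(sprintf("Thermal sweep: %d temperatures (%.0f..%.0f C), %d viable\n",
              nrow(x), min(x$temperature), max(x$temperature), sum(v)))
  if (any(v)) {
    i <- which.max(ifelse(v, x$mu_per_day, -Inf))
    cat(sprintf("  max growth %.4f day^-1 at %.0f C\n",
                x$mu_per_day[i], x$temperature[i]))
    sw <- detect_metabolic_switch(x)
    if (nrow(sw))
      cat("  metabolic switches:",
          paste(sprintf("%s->%s @%g C", sw$from_pathway, sw$to_pathway,
                        sw$temperature), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
plot.thermal_sweep <- function(x, which = c("growth", "traits"), ...) {
  which <- match.arg(which)
  v <- x$status == "optimal"
  if (which == "growth") {
    graphics::plot(x$temperature, x$mu_per_day, type = "b", pch = 16,
                   xlab = "temperature (C)", ylab = "growth rate (1/day)",
                   ...)
  } else {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::plot(x$temperature, x$mu_per_day, type = "b", pch = 16,
                   xlab = "T (C)", ylab = "growth (1/day)")
    graphics::plot(x$temperature, x$CUE, type = "b", pch = 16,
                   xlab = "T (C)", ylab = "CUE")
    graphics::plot(x$temperature, x$volume, type = "b", pch = 16, log = "y",
                   xlab = "T (C)", ylab = "volume (um^3)")
    graphics::plot(x$temperature, x$q_cell, type = "b", pch = 16,
                   xlab = "T (C)", ylab = "N:C quota")
  }
  invisible(x)
}
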