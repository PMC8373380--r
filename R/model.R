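#' Two-threshold phenomenological model of GAL induction
#'
#' Constructs the parameter set describing how glucose inhibits galactose
#' (GAL) pathway induction in single cells. Two decreasing Hill curves carry
#' the whole phenomenology: one for the *fraction* of cells that induce the
#' pathway, positioned by the threshold `F90` (the glucose concentration at
#' which 90% of cells are still induced), and one for the mean log10
#' expression *level* of the induced subpopulation, positioned by `E10` (the
#' glucose concentration at which that level has fallen to 10% of its
#' zero-glucose maximum). Cell-to-cell spread around either subpopulation
#' mean is a quadratic function of the mean (see [sd_of_log_level()]).
#'
#' Expression is measured as log10 reporter level relative to the maximal
#' induction in pure galactose. The level curve is scaled to run from
#' `log_level_max` (default -0.5) at zero glucose down to `log_level_min`
#' (default -3); the uninduced subpopulation sits at a constant
#' `log_level_uninduced` (default -3, i.e. a relative expression of 1e-3).
#'
#' Default Hill coefficients (1.15 for the level curve, 1.69 for the
#' fraction curve) are the mean values fitted to natural-isolate induction
#' curves; they are consumed here as constants.
#'
#' @param E10 Glucose concentration (% w/v, > 0) at which the induced
#'   subpopulation's level reaches 10% of maximal.
#' @param F90 Glucose concentration (% w/v, > 0) at which 90% of cells are
#'   induced.
#' @param n_level,n_frac Hill coefficients (> 0) of the level and fraction
#'   curves.
#' @param log_level_max,log_level_min Upper and lower ends of the scaled
#'   level curve, in log10 relative expression.
#' @param log_level_uninduced Mean log10 relative expression of the
#'   uninduced subpopulation.
#' @param sd_a,sd_c,sd_b Constants of the quadratic noise model
#'   `sd = sd_a * (log_level + sd_c)^2 + sd_b`.
#' @param sd_floor Small positive floor applied to the quadratic, which goes
#'   negative far outside the expression range it was fitted on.
#'
#' @return An object of class `gal_model`: a named list of validated
#'   parameters.
#' @seealso [mean_induced_log_level()], [induced_fraction_model()],
#'   [simulate_profile()]
#' @examples
#' m <- gal_model(E10 = 0.0625, F90 = 0.0625)
#' mean_induced_log_level(0, m) # -0.5, the zero-glucose maximum
#' induced_fraction_model(m$F90, m) # 0.9 by definition of F90
#' @export
gal_model <- function(E10, F90, n_level = 1.15, n_frac = 1.69,
                      log_level_max = -0.5, log_level_min = -3,
                      log_level_uninduced = -3,
                      sd_a = -0.2, sd_c = 1.75, sd_b = 0.4,
                      sd_floor = 0.01) {
  stop_if_not_scalar_number(E10, "E10", positive = TRUE)
  stop_if_not_scalar_number(F90, "F90", positive = TRUE)
  stop_if_not_scalar_number(n_level, "n_level", positive = TRUE)
  stop_if_not_scalar_number(n_frac, "n_frac", positive = TRUE)
  stop_if_not_scalar_number(log_level_max, "log_level_max")
  stop_if_not_scalar_number(log_level_min, "log_level_min")
  stop_if_not_scalar_number(log_level_uninduced, "log_level_uninduced")
  stop_if_not_scalar_number(sd_floor, "sd_floor", positive = TRUE)
  if (log_level_min >= log_level_max) {
    abort("`log_level_min` must be below `log_level_max`.")
  }
  structure(
    list(
      E10 = E10, F90 = F90, n_level = n_level, n_frac = n_frac,
      log_level_max = log_level_max, log_level_min = log_level_min,
      log_level_uninduced = log_level_uninduced,
      sd_a = sd_a, sd_c = sd_c, sd_b = sd_b, sd_floor = sd_floor
    ),
    class = "gal_model"
  )
}

#' @export
print.gal_model <- function(x, ...) {
  cat("<gal_model>\n")
  cat(sprintf("  E10 = %g%% glucose (level curve, n = %g)\n", x$E10, x$n_level))
  cat(sprintf("  F90 = %g%% glucose (fraction curve, n = %g)\n", x$F90, x$n_frac))
  cat(sprintf(
    "  log10 level range [%g, %g], uninduced at %g\n",
    x$log_level_min, x$log_level_max, x$log_level_uninduced
  ))
  cat(sprintf(
    "  noise sd = %g*(log10 level + %g)^2 + %g (floor %g)\n",
    x$sd_a, x$sd_c, x$sd_b, x$sd_floor
  ))
  invisible(x)
}

#' Threshold conversion factors for the two Hill curves
#'
#' The Hill curves are parameterized by their 10%/90% thresholds rather than
#' their midpoints. `hill_beta()` converts `E10` into the level curve's
#' midpoint `beta * E10`: with `beta = (0.6/0.4)^(1/n)`, the scaled level at
#' glucose `E10` is exactly 10% of the zero-glucose maximum on the linear
#' scale. `hill_alpha()` converts `F90` into the fraction curve's midpoint
#' `alpha * F90`: with `alpha = (0.9/0.1)^(1/n)`, the induced fraction at
#' glucose `F90` is exactly 0.9.
#'
#' @param n_level,n_frac Hill coefficient (> 0).
#' @return A dimensionless conversion factor (>= 1).
#' @examples
#' hill_alpha(1) # 9
#' hill_beta(1) # 1.5
#' @export
hill_beta <- function(n_level) {
  stop_if_not_scalar_number(n_level, "n_level", positive = TRUE)
  (0.6 / 0.4)^(1 / n_level)
}

#' @rdname hill_beta
#' @export
hill_alpha <- function(n_frac) {
  stop_if_not_scalar_number(n_frac, "n_frac", positive = TRUE)
  (0.9 / 0.1)^(1 / n_frac)
}

check_glucose <- function(glucose) {
  if (!is.numeric(glucose) || any(!is.finite(glucose)) || any(glucose < 0)) {
    abort("`glucose` must be numeric and >= 0.")
  }
  invisible(glucose)
}

#' Mean log10 expression level of the induced subpopulation
#'
#' Evaluates the level Hill curve
#' `log10(level) = (B^n / (g^n + B^n)) * (max - min) + min` with midpoint
#' `B = hill_beta(n) * E10`. With the default scaling from -3 to -0.5 this
#' is the printed form `... * 2.5 - 3`. The curve decreases from
#' `log_level_max` at zero glucose towards `log_level_min`, and passes one
#' log10 unit (10% on the linear scale) below its maximum at `glucose = E10`.
#'
#' @param glucose Glucose concentration(s), % w/v, >= 0. Vectorized.
#' @param model A [gal_model()].
#' @return Log10 relative expression, same length as `glucose`.
#' @export
mean_induced_log_level <- function(glucose, model) {
  stopifnot(inherits(model, "gal_model"))
  check_glucose(glucose)
  mid <- hill_beta(model$n_level) * model$E10
  h <- mid^model$n_level / (glucose^model$n_level + mid^model$n_level)
  h * (model$log_level_max - model$log_level_min) + model$log_level_min
}

#' Fraction of induced cells as a function of glucose
#'
#' Evaluates the fraction Hill curve `f = A^n / (g^n + A^n)` with midpoint
#' `A = hill_alpha(n) * F90`. The fraction decreases from 1 at zero glucose
#' and equals 0.9 at `glucose = F90`.
#'
#' @inheritParams mean_induced_log_level
#' @return Induced fraction in `[0, 1]`, same length as `glucose`.
#' @export
induced_fraction_model <- function(glucose, model) {
  stopifnot(inherits(model, "gal_model"))
  check_glucose(glucose)
  mid <- hill_alpha(model$n_frac) * model$F90
  mid^model$n_frac / (glucose^model$n_frac + mid^model$n_frac)
}

#' Cell-to-cell standard deviation of log10 expression
#'
#' The spread of a subpopulation around its mean log10 level is modelled as
#' a downward quadratic in the mean,
#' `sd = sd_a * (log_level + sd_c)^2 + sd_b` (defaults
#' `-0.2 * (x + 1.75)^2 + 0.4`), fitted to observed expression
#' distributions. The quadratic peaks at 0.4 at `log_level = -1.75` and is
#' clamped from below at `model$sd_floor` because it turns negative outside
#' roughly (-3.16, -0.34), a range the level curve never leaves by much.
#'
#' @param log_level Mean log10 relative expression. Vectorized.
#' @param model A [gal_model()].
#' @return Standard deviation(s) of log10 expression, always > 0.
#' @export
sd_of_log_level <- function(log_level, model) {
  stopifnot(inherits(model, "gal_model"))
  raw <- model$sd_a * (log_level + model$sd_c)^2 + model$sd_b
  pmax(raw, model$sd_floor)
}

#' Tabulate both response curves over a glucose grid
#'
#' Convenience wrapper that evaluates the induced fraction, the induced mean
#' log10 level and the noise SD at each glucose concentration, returning one
#' tidy row per concentration. Useful for plotting and for Hill-coefficient
#' fitting ([fit_hill_coefficient()]).
#'
#' @inheritParams mean_induced_log_level
#' @return A tibble with columns `glucose`, `induced_fraction`,
#'   `induced_mean_log_level`, `induced_sd`.
#' @export
induction_curves <- function(glucose, model) {
  lvl <- mean_induced_log_level(glucose, model)
  tibble(
    glucose = glucose,
    induced_fraction = induced_fraction_model(glucose, model),
    induced_mean_log_level = lvl,
    induced_sd = sd_of_log_level(lvl, model)
  )
}

#' Read and write model parameters as flat JSON
#'
#' Serializes a [gal_model()] to a flat key-value JSON file and back, so
#' that parameter sets can travel alongside event tables.
#'
#' @param model A [gal_model()].
#' @param path File path.
#' @return `write_gal_model()` returns `path` invisibly; `read_gal_model()`
#'   returns a `gal_model`.
#' @export
write_gal_model <- function(model, path) {
  stopifnot(inherits(model, "gal_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gal_model
#' @export
read_gal_model <- function(path) {
  pars <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(gal_model, pars)
}
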