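#' Split a sample into induced and uninduced subpopulations
#'
#' Gates a condition's cells against an uninduced reference population: the
#' gate is the `gate_quantile` (default 0.99) quantile of the reference's
#' log10 expression, and cells above it are called induced. A one-sided
#' quantile gate operationalizes "outside the range of an uninduced
#' population": induction only raises expression, and the literal min/max
#' range of a 20,000-cell sample is an unstable order statistic.
#'
#' @param x Condition cells: numeric vector, `population_sample`, or data
#'   frame with a `log_expression` column.
#' @param uninduced_ref Uninduced reference cells (same forms accepted).
#' @param gate_quantile Quantile of the reference used as the gate.
#' @return A list of class `subpop_split`: `gate_threshold`, `induced`
#'   (per-cell logical), `induced_fraction`, `n_induced` and
#'   `induced_mean_log_level` (NA when no cell passes the gate).
#' @export
split_subpopulations <- function(x, uninduced_ref, gate_quantile = 0.99) {
  x <- as_log_expression(x)
  ref <- as_log_expression(uninduced_ref)
  if (length(ref) < 1) abort("`uninduced_ref` must be non-empty.")
  if (gate_quantile <= 0 || gate_quantile >= 1) {
    abort("`gate_quantile` must be in (0, 1).")
  }
  gate <- quantile(ref, gate_quantile, names = FALSE)
  induced <- x > gate
  structure(
    list(
      gate_threshold = gate,
      induced = induced,
      induced_fraction = mean(induced),
      n_induced = sum(induced),
      induced_mean_log_level = if (any(induced)) mean(x[induced]) else NA_real_
    ),
    class = "subpop_split"
  )
}

#' Extract E10 and F90 summary metrics from an induction profile
#'
#' Computes the two summary metrics that position a strain in the
#' phase diagram. Each titration condition is gated against the profile's
#' uninduced reference ([split_subpopulations()]) to obtain the empirical
#' induced fraction and the mean log10 level of the induced subpopulation.
#' Then, interpolating linearly in log10(glucose):
#'
#' * `F90` is the glucose concentration where the induced fraction crosses
#'   0.9. If every condition is below 0.9 the metric is `NA` ("not
#'   reached"); if every condition is at or above 0.9 the highest tested
#'   glucose is returned and flagged as a lower bound.
#' * `E10` is the glucose concentration where the induced subpopulation's
#'   mean log10 level crosses one log10 unit (10% on the linear scale)
#'   below the maximal-induction reference level. `NA` when the profile
#'   never crosses that target.
#'
#' Because measuring F90 requires measurable induction, the F90 of a strain
#' whose expression level shuts off early (a unimodal strain) is a lower
#' bound on the true threshold; pass the strain's modality call via
#' `modality` to have such metrics flagged.
#'
#' @param profile An `induction_profile` with both reference populations.
#' @param gate_quantile Gate quantile for [split_subpopulations()].
#' @param modality Optional modality for lower-bound flagging: a
#'   [classify_profile()] result or one of `"bimodal"`/`"unimodal"`.
#' @return An object of class `gal_metrics`: list with `per_condition`
#'   (tibble of glucose, induced fraction, induced mean level), `E10`,
#'   `F90`, `f90_lower_bound`, `max_level_log`, `gate_threshold`,
#'   `gate_quantile`, `replicate_id`.
#' @export
profile_metrics <- function(profile, gate_quantile = 0.99, modality = NULL) {
  stopifnot(inherits(profile, "induction_profile"))
  ref <- as_log_expression(profile$uninduced_ref)
  splits <- purrr::map(profile$conditions$condition, function(cond) {
    cells <- profile$cells$log_expression[profile$cells$condition == cond]
    split_subpopulations(cells, ref, gate_quantile)
  })
  per <- dplyr::arrange(
    tibble(
      condition = profile$conditions$condition,
      glucose = profile$conditions$glucose,
      induced_fraction = purrr::map_dbl(splits, "induced_fraction"),
      n_induced = purrr::map_int(splits, "n_induced"),
      induced_mean_log_level = purrr::map_dbl(splits, "induced_mean_log_level")
    ),
    .data$glucose
  )
  max_split <- split_subpopulations(
    profile$max_induction_ref, ref, gate_quantile
  )
  max_level <- max_split$induced_mean_log_level
  is_unimodal <- !is.null(modality) && identical(modality_label(modality), "unimodal")

  # F90: glucose where the induced fraction falls through 0.9
  fr <- per$induced_fraction
  if (all(fr < 0.9)) {
    f90 <- NA_real_
    f90_lb <- FALSE
  } else if (all(fr >= 0.9)) {
    f90 <- max(per$glucose)
    f90_lb <- TRUE
  } else {
    f90 <- cross_glucose(per$glucose, fr, 0.9)
    f90_lb <- FALSE
  }
  if (is_unimodal && !is.na(f90)) f90_lb <- TRUE

  # E10: glucose where the induced mean level falls 1 log10 below maximum
  e10 <- if (is.na(max_level) || sum(is.finite(per$induced_mean_log_level)) < 2) {
    NA_real_
  } else {
    cross_glucose(per$glucose, per$induced_mean_log_level, max_level - 1)
  }
  structure(
    list(
      per_condition = per,
      E10 = e10,
      F90 = f90,
      f90_lower_bound = f90_lb,
      max_level_log = max_level,
      gate_threshold = splits[[1]]$gate_threshold,
      gate_quantile = gate_quantile,
      replicate_id = profile$replicate_id
    ),
    class = "gal_metrics"
  )
}

modality_label <- function(modality) {
  if (inherits(modality, "modality_call")) {
    if (modality$status != "ok") {
      return("unclassifiable")
    }
    return(if (modality$profile_is_bimodal) "bimodal" else "unimodal")
  }
  as.character(modality)
}

#' @rdname profile_metrics
#' @export
compute_F90 <- function(profile, gate_quantile = 0.99, modality = NULL) {
  m <- profile_metrics(profile, gate_quantile, modality)
  structure(m$F90, lower_bound = m$f90_lower_bound)
}

#' @rdname profile_metrics
#' @export
compute_E10 <- function(profile, gate_quantile = 0.99) {
  profile_metrics(profile, gate_quantile)$E10
}

#' @export
print.gal_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not reached" else sprintf("%.4g%%", v)
  cat(sprintf(
    "<gal_metrics> %s: E10 = %s, F90 = %s%s\n",
    x$replicate_id, fmt(x$E10), fmt(x$F90),
    if (x$f90_lower_bound) " (lower bound)" else ""
  ))
  invisible(x)
}

#' @export
tidy.gal_metrics <- function(x, ...) {
  x$per_condition
}

#' @export
glance.gal_metrics <- function(x, ...) {
  tibble(
    replicate_id = x$replicate_id,
    E10 = x$E10,
    F90 = x$F90,
    f90_lower_bound = x$f90_lower_bound,
    max_level_log = x$max_level_log,
    gate_threshold = x$gate_threshold
  )
}

#' Fit a Hill coefficient and threshold to an empirical response curve
#'
#' Least-squares fits the corresponding model-core Hill form to a measured
#' dose-response table: for `kind = "level"`, the scaled level curve of
#' [mean_induced_log_level()] (response in log10 relative expression,
#' threshold reported as E10); for `kind = "fraction"`, the fraction curve
#' of [induced_fraction_model()] (threshold reported as F90). The level
#' curve's -3 to -0.5 scaling is held fixed; only `n` and the threshold are
#' free.
#'
#' @param curve Data frame with columns `glucose` and `response` (log10
#'   level, or induced fraction), at least 4 points spanning the
#'   transition.
#' @param kind `"level"` or `"fraction"`.
#' @param log_level_max,log_level_min Scale of the level curve (ignored for
#'   `kind = "fraction"`).
#' @return One-row tibble: `kind`, `n`, `threshold`, `converged`.
#' @export
fit_hill_coefficient <- function(curve, kind = c("level", "fraction"),
                                 log_level_max = -0.5, log_level_min = -3) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(curve), all(c("glucose", "response") %in% names(curve)))
  curve <- curve[is.finite(curve$glucose) & is.finite(curve$response), ]
  if (nrow(curve) < 4) abort("Need at least 4 finite curve points.")
  g <- curve$glucose
  y <- curve$response
  start <- list(n = 1, K = exp(mean(log(g))))
  form <- if (kind == "level") {
    rng <- log_level_max - log_level_min
    y ~ (((0.6 / 0.4)^(1 / n) * K)^n /
      (g^n + ((0.6 / 0.4)^(1 / n) * K)^n)) * rng + log_level_min
  } else {
    y ~ ((9^(1 / n) * K)^n / (g^n + (9^(1 / n) * K)^n))
  }
  fit <- try(
    minpack.lm::nlsLM(
      form,
      start = start, lower = c(1e-3, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    silent = TRUE
  )
  if (inherits(fit, "try-error")) {
    return(tibble(
      kind = kind, n = NA_real_, threshold = NA_real_, converged = FALSE
    ))
  }
  cf <- coef(fit)
  tibble(
    kind = kind, n = unname(cf["n"]), threshold = unname(cf["K"]),
    converged = TRUE
  )
}

#' One-row summary of a profile: metrics plus modality
#'
#' Convenience pipeline step combining [classify_profile()] and
#' [profile_metrics()] (with lower-bound flagging wired through) into a
#' single tidy row per profile, the shape a strain panel summary table
#' wants.
#'
#' @param profile An `induction_profile`.
#' @inheritParams classify_condition
#' @inheritParams profile_metrics
#' @return One-row tibble: `replicate_id`, `modality`, `n_bimodal`, `E10`,
#'   `F90`, `f90_lower_bound`, `max_level_log`.
#' @export
analyze_profile <- function(profile, gate_quantile = 0.99,
                            r2_threshold = 0.99, sep_mult = 2,
                            min_fraction = 0.15, n_bins = 64) {
  call <- classify_profile(profile, r2_threshold, sep_mult, min_fraction, n_bins)
  met <- profile_metrics(profile, gate_quantile, modality = call)
  tibble(
    replicate_id = profile$replicate_id,
    modality = modality_label(call),
    n_bimodal = sum(call$per_condition$is_bimodal, na.rm = TRUE),
    E10 = met$E10,
    F90 = met$F90,
    f90_lower_bound = met$f90_lower_bound,
    max_level_log = met$max_level_log
  )
}
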