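#' Fit a one- or two-component Gaussian curve to an expression histogram
#'
#' Bins the log10 expression values into `n_bins` equal-width bins spanning
#' the sample range and least-squares fits a sum of `k` Gaussian curves to
#' the binned density (Levenberg-Marquardt, via minpack.lm). The fit is the
#' curve-fitting analogue of eyeballing a flow-cytometry histogram, not a
#' likelihood-based mixture model, so goodness of fit is summarized by the
#' degree-of-freedom adjusted R-squared
#' `1 - (1 - R2) * (N - 1) / (N - p - 1)` with `N = n_bins` bins and
#' `p = 3k` fitted parameters (amplitude, mean, sd per component).
#'
#' Initialization is deterministic so calls are reproducible: the
#' one-component fit starts from sample moments; the two-component fit is
#' started from a fixed ladder of quantile pairs (25/75, then 10/90, then
#' 5/95) for the means, both SDs at the pooled within-half SD after
#' splitting the sample midway between the starting means, and equal
#' amplitudes. All starts are tried and the converged fit with the smallest
#' residual sum of squares wins; no random restarts are involved. A single symmetric start
#' can land in a local optimum that splits the major peak when one
#' component is small, which is exactly the regime the minor-fraction
#' criterion must resolve. Component weights are recovered from the fitted
#' curve areas (`amplitude * sd`, normalized).
#'
#' @param x Per-cell log10 expression values: a numeric vector, a
#'   `population_sample`, or any data frame with a `log_expression` column.
#' @param k Number of Gaussian components, 1 or 2.
#' @param n_bins Number of histogram bins (default 64).
#' @return An object of class `gaussian_fit` with elements `k`, `means`,
#'   `sds`, `weights`, `amplitudes`, `r2`, `adj_r2`, `n_bins` and
#'   `converged`. A fit that fails to converge is returned with
#'   `converged = FALSE` and `adj_r2 = -Inf` (worst possible), never
#'   silently dropped.
#' @export
fit_gaussians <- function(x, k, n_bins = 64) {
  x <- as_log_expression(x)
  if (length(x) < 100) abort("Need at least 100 cells to fit a histogram.")
  if (!k %in% c(1, 2)) abort("`k` must be 1 or 2.")
  if (sd(x) == 0) abort("Degenerate sample: zero variance.")
  brk <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = brk, plot = FALSE)
  d <- h$density
  mid <- h$mids
  failed <- structure(
    list(
      k = k, means = rep(NA_real_, k), sds = rep(NA_real_, k),
      weights = rep(NA_real_, k), amplitudes = rep(NA_real_, k),
      r2 = NA_real_, adj_r2 = -Inf, n_bins = n_bins, converged = FALSE
    ),
    class = "gaussian_fit"
  )
  if (k == 1L) {
    starts <- list(list(a1 = max(d), m1 = mean(x), s1 = sd(x)))
    form <- d ~ a1 * exp(-(mid - m1)^2 / (2 * s1^2))
    lower <- c(0, -Inf, 1e-4)
  } else {
    starts <- lapply(list(c(0.25, 0.75), c(0.10, 0.90), c(0.05, 0.95)), function(p) {
      q <- quantile(x, p, names = FALSE)
      lo <- x[x <= mean(q)]
      hi <- x[x > mean(q)]
      s0 <- sqrt(
        (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) / (length(x) - 2)
      )
      s0 <- max(s0, diff(range(x)) / n_bins, 1e-4)
      list(
        a1 = max(d) / 2, m1 = q[1], s1 = s0,
        a2 = max(d) / 2, m2 = q[2], s2 = s0
      )
    })
    form <- d ~ a1 * exp(-(mid - m1)^2 / (2 * s1^2)) +
      a2 * exp(-(mid - m2)^2 / (2 * s2^2))
    lower <- c(0, -Inf, 1e-4, 0, -Inf, 1e-4)
  }
  fit <- NULL
  best_ss <- Inf
  for (start in starts) {
    cand <- try(
      minpack.lm::nlsLM(
        form,
        start = start, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      silent = TRUE
    )
    if (inherits(cand, "try-error")) next
    ss <- sum(resid(cand)^2)
    if (ss < best_ss) {
      fit <- cand
      best_ss <- ss
    }
  }
  if (is.null(fit)) {
    return(failed)
  }
  cf <- coef(fit)
  amps <- cf[paste0("a", seq_len(k))]
  means <- cf[paste0("m", seq_len(k))]
  sds <- cf[paste0("s", seq_len(k))]
  areas <- amps * sds
  weights <- if (sum(areas) > 0) areas / sum(areas) else rep(NA_real_, k)
  r2 <- 1 - sum(resid(fit)^2) / sum((d - mean(d))^2)
  p <- 3 * k
  adj_r2 <- 1 - (1 - r2) * (n_bins - 1) / (n_bins - p - 1)
  structure(
    list(
      k = k, means = unname(means), sds = unname(sds),
      weights = unname(weights), amplitudes = unname(amps),
      r2 = r2, adj_r2 = adj_r2, n_bins = n_bins, converged = TRUE
    ),
    class = "gaussian_fit"
  )
}

as_log_expression <- function(x) {
  if (is.data.frame(x)) {
    if (!"log_expression" %in% names(x)) {
      abort("Data frame input must have a `log_expression` column.")
    }
    x <- x$log_expression
  }
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("Expression values must be finite numerics.")
  }
  x
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_fit> k = %d, adj R2 = %.4f%s\n", x$k, x$adj_r2,
    if (x$converged) "" else " (fit failed)"
  ))
  if (x$converged) {
    for (i in seq_len(x$k)) {
      cat(sprintf(
        "  component %d: mean %.3f, sd %.3f, weight %.3f\n",
        i, x$means[i], x$sds[i], x$weights[i]
      ))
    }
  }
  invisible(x)
}

#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble(
    component = seq_len(x$k),
    mean = x$means,
    sd = x$sds,
    weight = x$weights,
    amplitude = x$amplitudes
  )
}

#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble(
    k = x$k, r2 = x$r2, adj_r2 = x$adj_r2,
    n_bins = x$n_bins, converged = x$converged
  )
}

#' Bimodality criteria on a two-component fit
#'
#' Applies the two bimodality criteria to a fitted two-component
#' `gaussian_fit`: the component means must be separated by more than
#' `sep_mult` times the larger component SD, and the minor component's
#' weight must exceed `min_fraction`. The decision is symmetric under
#' relabelling of the components.
#'
#' @param fit A `gaussian_fit` with `k = 2`.
#' @param sep_mult Separation multiplier (default 2).
#' @param min_fraction Minor-component weight threshold (default 0.15).
#' @return One-row tibble with `separation`, `max_sd`, `minor_fraction`,
#'   `is_bimodal`.
#' @export
bimodality_criteria <- function(fit, sep_mult = 2, min_fraction = 0.15) {
  stopifnot(inherits(fit, "gaussian_fit"), fit$k == 2L)
  sep <- abs(diff(fit$means))
  mx <- max(fit$sds)
  minor <- min(fit$weights)
  tibble(
    separation = sep,
    max_sd = mx,
    minor_fraction = minor,
    is_bimodal = isTRUE(sep > sep_mult * mx && minor > min_fraction)
  )
}

#' Classify one condition's expression distribution as uni- or bimodal
#'
#' Implements the model-selection rule used throughout the analysis: fit a
#' single Gaussian first; if its adjusted R-squared is at least
#' `r2_threshold` (default 0.99) the distribution is called unimodal.
#' Otherwise fit two Gaussians and call the distribution bimodal only if
#' the means are separated by more than `sep_mult` times the larger SD
#' *and* the smaller component carries more than `min_fraction` of the
#' cells. Fit failures yield status `"unclassifiable"` rather than a
#' silent default call.
#'
#' @inheritParams fit_gaussians
#' @param r2_threshold Adjusted R-squared above which the single-Gaussian
#'   fit is accepted (default 0.99).
#' @param sep_mult,min_fraction Bimodality criteria, see
#'   [bimodality_criteria()].
#' @return One-row tibble: `status` ("ok"/"unclassifiable"), `is_bimodal`,
#'   `adj_r2_single`, `separation`, `max_sd`, `minor_fraction` and a `fit`
#'   list-column holding the decisive `gaussian_fit`.
#' @export
classify_condition <- function(x, r2_threshold = 0.99, sep_mult = 2,
                               min_fraction = 0.15, n_bins = 64) {
  fit1 <- try(fit_gaussians(x, 1, n_bins), silent = TRUE)
  if (inherits(fit1, "try-error")) {
    return(tibble(
      status = "unclassifiable", is_bimodal = NA,
      adj_r2_single = NA_real_, separation = NA_real_,
      max_sd = NA_real_, minor_fraction = NA_real_, fit = list(NULL)
    ))
  }
  if (fit1$converged && fit1$adj_r2 >= r2_threshold) {
    return(tibble(
      status = "ok", is_bimodal = FALSE,
      adj_r2_single = fit1$adj_r2, separation = NA_real_,
      max_sd = NA_real_, minor_fraction = NA_real_, fit = list(fit1)
    ))
  }
  fit2 <- try(fit_gaussians(x, 2, n_bins), silent = TRUE)
  if (inherits(fit2, "try-error") || !fit2$converged) {
    return(tibble(
      status = "unclassifiable", is_bimodal = NA,
      adj_r2_single = fit1$adj_r2, separation = NA_real_,
      max_sd = NA_real_, minor_fraction = NA_real_, fit = list(NULL)
    ))
  }
  crit <- bimodality_criteria(fit2, sep_mult, min_fraction)
  tibble(
    status = "ok", is_bimodal = crit$is_bimodal,
    adj_r2_single = fit1$adj_r2, separation = crit$separation,
    max_sd = crit$max_sd, minor_fraction = crit$minor_fraction,
    fit = list(fit2)
  )
}

#' Classify every condition of a profile and aggregate to a profile call
#'
#' Runs [classify_condition()] on each titration condition of an
#' [simulate_profile()] (or [read_profile()]) object. The profile is called
#' bimodal if at least one condition is bimodal. Unclassifiable conditions
#' are excluded from that rule but retained in the per-condition table; a
#' profile with no classifiable condition gets status `"unclassifiable"`.
#'
#' @param profile An `induction_profile`.
#' @inheritParams classify_condition
#' @return An object of class `modality_call`: list with `per_condition`
#'   (tibble, one row per condition), `profile_is_bimodal`, `status`,
#'   `replicate_id` and the thresholds used.
#' @export
classify_profile <- function(profile, r2_threshold = 0.99, sep_mult = 2,
                             min_fraction = 0.15, n_bins = 64) {
  stopifnot(inherits(profile, "induction_profile"))
  if (nrow(profile$conditions) < 1) abort("Profile has no conditions.")
  per <- purrr::map_dfr(profile$conditions$condition, function(cond) {
    cells <- profile$cells$log_expression[profile$cells$condition == cond]
    dplyr::bind_cols(
      tibble(condition = cond),
      classify_condition(cells, r2_threshold, sep_mult, min_fraction, n_bins)
    )
  })
  per <- dplyr::left_join(
    per, profile$conditions[, c("condition", "glucose", "galactose")],
    by = "condition"
  )
  per <- dplyr::relocate(per, "glucose", "galactose", .after = "condition")
  classifiable <- per$status == "ok"
  status <- if (any(classifiable)) "ok" else "unclassifiable"
  structure(
    list(
      per_condition = per,
      profile_is_bimodal = if (status == "ok") {
        any(per$is_bimodal[classifiable])
      } else {
        NA
      },
      status = status,
      replicate_id = profile$replicate_id,
      thresholds = list(
        r2_threshold = r2_threshold, sep_mult = sep_mult,
        min_fraction = min_fraction, n_bins = n_bins
      )
    ),
    class = "modality_call"
  )
}

#' @export
print.modality_call <- function(x, ...) {
  lab <- if (x$status != "ok") {
    "unclassifiable"
  } else if (x$profile_is_bimodal) "bimodal" else "unimodal"
  cat(sprintf(
    "<modality_call> %s: %s (%d/%d conditions bimodal)\n",
    x$replicate_id, lab,
    sum(x$per_condition$is_bimodal, na.rm = TRUE),
    nrow(x$per_condition)
  ))
  invisible(x)
}

#' @export
tidy.modality_call <- function(x, ...) {
  x$per_condition
}

#' @export
glance.modality_call <- function(x, ...) {
  tibble(
    replicate_id = x$replicate_id,
    status = x$status,
    profile_is_bimodal = x$profile_is_bimodal,
    n_conditions = nrow(x$per_condition),
    n_bimodal = sum(x$per_condition$is_bimodal, na.rm = TRUE),
    n_unclassifiable = sum(x$per_condition$status != "ok")
  )
}

#' Aggregate modality calls across replicates
#'
#' A strain is called bimodal only if *every* replicate's profile shows a
#' bimodal distribution in at least one condition; otherwise it is called
#' unimodal. A replicate with no classifiable condition makes the overall
#' call `"unclassifiable"`.
#'
#' @param calls A list of [classify_profile()] results (one per replicate).
#' @return `"bimodal"`, `"unimodal"` or `"unclassifiable"`.
#' @export
aggregate_modality <- function(calls) {
  if (inherits(calls, "modality_call")) calls <- list(calls)
  if (length(calls) < 1) abort("Need at least one replicate call.")
  stopifnot(all(purrr::map_lgl(calls, inherits, "modality_call")))
  if (any(purrr::map_chr(calls, "status") != "ok")) {
    return("unclassifiable")
  }
  if (all(purrr::map_lgl(calls, "profile_is_bimodal"))) "bimodal" else "unimodal"
}
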