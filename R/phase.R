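#' Threshold grids for the phase-diagram scan
#'
#' The ten-value threshold grid used for the phase-diagram scan. The
#' `"printed"` variant is the list exactly as published, which contains
#' 0.156 where the surrounding twofold series implies 0.0156 (and in fact
#' holds eleven values); the `"twofold"` variant substitutes 0.0156. Both
#' are shipped; neither is asserted as the authors' intent.
#'
#' @param variant `"printed"` or `"twofold"`.
#' @return Descending numeric vector of thresholds (% w/v).
#' @export
phase_grid_values <- function(variant = c("printed", "twofold")) {
  variant <- match.arg(variant)
  v <- c(1, 0.5, 0.25, 0.125, 0.0625, 0.0313, 0.156, 0.0078, 0.0039, 0.0020, 0.0010)
  if (variant == "twofold") v[v == 0.156] <- 0.0156
  sort(v, decreasing = TRUE)
}

#' Simulate and classify a grid of (E10, F90, Hill-coefficient) models
#'
#' For every combination of input thresholds and Hill coefficients,
#' simulates a full titration profile ([simulate_profile()]), classifies
#' its modality ([classify_profile()]) and re-measures the E10/F90 metrics
#' from the simulated cells ([profile_metrics()]). Hill coefficients
#' default to the experimentally fitted extremes plus the fitted means
#' (level curve 0.84/1.15/1.50, fraction curve 0.75/1.69/2.95).
#'
#' Each grid point is simulated as `replicates` independent profiles and
#' the point's modality is the all-replicates aggregate of
#' [aggregate_modality()]: bimodal only if every replicate shows a bimodal
#' condition. A single replicate occasionally yields a false-positive
#' bimodal call when a marginally-resolved condition's curve fit crosses
#' the separation criterion by a hair; requiring the call in every
#' replicate is the rule's own safeguard against that. Measured metrics
#' are averaged over replicates.
#'
#' @param E10_values,F90_values Input threshold grids (% w/v); default
#'   [phase_grid_values()].
#' @param n_level,n_frac Hill-coefficient values to cross with the grids.
#' @param glucose Titration grid for each simulated profile.
#' @param n_cells Cells per condition (default 20000).
#' @param replicates Independent replicate profiles per grid point
#'   (default 2).
#' @param seed Master seed (default 1).
#' @param gate_quantile Gate for metric re-measurement.
#' @param ... Classifier thresholds passed to [classify_profile()].
#' @return A tibble with one row per grid point: `E10_in`, `F90_in`,
#'   `n_level`, `n_frac`, `seed`, `modality`, `n_bimodal_conditions` (in
#'   the least-bimodal replicate, the one the all-replicates rule listens
#'   to), `E10_out`, `F90_out` (replicate means), `f90_lower_bound`.
#' @export
scan_phase_grid <- function(E10_values = phase_grid_values(),
                            F90_values = phase_grid_values(),
                            n_level = c(0.84, 1.15, 1.50),
                            n_frac = c(0.75, 1.69, 2.95),
                            glucose = glucose_titration(),
                            n_cells = 20000, replicates = 2, seed = 1,
                            gate_quantile = 0.99, ...) {
  if (length(E10_values) < 1 || length(F90_values) < 1) {
    abort("Threshold grids must be non-empty.")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")
  combos <- tidyr::expand_grid(
    E10_in = E10_values, F90_in = F90_values,
    n_level = n_level, n_frac = n_frac
  )
  combos$seed <- as.integer(seed) + 100L * seq_len(nrow(combos))
  rows <- purrr::pmap(combos, function(E10_in, F90_in, n_level, n_frac, seed) {
    model <- gal_model(E10_in, F90_in, n_level = n_level, n_frac = n_frac)
    calls <- vector("list", replicates)
    mets <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      prof <- simulate_profile(
        model, glucose,
        n_cells = n_cells, seed = seed + r - 1L,
        replicate_id = sprintf(
          "E%g_F%g_nl%g_nf%g_rep%d", E10_in, F90_in, n_level, n_frac, r
        )
      )
      calls[[r]] <- classify_profile(prof, ...)
      mets[[r]] <- profile_metrics(prof, gate_quantile, modality = calls[[r]])
    }
    mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    tibble(
      modality = aggregate_modality(calls),
      n_bimodal_conditions = min(purrr::map_int(
        calls, ~ sum(.x$per_condition$is_bimodal, na.rm = TRUE)
      )),
      E10_out = mean_or_na(purrr::map_dbl(mets, "E10")),
      F90_out = mean_or_na(purrr::map_dbl(mets, "F90")),
      f90_lower_bound = any(purrr::map_lgl(mets, "f90_lower_bound"))
    )
  })
  dplyr::bind_cols(combos, dplyr::bind_rows(rows))
}

#' Delineate unimodal/bimodal regimes with slope-1 bounding lines
#'
#' In log10(F90) (x) versus log10(E10) (y) space a slope-1 line is
#' `y = x + c`, so each point reduces to its intercept
#' `d = log10(E10) - log10(F90) = log10(E10/F90)`. The unimodal boundary is
#' the slope-1 line with the extreme intercept that still captures every
#' unimodal point on one side; the bimodal boundary does the same for
#' bimodal points. The ambiguous regime is the band between the two lines
#' where both behaviors occur (empty when the classes separate cleanly).
#' Boundaries are exact extremes of the point intercepts, not regression
#' fits, so by construction every point of a class lies on its own side of
#' (or on) its boundary.
#'
#' By default the diagram lives in *measured* metric space (`E10_out`,
#' `F90_out`, as re-measured from the simulated profiles); points whose
#' metrics are not reached within the titration are excluded from boundary
#' fitting but kept in `points`. Set `basis = "input"` to delineate on the
#' model's input thresholds instead.
#'
#' @param points A [scan_phase_grid()] tibble.
#' @param basis `"measured"` or `"input"`.
#' @return An object of class `phase_diagram`: list with `points`,
#'   `basis`, `orientation` (which side of the intercept axis is bimodal),
#'   `unimodal_intercept`, `bimodal_intercept`, `ambiguous` (length-2
#'   interval of intercepts, or NULL), `degenerate`.
#' @export
delineate_regimes <- function(points, basis = c("measured", "input")) {
  basis <- match.arg(basis)
  stopifnot(is.data.frame(points))
  d <- if (basis == "measured") {
    log10(points$E10_out) - log10(points$F90_out)
  } else {
    log10(points$E10_in) - log10(points$F90_in)
  }
  keep <- is.finite(d) & points$modality %in% c("unimodal", "bimodal")
  d_uni <- d[keep & points$modality == "unimodal"]
  d_bi <- d[keep & points$modality == "bimodal"]
  degenerate <- length(d_uni) == 0 || length(d_bi) == 0
  if (degenerate) {
    orientation <- NA_character_
    uni_int <- if (length(d_uni)) max(d_uni) else NA_real_
    bi_int <- if (length(d_bi)) min(d_bi) else NA_real_
    amb <- NULL
  } else if (mean(d_bi) >= mean(d_uni)) {
    # bimodal occupies the high-intercept side (level threshold above
    # fraction threshold)
    orientation <- "bimodal_high"
    uni_int <- max(d_uni)
    bi_int <- min(d_bi)
    amb <- if (bi_int <= uni_int) c(bi_int, uni_int) else NULL
  } else {
    orientation <- "bimodal_low"
    uni_int <- min(d_uni)
    bi_int <- max(d_bi)
    amb <- if (uni_int <= bi_int) c(uni_int, bi_int) else NULL
  }
  structure(
    list(
      points = as_tibble(points),
      basis = basis,
      orientation = orientation,
      unimodal_intercept = uni_int,
      bimodal_intercept = bi_int,
      ambiguous = amb,
      degenerate = degenerate
    ),
    class = "phase_diagram"
  )
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf(
    "<phase_diagram> %d points (%s basis)%s\n",
    nrow(x$points), x$basis,
    if (x$degenerate) " [degenerate: single class]" else ""
  ))
  cat(sprintf(
    "  slope-1 intercepts in log10(E10) - log10(F90): unimodal %s, bimodal %s\n",
    format(x$unimodal_intercept, digits = 3),
    format(x$bimodal_intercept, digits = 3)
  ))
  if (!is.null(x$ambiguous)) {
    cat(sprintf(
      "  ambiguous band: [%.3f, %.3f]\n", x$ambiguous[1], x$ambiguous[2]
    ))
  }
  invisible(x)
}

#' @export
tidy.phase_diagram <- function(x, ...) {
  x$points
}

#' @export
glance.phase_diagram <- function(x, ...) {
  tibble(
    basis = x$basis,
    orientation = x$orientation,
    unimodal_intercept = x$unimodal_intercept,
    bimodal_intercept = x$bimodal_intercept,
    ambiguous_low = if (is.null(x$ambiguous)) NA_real_ else x$ambiguous[1],
    ambiguous_high = if (is.null(x$ambiguous)) NA_real_ else x$ambiguous[2],
    degenerate = x$degenerate,
    n_points = nrow(x$points)
  )
}

#' Predict modality from a strain's position in the phase diagram
#'
#' Side-of-line test of a (E10, F90) pair against the two slope-1
#' boundaries of a [delineate_regimes()] diagram. Points between the
#' boundaries (boundary values inclusive) are `"ambiguous"`; beyond the
#' boundary on the bimodal side, `"bimodal"`; beyond it on the unimodal
#' side, `"unimodal"`. For a degenerate (single-class) diagram the present
#' class's half-plane is used and everything else is `"ambiguous"`.
#'
#' @param diagram A `phase_diagram`.
#' @param E10,F90 Threshold values (% w/v); vectorized, recycled.
#' @return Character vector of `"unimodal"`, `"bimodal"`, `"ambiguous"`.
#' @export
predict_modality <- function(diagram, E10, F90) {
  stopifnot(inherits(diagram, "phase_diagram"))
  d <- log10(E10) - log10(F90)
  ints <- c(diagram$unimodal_intercept, diagram$bimodal_intercept)
  if (diagram$degenerate) {
    present <- if (is.na(diagram$bimodal_intercept)) "unimodal" else "bimodal"
    return(rep(present, length(d)))
  }
  lo <- min(ints)
  hi <- max(ints)
  bi_high <- diagram$orientation == "bimodal_high"
  dplyr::case_when(
    d >= lo & d <= hi ~ "ambiguous",
    (d > hi) == bi_high ~ "bimodal",
    .default = "unimodal"
  )
}
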