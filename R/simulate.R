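#' Twofold glucose titration grid
#'
#' Builds the descending geometric series of glucose concentrations used in
#' the induction experiments: by default a twofold titration from 1% down
#' to 0.0039%, which yields the canonical nine conditions.
#'
#' @param top Highest concentration (% w/v, > 0).
#' @param bottom Lowest concentration to reach (% w/v, > 0, <= `top`).
#' @param factor Fold-step between consecutive concentrations (> 1).
#' @return Numeric vector of concentrations, descending from `top`. Both
#'   endpoints are included when the series reaches `bottom` exactly (a
#'   relative tolerance of 1e-8 absorbs floating-point drift).
#' @examples
#' glucose_titration() # 9 concentrations, 1 down to 0.0039
#' @export
glucose_titration <- function(top = 1, bottom = 0.0039, factor = 2) {
  stop_if_not_scalar_number(top, "top", positive = TRUE)
  stop_if_not_scalar_number(bottom, "bottom", positive = TRUE)
  stop_if_not_scalar_number(factor, "factor")
  if (factor <= 1) abort("`factor` must be > 1.")
  if (bottom > top) abort("`bottom` must not exceed `top`.")
  n_steps <- floor(log(top / (bottom * (1 - 1e-8))) / log(factor))
  top / factor^(0:n_steps)
}

#' Simulate a single-cell expression sample for one condition
#'
#' Draws `n_cells` per-cell log10 relative expression values as the
#' two-component normal mixture the model prescribes at this glucose
#' concentration: a fraction `f` of induced cells (from
#' [induced_fraction_model()]) around the induced mean level (from
#' [mean_induced_log_level()]), and the remaining cells around the constant
#' uninduced level. The induced cell count is `f * n_cells` rounded half-up;
#' the rounding and the per-cell ground-truth labels are recorded so that
#' downstream gates can be validated exactly. Subpopulation SDs both come
#' from the quadratic noise model evaluated at the respective mean (0.0875
#' at the uninduced level of -3). Values are not truncated; histogramming
#' downstream handles tails.
#'
#' @param model A [gal_model()].
#' @param glucose Glucose concentration, % w/v, >= 0.
#' @param galactose Galactose concentration, % w/v (metadata only: the model
#'   holds galactose fixed and responds to glucose).
#' @param n_cells Number of cells to draw (>= 1; default 20000).
#' @param seed Optional integer seed; the same seed reproduces the sample
#'   exactly.
#' @param label Condition label; derived from the sugar mix when `NULL`.
#' @param induced_fraction Optional override of the model's induced
#'   fraction, e.g. 0 for a reference population known to be uninduced or 1
#'   for maximal induction.
#' @return A tibble of class `population_sample` with one row per cell
#'   (`condition`, `glucose`, `galactose`, `log_expression`, `induced`) and
#'   attributes `true_fraction`, `true_level`, `seed`, `n_cells`.
#' @export
simulate_population <- function(model, glucose, galactose = 0.25,
                                n_cells = 20000, seed = NULL, label = NULL,
                                induced_fraction = NULL) {
  stopifnot(inherits(model, "gal_model"))
  check_glucose(glucose)
  stop_if_not_scalar_number(n_cells, "n_cells")
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  f <- induced_fraction %||% induced_fraction_model(glucose, model)
  if (f < 0 || f > 1) abort("`induced_fraction` must be in [0, 1].")
  m_ind <- mean_induced_log_level(glucose, model)
  m_un <- model$log_level_uninduced
  n_ind <- round_half_up(f * n_cells)
  n_un <- n_cells - n_ind
  x <- with_seed_maybe(seed, c(
    rnorm(n_ind, m_ind, sd_of_log_level(m_ind, model)),
    rnorm(n_un, m_un, sd_of_log_level(m_un, model))
  ))
  out <- tibble(
    condition = label %||% sprintf("glu%.6g_gal%.6g", glucose, galactose),
    glucose = glucose,
    galactose = galactose,
    log_expression = x,
    induced = rep(c(TRUE, FALSE), c(n_ind, n_un))
  )
  attr(out, "true_fraction") <- f
  attr(out, "true_level") <- m_ind
  attr(out, "seed") <- seed
  attr(out, "n_cells") <- n_cells
  class(out) <- c("population_sample", class(out))
  out
}

#' Simulate a full induction profile across a glucose titration
#'
#' Generates one [simulate_population()] sample per glucose concentration,
#' plus the two reference populations every metric extraction needs: an
#' uninduced reference (grown in 2% glucose, simulated with the induced
#' fraction forced to 0 because that control is uninduced by construction)
#' and a maximal-induction reference (2% galactose, no glucose, induced
#' fraction forced to 1). Per-condition seeds are derived deterministically
#' from the master seed (`seed + condition index`), so profiles are
#' reproducible while conditions stay independent.
#'
#' @param model A [gal_model()].
#' @param glucose Vector of glucose concentrations (% w/v); default the
#'   nine-point twofold titration of [glucose_titration()]. Stored and
#'   processed in ascending order.
#' @param galactose Galactose concentration held constant across the
#'   titration (metadata).
#' @param n_cells Cells per condition.
#' @param seed Optional master seed.
#' @param replicate_id Identifier carried through classification and
#'   metrics.
#' @return An object of class `induction_profile`: a list with `cells`
#'   (tibble of all titration cells), `conditions` (one row per condition
#'   with seeds and simulation ground truth), `uninduced_ref`,
#'   `max_induction_ref`, `replicate_id` and `model`.
#' @export
simulate_profile <- function(model, glucose = glucose_titration(),
                             galactose = 0.25, n_cells = 20000, seed = NULL,
                             replicate_id = "rep1") {
  stopifnot(inherits(model, "gal_model"))
  if (length(glucose) < 1) abort("`glucose` must be non-empty.")
  check_glucose(glucose)
  glucose <- sort(unique(glucose))
  seeds <- if (is.null(seed)) rep(list(NULL), length(glucose) + 2L) else
    as.list(as.integer(seed) + seq_len(length(glucose) + 2L))
  samples <- purrr::map2(glucose, seeds[seq_along(glucose)], function(g, s) {
    simulate_population(model, g, galactose, n_cells, seed = s)
  })
  uninduced <- simulate_population(
    model, 2, 0, n_cells,
    seed = seeds[[length(glucose) + 1L]],
    label = "uninduced_ref", induced_fraction = 0
  )
  maxind <- simulate_population(
    model, 0, 2, n_cells,
    seed = seeds[[length(glucose) + 2L]],
    label = "max_induction_ref", induced_fraction = 1
  )
  conditions <- tibble(
    condition = purrr::map_chr(samples, ~ .x$condition[1]),
    glucose = glucose,
    galactose = galactose,
    n_cells = n_cells,
    seed = purrr::map_int(
      seeds[seq_along(glucose)],
      ~ if (is.null(.x)) NA_integer_ else .x
    ),
    true_fraction = purrr::map_dbl(samples, ~ attr(.x, "true_fraction")),
    true_level = purrr::map_dbl(samples, ~ attr(.x, "true_level"))
  )
  cells <- dplyr::bind_rows(lapply(samples, as_tibble))
  for (a in c("true_fraction", "true_level", "seed", "n_cells")) {
    attr(cells, a) <- NULL
  }
  structure(
    list(
      cells = cells,
      conditions = conditions,
      uninduced_ref = uninduced,
      max_induction_ref = maxind,
      replicate_id = replicate_id,
      model = model
    ),
    class = "induction_profile"
  )
}

#' @export
print.induction_profile <- function(x, ...) {
  cat(sprintf(
    "<induction_profile> %s: %d conditions x %d cells (glucose %g-%g%%, galactose %g%%)\n",
    x$replicate_id, nrow(x$conditions), x$conditions$n_cells[1],
    min(x$conditions$glucose), max(x$conditions$glucose),
    x$conditions$galactose[1]
  ))
  invisible(x)
}

#' Write and read induction profiles as event-table directories
#'
#' `write_profile()` lays an [simulate_profile()] object out as one CSV
#' event table per condition (columns `condition`, `glucose`, `galactose`,
#' `log_expression`, `induced`) plus `uninduced_ref.csv`,
#' `max_induction_ref.csv` and a `manifest.json` sidecar holding the model
#' parameters, seeds and per-condition ground truth. This is the same
#' tabular stand-in for flow-cytometry exports that the metrics and
#' classifier functions consume; `read_profile()` reconstructs the profile
#' losslessly from such a directory.
#'
#' @param profile An `induction_profile`.
#' @param dir Directory to create/fill.
#' @return `write_profile()` returns `dir` invisibly; `read_profile()`
#'   returns an `induction_profile`.
#' @export
write_profile <- function(profile, dir) {
  stopifnot(inherits(profile, "induction_profile"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(profile$conditions))) {
    cond <- profile$conditions$condition[i]
    readr::write_csv(
      dplyr::filter(profile$cells, .data$condition == cond),
      file.path(dir, sprintf("condition_%02d.csv", i))
    )
  }
  readr::write_csv(
    as_tibble(profile$uninduced_ref),
    file.path(dir, "uninduced_ref.csv")
  )
  readr::write_csv(
    as_tibble(profile$max_induction_ref),
    file.path(dir, "max_induction_ref.csv")
  )
  manifest <- list(
    replicate_id = profile$replicate_id,
    model = unclass(profile$model),
    conditions = profile$conditions,
    reference_seeds = list(
      uninduced = attr(profile$uninduced_ref, "seed"),
      max_induction = attr(profile$max_induction_ref, "seed")
    )
  )
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

read_event_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      condition = readr::col_character(),
      glucose = readr::col_double(),
      galactose = readr::col_double(),
      log_expression = readr::col_double(),
      induced = readr::col_logical()
    )
  )
}

#' @rdname write_profile
#' @export
read_profile <- function(dir) {
  manifest <- jsonlite::read_json(
    file.path(dir, "manifest.json"),
    simplifyVector = TRUE
  )
  conds <- as_tibble(manifest$conditions)
  files <- file.path(dir, sprintf("condition_%02d.csv", seq_len(nrow(conds))))
  cells <- dplyr::bind_rows(lapply(files, read_event_csv))
  as_ref <- function(path, true_fraction) {
    ref <- read_event_csv(path)
    attr(ref, "true_fraction") <- true_fraction
    attr(ref, "n_cells") <- nrow(ref)
    class(ref) <- c("population_sample", class(ref))
    ref
  }
  structure(
    list(
      cells = cells,
      conditions = conds,
      uninduced_ref = as_ref(file.path(dir, "uninduced_ref.csv"), 0),
      max_induction_ref = as_ref(file.path(dir, "max_induction_ref.csv"), 1),
      replicate_id = manifest$replicate_id,
      model = do.call(gal_model, manifest$model)
    ),
    class = "induction_profile"
  )
}
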