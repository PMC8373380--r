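#' Generate a panel of synthetic strain parameter sets
#'
#' Draws `n_strains` strain-like parameter sets emulating a natural-isolate
#' panel: E10 and F90 log-uniform over `[0.001, 1]` % w/v and Hill
#' coefficients uniform over the experimentally fitted ranges (level
#' 0.84-1.50, fraction 0.75-2.95). The draw is stratified on
#' `log10(E10/F90)`: strain `i` receives the `i`-th stratum of the
#' log-ratio range `[-3, 3]`, so a panel of a handful of strains or more is
#' guaranteed to span both the unimodal (ratio well below 1) and bimodal
#' (ratio well above 1) regimes.
#'
#' @param n_strains Number of strains (>= 1).
#' @param seed Seed; the panel is fully reproducible.
#' @param history_shift Multiplicative factor applied to F90 per
#'   pre-induction history step (default 8.6, the observed fold-change of
#'   F90 across pre-induction carbon sources, versus 1.8 for E10).
#' @param replicates Replicates per (strain, history).
#' @return Tibble of class `strain_panel`: `name`, `E10`, `F90`,
#'   `n_level`, `n_frac`, `history_shift`, `replicates`.
#' @export
make_strain_panel <- function(n_strains = 30, seed = 1, history_shift = 8.6,
                              replicates = 2) {
  stop_if_not_scalar_number(n_strains, "n_strains", positive = TRUE)
  ratio_breaks <- seq(-3, 3, length.out = n_strains + 1L)
  panel <- with_seed_maybe(seed, {
    d <- stats::runif(n_strains, ratio_breaks[-(n_strains + 1L)], ratio_breaks[-1L])
    # feasible band for the log10 geometric-mean threshold given the ratio
    m_lo <- -3 + abs(d) / 2
    m_hi <- -abs(d) / 2
    m <- stats::runif(n_strains, m_lo, m_hi)
    tibble(
      name = sprintf("strain%02d", seq_len(n_strains)),
      E10 = 10^(m + d / 2),
      F90 = 10^(m - d / 2),
      n_level = stats::runif(n_strains, 0.84, 1.50),
      n_frac = stats::runif(n_strains, 0.75, 2.95),
      history_shift = history_shift,
      replicates = as.integer(replicates)
    )
  })
  class(panel) <- c("strain_panel", class(panel))
  panel
}

#' Write a multi-strain, multi-history fixture of event tables
#'
#' Simulates and writes to disk a complete synthetic dataset with the
#' statistical structure the analysis pipeline assumes: for every (strain,
#' history, replicate) a full titration profile plus references is
#' simulated with [simulate_profile()] and written with [write_profile()]
#' under `out_dir/<strain>/<history>/rep<k>/`. Pre-induction history is
#' emulated as a multiplicative shift of the strain's F90: the `k`-th
#' history label applies `history_shift^(k - 1)` (E10 untouched, matching
#' the observation that pre-induction carbon acts mainly through F90). A
#' `manifest.json` at the fixture root records the master seed and the
#' ground truth of every profile.
#'
#' @param panel A [make_strain_panel()] tibble (or compatible data frame).
#' @param histories Character vector of history labels; successive labels
#'   apply successive powers of the strain's `history_shift` to F90.
#' @param out_dir Output directory (created if missing).
#' @param n_cells Cells per condition.
#' @param glucose Titration grid.
#' @param seed Master seed; all profile seeds derive from it.
#' @return A `fixture_set`: list with `manifest` (profile-level tibble with
#'   paths and ground truth), `panel`, `out_dir`, `seed`.
#' @export
emit_fixture <- function(panel, histories = c("glucose", "raffinose"),
                         out_dir, n_cells = 20000,
                         glucose = glucose_titration(), seed = 1) {
  stopifnot(is.data.frame(panel), length(histories) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- tidyr::expand_grid(
    strain = panel$name,
    history = histories,
    replicate = seq_len(max(panel$replicates))
  )
  grid <- dplyr::inner_join(
    grid, dplyr::rename(panel, strain = "name"),
    by = "strain"
  )
  grid <- dplyr::filter(grid, .data$replicate <= .data$replicates)
  grid$profile_seed <- as.integer(seed) + 1000L * seq_len(nrow(grid))
  rows <- purrr::pmap(
    grid[, c(
      "strain", "history", "replicate", "E10", "F90", "n_level",
      "n_frac", "history_shift", "profile_seed"
    )],
    function(strain, history, replicate, E10, F90, n_level, n_frac,
             history_shift, profile_seed) {
      mult <- history_shift^(match(history, histories) - 1L)
      f90_true <- F90 * mult
      model <- gal_model(E10, f90_true, n_level = n_level, n_frac = n_frac)
      prof <- simulate_profile(
        model, glucose,
        n_cells = n_cells, seed = profile_seed,
        replicate_id = sprintf("%s_%s_rep%d", strain, history, replicate)
      )
      rel <- file.path(strain, history, sprintf("rep%d", replicate))
      write_profile(prof, file.path(out_dir, rel))
      tibble(
        path = rel,
        history_multiplier = mult,
        true_E10 = E10,
        true_F90 = f90_true
      )
    }
  )
  manifest <- dplyr::bind_cols(
    grid[, c(
      "strain", "history", "replicate", "n_level", "n_frac", "profile_seed"
    )],
    dplyr::bind_rows(rows)
  )
  jsonlite::write_json(
    list(seed = seed, n_cells = n_cells, glucose = glucose,
         histories = histories, panel = panel, profiles = manifest),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  structure(
    list(manifest = manifest, panel = panel, out_dir = out_dir, seed = seed),
    class = "fixture_set"
  )
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf(
    "<fixture_set> %d profiles (%d strains) under %s\n",
    nrow(x$manifest), nrow(x$panel), x$out_dir
  ))
  invisible(x)
}

#' Read a fixture back from disk
#'
#' `read_fixture()` loads the manifest (ground truth included) written by
#' [emit_fixture()]; `read_fixture_profile()` reconstructs one profile's
#' `induction_profile` from its event tables.
#'
#' @param out_dir Fixture root directory.
#' @return `read_fixture()`: a `fixture_set`; `read_fixture_profile()`: an
#'   `induction_profile`.
#' @export
read_fixture <- function(out_dir) {
  manifest <- jsonlite::read_json(
    file.path(out_dir, "manifest.json"),
    simplifyVector = TRUE
  )
  structure(
    list(
      manifest = as_tibble(manifest$profiles),
      panel = as_tibble(manifest$panel),
      out_dir = out_dir,
      seed = manifest$seed
    ),
    class = "fixture_set"
  )
}

#' @rdname read_fixture
#' @param fixture A `fixture_set`.
#' @param strain,history Labels identifying the profile.
#' @param replicate Replicate number.
#' @export
read_fixture_profile <- function(fixture, strain, history, replicate = 1) {
  stopifnot(inherits(fixture, "fixture_set"))
  rel <- file.path(strain, history, sprintf("rep%d", replicate))
  read_profile(file.path(fixture$out_dir, rel))
}
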