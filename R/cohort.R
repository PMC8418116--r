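#' Synthetic-cohort specification
#'
#' Defines the generative model for a cohort of single-vessel stenosis cases.
#' Each case draws a straight vessel (diameter log-normal around 3 mm, length
#' uniform 20-60 mm), a mid-vessel cosine stenosis with area severity uniform
#' on 30-90% and length uniform 10-20 mm, and couples the resulting
#' pressure-drop model to a constant hyperemic microvascular resistance
#' (default 25 mmHg/(ml/s), so a healthy vessel reaches 4 ml/s hyperemic flow
#' at 100 mmHg) to define a reference "invasive" FFR. Measurement noise is
#' Gaussian on the measured FFR only.
#'
#' @param n_vessels Number of cases, >= 1.
#' @param seed Integer RNG seed; each case uses an independent stream keyed
#'   by `(seed, case index)`, so enlarging the cohort never reshuffles
#'   existing cases.
#' @param diameter_meanlog,diameter_sdlog Log-normal parameters of the vessel
#'   diameter (mm); defaults give median 3 mm.
#' @param length_range Vessel length range (mm), uniform.
#' @param area_stenosis_range Area-stenosis severity range, uniform within
#'   `[0.30, 0.90]`.
#' @param stenosis_length_range Lesion length range (mm), uniform.
#' @param r_micro Hyperemic microvascular resistance (mmHg/(ml/s)).
#' @param ffr_noise_sd SD of the Gaussian measurement noise added to the
#'   reference FFR (dimensionless).
#'
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_vessels = 200, seed = 1,
                        diameter_meanlog = log(3), diameter_sdlog = 0.15,
                        length_range = c(20, 60),
                        area_stenosis_range = c(0.30, 0.90),
                        stenosis_length_range = c(10, 20),
                        r_micro = 25, ffr_noise_sd = 0.03) {
  if (n_vessels < 1) stop_invalid("`n_vessels` must be at least 1.")
  if (r_micro <= 0) stop_invalid("`r_micro` must be positive.")
  if (ffr_noise_sd < 0) stop_invalid("`ffr_noise_sd` must be non-negative.")
  if (diameter_sdlog < 0) stop_invalid("`diameter_sdlog` must be non-negative.")
  for (rng in list(length_range, area_stenosis_range, stenosis_length_range)) {
    if (length(rng) != 2 || rng[1] > rng[2]) stop_invalid("Ranges must be increasing pairs.")
  }
  if (length_range[1] <= 0 || stenosis_length_range[1] <= 0) {
    stop_invalid("Length supports must be positive.")
  }
  if (area_stenosis_range[1] < 0 || area_stenosis_range[2] >= 1) {
    stop_invalid("`area_stenosis_range` must lie within [0, 1).")
  }
  structure(
    list(n_vessels = as.integer(n_vessels), seed = as.integer(seed),
         diameter_meanlog = diameter_meanlog, diameter_sdlog = diameter_sdlog,
         length_range = length_range,
         area_stenosis_range = area_stenosis_range,
         stenosis_length_range = stenosis_length_range,
         r_micro = r_micro, ffr_noise_sd = ffr_noise_sd),
    class = "cohort_spec"
  )
}

#' Reference FFR under a microvascular-resistance coupling
#'
#' The hyperemic operating point is where the inlet pressure balances the
#' epicardial drop plus the microvascular bed:
#' `Pa = f*Q + s*Q^2 + Q*R`. Its positive root
#' `Q* = (-(f + R) + sqrt((f + R)^2 + 4*s*Pa)) / (2*s)` (limit `Pa/(f + R)`
#' when `s = 0`) gives `FFR = Q*R/Pa = (Pa - dP(Q*))/Pa` — the distal-to-
#' proximal pressure ratio at maximal hyperemia, the quantity a pressure
#' wire measures.
#'
#' @param model A [pressure_drop_model()].
#' @param r_micro Hyperemic microvascular resistance (mmHg/(ml/s)), > 0.
#' @param inlet_pressure Aortic pressure (mmHg).
#'
#' @return Reference FFR in `(0, 1]`.
#' @export
#'
#' @examples
#' simulate_reference_ffr(pressure_drop_model(0, 0), 25, 100) # healthy: 1
simulate_reference_ffr <- function(model, r_micro = 25, inlet_pressure = 100) {
  if (r_micro <= 0) stop_invalid("`r_micro` must be positive.")
  fr <- model$f + r_micro
  if (model$s < 1e-12) {
    q_star <- inlet_pressure / fr
  } else {
    q_star <- (-fr + sqrt(fr^2 + 4 * model$s * inlet_pressure)) / (2 * model$s)
  }
  q_star * r_micro / inlet_pressure
}

#' Generate a synthetic stenosis cohort
#'
#' For each case: draw the geometry, derive the pressure-drop coefficients,
#' compute SmartFFR through the full protocol-spline-AUC pipeline, compute
#' the reference FFR via [simulate_reference_ffr()], and add measurement
#' noise to obtain `ffr_measured` (clipped to `[0, 1]`). Deterministic given
#' the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param config A [sim_config()].
#' @param fluid A [fluid_properties()].
#' @param n_centerline_samples Centerline resolution per vessel.
#'
#' @return A tibble with one row per case: `case_id`, `diameter_mm`,
#'   `length_mm`, `area_stenosis`, `f_mmhg_per_mls`, `s_mmhg_per_mls2`,
#'   `ffr_true`, `ffr_measured`, `smartffr`.
#' @export
#'
#' @examples
#' generate_cohort(cohort_spec(n_vessels = 5, seed = 42))
generate_cohort <- function(spec = cohort_spec(), config = sim_config(),
                            fluid = fluid_properties(),
                            n_centerline_samples = 201) {
  stopifnot(inherits(spec, "cohort_spec"))
  cases <- purrr::map(seq_len(spec$n_vessels), function(i) {
    # per-case stream keyed by (seed, index): extensible without reshuffling
    set.seed((abs(spec$seed) * 10007L + i) %% .Machine$integer.max)
    d <- rlnorm(1, spec$diameter_meanlog, spec$diameter_sdlog)
    len <- runif(1, spec$length_range[1], spec$length_range[2])
    sa <- runif(1, spec$area_stenosis_range[1], spec$area_stenosis_range[2])
    sl <- min(runif(1, spec$stenosis_length_range[1], spec$stenosis_length_range[2]),
              0.8 * len)
    noise <- rnorm(1, 0, 1)

    seg <- make_straight_vessel(d, len, n_centerline_samples,
                                segment_id = sprintf("case%03d", i))
    seg <- apply_stenosis(seg, stenosis_spec(len / 2, sl, sa))
    model <- segment_pressure_drop_model(seg, fluid)
    sffr <- smartffr(seg, config = config, fluid = fluid)$value
    ffr_true <- simulate_reference_ffr(model, spec$r_micro, config$inlet_pressure)
    ffr_meas <- min(max(ffr_true + spec$ffr_noise_sd * noise, 0), 1)
    tibble(
      case_id = sprintf("case%03d", i),
      diameter_mm = d, length_mm = len, area_stenosis = sa,
      f_mmhg_per_mls = model$f, s_mmhg_per_mls2 = model$s,
      ffr_true = ffr_true, ffr_measured = ffr_meas, smartffr = sffr
    )
  })
  dplyr::bind_rows(cases)
}

#' Read and write cohort CSV files
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param path File path.
#'
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_format(paste0("Cohort file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE)
}

#' Evaluate an index against a reference FFR column
#'
#' Bundles the diagnostic-validation layer for a paired dataset: Pearson
#' correlation, Bland-Altman agreement, ROC with Youden cutoff, and the
#' confusion matrix at a given (or the Youden-optimal) index cutoff.
#'
#' @param data Data frame with the index and reference columns.
#' @param index_col,reference_col Column names (default `"smartffr"`,
#'   `"ffr_measured"`).
#' @param index_cutoff Index positivity cutoff; `NULL` (default) uses the
#'   Youden-optimal cutoff from the ROC analysis.
#' @param reference_cutoff Reference positivity cutoff, default 0.80.
#'
#' @return A `diagnostic_evaluation` list with elements `roc`,
#'   `bland_altman`, `pearson_r`, `confusion`, `metrics`, `index_cutoff`,
#'   `reference_cutoff`, `n`.
#' @export
evaluate_index <- function(data, index_col = "smartffr",
                           reference_col = "ffr_measured",
                           index_cutoff = NULL, reference_cutoff = 0.80) {
  if (!all(c(index_col, reference_col) %in% names(data))) {
    stop_invalid("`data` must contain the index and reference columns.")
  }
  idx <- data[[index_col]]
  ref <- data[[reference_col]]
  labels <- as.integer(ref <= reference_cutoff)
  roc <- roc_youden(idx, labels)
  cutoff <- index_cutoff %||% roc$youden_cutoff
  cm <- classify(idx, ref, cutoff, reference_cutoff)
  structure(
    list(roc = roc, bland_altman = bland_altman(idx, ref),
         pearson_r = pearson_r(idx, ref),
         confusion = cm, metrics = confusion_metrics(cm),
         index_cutoff = cutoff, reference_cutoff = reference_cutoff,
         n = length(idx)),
    class = "diagnostic_evaluation"
  )
}

#' @export
print.diagnostic_evaluation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<diagnostic_evaluation> n = %d | r = %.3f | AUC = %.3f | cutoff <= %g\n",
              x$n, x$pearson_r, x$roc$auc, x$index_cutoff))
  cat(sprintf("  accuracy %.1f%% | sens %.1f%% | spec %.1f%% | PPV %.1f%% | NPV %.1f%%\n",
              m$accuracy, m$sensitivity, m$specificity, m$ppv, m$npv))
  invisible(x)
}
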