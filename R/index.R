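#' Build the Pd/Pa-versus-flow curve
#'
#' The per-step distal-to-proximal pressure ratios are joined by a cubic
#' interpolating spline evaluated at `n_grid` (default 100) evenly spaced
#' points on the standard flow range 0-4 ml/s. An anchor point (0, 1) is
#' prepended — zero flow causes zero pressure drop — and the curve is clipped
#' to `[0, 1]` since supra-unity ratios are interpolation artifacts.
#'
#' @param samples Pressure-flow samples (`flow_mls`, `pa_mmhg`, `pd_mmhg`)
#'   with at least 2 rows and no duplicate flows.
#' @param config A [sim_config()].
#' @param source Provenance tag: `"single-vessel"` or `"branch"`.
#'
#' @return A `pdpa_curve` tibble with columns `flow_mls`, `ratio`.
#' @export
build_curve <- function(samples, config = sim_config(), source = "single-vessel") {
  samples <- as_pressure_flow(samples)
  if (nrow(samples) < 1) stop_invalid("Need at least 1 pressure-flow sample.")
  if (anyDuplicated(samples$flow_mls) > 0) {
    stop_invalid("Duplicate flow values in the samples.")
  }
  q <- c(0, samples$flow_mls)
  r <- c(1, samples$pd_mmhg / samples$pa_mmhg)
  ord <- order(q)
  grid <- seq(config$flow_range[1], config$flow_range[2], length.out = config$n_grid)
  ratio <- spline(q[ord], r[ord], xout = grid, method = "fmm")$y
  new_pdpa_curve(grid, pmin(pmax(ratio, 0), 1), source)
}

new_pdpa_curve <- function(flow_mls, ratio, source) {
  curve <- tibble(flow_mls = flow_mls, ratio = ratio)
  attr(curve, "source") <- source
  class(curve) <- c("pdpa_curve", class(curve))
  curve
}

#' SmartFFR from a Pd/Pa curve
#'
#' SmartFFR is the area under the Pd/Pa-versus-flow curve over 0-4 ml/s
#' divided by the area under the healthy-vessel curve, which is identically 1
#' over the same range (AUC = 4). The area is a composite trapezoidal
#' integral over the curve grid.
#'
#' @param curve A `pdpa_curve` from [build_curve()] or
#'   [rebase_branch_curve()].
#' @param vessel_id,branch_id Optional provenance identifiers.
#'
#' @return A `smartffr_result` with fields `value` (= auc / flow span),
#'   `auc`, `vessel_id`, `branch_id`, `curve`.
#' @export
smartffr_from_curve <- function(curve, vessel_id = NULL, branch_id = NULL) {
  if (!inherits(curve, "pdpa_curve")) stop_invalid("`curve` must be a pdpa_curve.")
  auc <- trapz(curve$flow_mls, curve$ratio)
  span <- max(curve$flow_mls) - min(curve$flow_mls)
  structure(
    list(value = auc / span, auc = auc,
         vessel_id = vessel_id, branch_id = branch_id, curve = curve),
    class = "smartffr_result"
  )
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Closed-form SmartFFR for the quadratic pressure-drop law
#'
#' For `dP(Q) = f*Q + s*Q^2` and constant proximal pressure, the ratio curve
#' is the exact quadratic `1 - (f*Q + s*Q^2)/Pa`, whose mean over 0-4 ml/s is
#' `1 - (2f + 16s/3)/Pa`. Valid while the distal pressure stays positive over
#' the whole range, i.e. `4f + 16s <= Pa`; serves as the analytic oracle for
#' the spline-plus-trapezoid pipeline.
#'
#' @param model A [pressure_drop_model()].
#' @param inlet_pressure Proximal pressure (mmHg).
#'
#' @return SmartFFR value (dimensionless).
#' @export
smartffr_closed_form <- function(model, inlet_pressure = 100) {
  if (4 * model$f + 16 * model$s > inlet_pressure) {
    stop_domain("delta_p(4) exceeds the inlet pressure; the clamped pipeline value no longer matches the closed form.")
  }
  1 - (2 * model$f + 16 * model$s / 3) / inlet_pressure
}

#' Rebase a bifurcation branch curve onto the standard flow range
#'
#' A branch sees only its Murray fraction of each total flow, so its sampled
#' flows rarely match the standard 0-4 ml/s range. The branch samples are
#' summarised by the origin-forced quadratic fit ([fit_pressure_drop()]) and
#' the ratio `1 - dP(Q)/Pa_branch` is evaluated on the standard grid: an
#' interpolation when the branch flows exceed 4 ml/s, an extrapolation when
#' they fall short. The branch's own inlet pressure (mean over its samples)
#' is the proximal pressure.
#'
#' @inheritParams build_curve
#'
#' @return A `pdpa_curve` tibble with source `"branch"`.
#' @export
rebase_branch_curve <- function(samples, config = sim_config()) {
  samples <- as_pressure_flow(samples)
  model <- fit_pressure_drop(samples)
  pa_branch <- mean(samples$pa_mmhg)
  grid <- seq(config$flow_range[1], config$flow_range[2], length.out = config$n_grid)
  ratio <- 1 - delta_p(model, grid) / pa_branch
  new_pdpa_curve(grid, pmin(pmax(ratio, 0), 1), "branch")
}

#' SmartFFR for both branches of a bifurcation
#'
#' Applies [rebase_branch_curve()] then [smartffr_from_curve()] to each
#' branch's pressure-flow samples, typically the output of
#' [run_bifurcation_protocol()].
#'
#' @param branch_samples Named list of exactly two pressure-flow sample
#'   tibbles (names = branch ids).
#' @param config A [sim_config()].
#'
#' @return Named list of `smartffr_result` objects.
#' @export
smartffr_bifurcation <- function(branch_samples, config = sim_config()) {
  if (!is.list(branch_samples) || length(branch_samples) != 2) {
    stop_topology("Exactly two branches are required.")
  }
  ids <- names(branch_samples) %||% c("branch1", "branch2")
  out <- lapply(seq_along(branch_samples), function(i) {
    curve <- rebase_branch_curve(branch_samples[[i]], config)
    smartffr_from_curve(curve, branch_id = ids[i])
  })
  names(out) <- ids
  out
}

#' Compute SmartFFR for a vessel segment
#'
#' End-to-end convenience wrapper: reduced-order protocol run
#' ([run_single_vessel_protocol()]), curve construction ([build_curve()])
#' and area normalisation ([smartffr_from_curve()]).
#'
#' @inheritParams run_single_vessel_protocol
#'
#' @return A `smartffr_result`.
#' @export
#'
#' @examples
#' v <- apply_stenosis(make_straight_vessel(3, 30, 201), stenosis_spec(15, 10, 0.7))
#' smartffr(v)
smartffr <- function(segment, protocol = flow_protocol(), config = sim_config(),
                     fluid = fluid_properties()) {
  samples <- run_single_vessel_protocol(segment, protocol, config, fluid)
  res <- smartffr_from_curve(build_curve(samples, config),
                             vessel_id = segment_id(segment))
  res$samples <- samples
  res
}

#' Read and write externally computed pressure-flow samples
#'
#' Adapter for genuine CFD output: a CSV with header
#' `flow_mls,pa_mmhg,pd_mmhg`, one row per timestep. Rows must have
#' non-negative flow and `pd <= pa`; samples are returned sorted by flow.
#'
#' @param path File path.
#'
#' @return `read_solver_samples()` returns a pressure-flow tibble;
#'   `write_solver_samples()` returns `path` invisibly.
#' @export
read_solver_samples <- function(path) {
  if (!file.exists(path)) stop_format(paste0("Sample file not found: ", path))
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double())),
    error = function(e) stop_format(paste0("Cannot parse ", path, ": ", conditionMessage(e)))
  )
  if (!all(c("flow_mls", "pa_mmhg", "pd_mmhg") %in% names(df))) {
    stop_format(paste0(path, ": missing required columns `flow_mls,pa_mmhg,pd_mmhg`."))
  }
  bad_flow <- which(!is.finite(df$flow_mls) | df$flow_mls < 0)
  if (length(bad_flow) > 0) {
    stop_format(paste0(path, ": negative flow at data row ", bad_flow[1], "."))
  }
  bad_p <- which(df$pd_mmhg > df$pa_mmhg)
  if (length(bad_p) > 0) {
    stop_format(paste0(path, ": pd_mmhg exceeds pa_mmhg at data row ", bad_p[1], "."))
  }
  dplyr::arrange(as_tibble(df), .data$flow_mls)
}

#' @rdname read_solver_samples
#' @param samples Pressure-flow samples to serialise.
#' @export
write_solver_samples <- function(samples, path) {
  samples <- as_pressure_flow(samples)
  lines <- c(
    "flow_mls,pa_mmhg,pd_mmhg",
    paste(fmt9(samples$flow_mls), fmt9(samples$pa_mmhg), fmt9(samples$pd_mmhg), sep = ",")
  )
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @export
print.smartffr_result <- function(x, ...) {
  id <- x$branch_id %||% x$vessel_id %||% "vessel"
  cat(sprintf("<smartffr_result> %s: SmartFFR = %.4f (AUC = %.4f over 0-4 ml/s)\n",
              id, x$value, x$auc))
  invisible(x)
}
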