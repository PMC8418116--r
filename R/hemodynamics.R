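#' Blood properties and simulation configuration
#'
#' Defaults describe blood as an incompressible Newtonian fluid with dynamic
#' viscosity 0.0035 Pa.s and density 1050 kg/m3 under laminar flow — the
#' standard assumptions for coronary-scale hemodynamics.
#'
#' @param dynamic_viscosity Dynamic viscosity (Pa.s), > 0.
#' @param density Density (kg/m3), > 0.
#'
#' @return A `fluid_properties` list.
#' @export
fluid_properties <- function(dynamic_viscosity = 0.0035, density = 1050) {
  if (dynamic_viscosity <= 0 || density <= 0) {
    stop_invalid("Fluid properties must be positive.")
  }
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "fluid_properties")
}

#' @rdname fluid_properties
#' @param inlet_pressure Proximal (aortic) pressure boundary condition (mmHg),
#'   default 100.
#' @param flow_range Flow range of the standard Pd/Pa curve (ml/s),
#'   default `c(0, 4)`.
#' @param n_grid Number of interpolation points on the curve grid, default 100.
#' @param pd_floor Lower clamp for the computed distal pressure (mmHg),
#'   default 0.
#' @export
sim_config <- function(inlet_pressure = 100, flow_range = c(0, 4),
                       n_grid = 100, pd_floor = 0) {
  if (inlet_pressure <= 0) stop_config("`inlet_pressure` must be > 0.")
  if (n_grid < 4) stop_config("`n_grid` must be at least 4.")
  if (length(flow_range) != 2 || flow_range[2] <= flow_range[1]) {
    stop_config("`flow_range` must be an increasing pair.")
  }
  structure(list(inlet_pressure = inlet_pressure, flow_range = flow_range,
                 n_grid = as.integer(n_grid), pd_floor = pd_floor),
            class = "sim_config")
}

#' Staged flow protocol
#'
#' The imposed outlet flows of the quasi-steady protocol. For a single vessel
#' the default is 4 steps at 1, 2, 3, 4 ml/s; for a bifurcation the default
#' total flows are 2, 4, 6, 8 ml/s (8 ml/s peak hyperemia for the left
#' system, i.e. 4 ml/s per branch when the split is even). The per-step
#' duration is retained as metadata only: with no inertial or compliance
#' terms each step is an independent steady state.
#'
#' @param flows Strictly increasing positive flow values (ml/s).
#' @param timestep_duration Duration of each step (s), metadata.
#'
#' @return A `flow_protocol` list.
#' @export
flow_protocol <- function(flows = c(1, 2, 3, 4), timestep_duration = 0.25) {
  if (any(flows <= 0) || any(diff(flows) <= 0)) {
    stop_invalid("`flows` must be strictly increasing and positive.")
  }
  structure(list(flows = as.numeric(flows), timestep_duration = timestep_duration),
            class = "flow_protocol")
}

#' @rdname flow_protocol
#' @export
bifurcation_protocol <- function(flows = c(2, 4, 6, 8), timestep_duration = 0.25) {
  flow_protocol(flows, timestep_duration)
}

#' Quadratic pressure-drop model of a segment
#'
#' The reduced-order engine summarises a segment's resistance as
#' `dP(Q) = f*Q + s*Q^2` (mmHg, Q in ml/s): a linear viscous term plus a
#' quadratic separation term — the standard stenosis pressure-drop law.
#'
#' @param f Viscous coefficient, mmHg/(ml/s), >= 0.
#' @param s Separation coefficient, mmHg/(ml/s)^2, >= 0.
#'
#' @return A `pressure_drop_model` list.
#' @export
pressure_drop_model <- function(f, s) {
  if (!is.finite(f) || !is.finite(s) || f < 0 || s < 0) {
    stop_invalid("`f` and `s` must be finite and non-negative.")
  }
  structure(list(f = f, s = s), class = "pressure_drop_model")
}

#' @rdname pressure_drop_model
#' @param model A `pressure_drop_model`.
#' @param flow Flow values (ml/s).
#' @return `delta_p()` returns the pressure drop (mmHg) at `flow`.
#' @export
delta_p <- function(model, flow) {
  model$f * flow + model$s * flow^2
}

#' Viscous (Poiseuille) coefficient of a segment
#'
#' Integrates the local Poiseuille resistance along the centerline:
#' `f = (128 mu / pi) * integral D(z)^-4 dz` (trapezoidal over the centerline
#' samples), converted to mmHg/(ml/s). For a straight tube this reduces to
#' the closed-form `128 mu L / (pi D^4)`.
#'
#' @param segment A [vessel_segment()].
#' @param fluid A [fluid_properties()].
#'
#' @return Viscous coefficient `f` in mmHg/(ml/s).
#' @export
#'
#' @examples
#' viscous_coefficient(make_straight_vessel(3, 30, 31)) # ~0.396 mmHg/(ml/s)
viscous_coefficient <- function(segment, fluid = fluid_properties()) {
  validate_segment(segment)
  z_m <- segment$arc_mm * 1e-3
  inv_d4 <- (2 * segment$radius_mm * 1e-3)^-4
  integral <- sum(diff(z_m) * (head(inv_d4, -1) + tail(inv_d4, -1)) / 2)
  f_si <- 128 * fluid$dynamic_viscosity / pi * integral # Pa / (m3/s)
  f_si * 1e-6 / MMHG_IN_PA
}

#' Separation (Young-Tsai) coefficient of a segment
#'
#' Expansion loss downstream of the throat:
#' `s = (rho * K_t / (2 * A0^2)) * (A0/As - 1)^2` with empirical constant
#' `K_t = 1.52`, reference area `A0` (from [reference_radius()]) and minimal
#' lumen area `As`; converted to mmHg/(ml/s)^2. A healthy vessel
#' (`As = A0`) has `s = 0`.
#'
#' @inheritParams viscous_coefficient
#' @param k_t Empirical separation constant, default 1.52.
#'
#' @return Separation coefficient `s` in mmHg/(ml/s)^2.
#' @export
separation_coefficient <- function(segment, fluid = fluid_properties(), k_t = 1.52) {
  validate_segment(segment)
  r0_m <- reference_radius(segment) * 1e-3
  rs_m <- min(segment$radius_mm) * 1e-3
  a0 <- pi * r0_m^2
  as_ <- pi * rs_m^2
  if (as_ >= a0) {
    return(0)
  }
  s_si <- fluid$density * k_t / (2 * a0^2) * (a0 / as_ - 1)^2 # Pa / (m3/s)^2
  s_si * 1e-12 / MMHG_IN_PA
}

#' @rdname viscous_coefficient
#' @export
segment_pressure_drop_model <- function(segment, fluid = fluid_properties()) {
  pressure_drop_model(
    f = viscous_coefficient(segment, fluid),
    s = separation_coefficient(segment, fluid)
  )
}

#' Fit the quadratic pressure-drop law to pressure-flow samples
#'
#' Least-squares fit of `Pa - Pd = f*Q + s*Q^2` forced through the origin
#' (no drop at zero flow), with `f` and `s` clipped at zero. Used to
#' summarise externally computed solver samples and to rebase bifurcation
#' branch curves onto the standard flow range.
#'
#' @param samples Data frame with columns `flow_mls`, `pa_mmhg`, `pd_mmhg`;
#'   at least 2 distinct positive flows.
#'
#' @return A [pressure_drop_model()].
#' @export
fit_pressure_drop <- function(samples) {
  samples <- as_pressure_flow(samples)
  q <- samples$flow_mls
  keep <- q > 0
  if (length(unique(q[keep])) < 2) {
    stop_invalid("Need at least 2 samples with distinct positive flows.")
  }
  dp <- samples$pa_mmhg[keep] - samples$pd_mmhg[keep]
  qq <- q[keep]
  fit <- lm(dp ~ 0 + qq + I(qq^2))
  cf <- unname(coef(fit))
  pressure_drop_model(f = max(0, cf[1]), s = max(0, cf[2]))
}

as_pressure_flow <- function(samples) {
  if (!is.data.frame(samples) ||
      !all(c("flow_mls", "pa_mmhg", "pd_mmhg") %in% names(samples))) {
    stop_invalid("Samples need columns `flow_mls`, `pa_mmhg`, `pd_mmhg`.")
  }
  as_tibble(samples)
}

#' Murray's-law flow split at a bifurcation
#'
#' Flow through the daughter branches scales with the cube of their
#' diameters: `q2/q1 = (d2/d1)^3`, so branch 1 receives the fraction
#' `d1^3 / (d1^3 + d2^3)` of the parent flow.
#'
#' @param d_d1,d_d2 Reference diameters of the two daughter branches (mm).
#'
#' @return A one-row tibble with `d_d1`, `d_d2`, `q_fraction_1`,
#'   `q_fraction_2` (fractions sum to 1).
#' @export
#'
#' @examples
#' murray_split(3, 2) # branch 1 takes 27/35 of the flow
murray_split <- function(d_d1, d_d2) {
  if (!is.numeric(d_d1) || !is.numeric(d_d2) || d_d1 <= 0 || d_d2 <= 0) {
    stop_invalid("Branch diameters must be positive.")
  }
  c1 <- d_d1^3
  c2 <- d_d2^3
  tibble(
    d_d1 = d_d1, d_d2 = d_d2,
    q_fraction_1 = c1 / (c1 + c2),
    q_fraction_2 = c2 / (c1 + c2)
  )
}

#' Run the staged-flow protocol on a single vessel
#'
#' For each protocol flow `Q` the proximal pressure is the configured inlet
#' pressure and the distal pressure is
#' `max(pd_floor, Pa - f*Q - s*Q^2)` with `(f, s)` from
#' [viscous_coefficient()] and [separation_coefficient()]. The protocol is
#' quasi-steady: each step is an independent steady state.
#'
#' @param segment A [vessel_segment()].
#' @param protocol A [flow_protocol()]; default 1, 2, 3, 4 ml/s.
#' @param config A [sim_config()].
#' @param fluid A [fluid_properties()].
#'
#' @return A tibble of pressure-flow samples: `flow_mls`, `pa_mmhg`,
#'   `pd_mmhg`.
#' @export
#'
#' @examples
#' v <- make_straight_vessel(3, 30, 201)
#' v <- apply_stenosis(v, stenosis_spec(15, 10, 0.7))
#' run_single_vessel_protocol(v)
run_single_vessel_protocol <- function(segment,
                                       protocol = flow_protocol(),
                                       config = sim_config(),
                                       fluid = fluid_properties()) {
  model <- segment_pressure_drop_model(segment, fluid)
  model_samples(model, protocol$flows, config$inlet_pressure, config$pd_floor)
}

model_samples <- function(model, flows, inlet_pressure, pd_floor = 0) {
  tibble(
    flow_mls = flows,
    pa_mmhg = rep(inlet_pressure, length(flows)),
    pd_mmhg = pmax(pd_floor, inlet_pressure - delta_p(model, flows))
  )
}

#' Run the staged-flow protocol on a bifurcating tree
#'
#' The tree must be a parent segment with exactly two daughter branches (the
#' parent may be omitted for a bare junction). Each total flow is divided
#' between the branches by [murray_split()] on their reference diameters;
#' the branch inlet pressure is the parent's distal pressure at the total
#' flow (pressure continuity), and each branch's distal pressure follows its
#' own pressure-drop model at its own flow. Flow conservation
#' `Q1 + Q2 = Qtot` holds exactly at every step.
#'
#' @param tree A [coronary_tree()] whose root has exactly two children.
#' @param protocol A [flow_protocol()] of **total** flows; default
#'   2, 4, 6, 8 ml/s.
#' @inheritParams run_single_vessel_protocol
#'
#' @return A named list (by branch id) of pressure-flow sample tibbles.
#' @export
run_bifurcation_protocol <- function(tree,
                                     protocol = bifurcation_protocol(),
                                     config = sim_config(),
                                     fluid = fluid_properties()) {
  if (!inherits(tree, "coronary_tree")) stop_invalid("`tree` must be a coronary_tree.")
  kids <- tree$children[[tree$root]]
  if (is.null(kids) || length(kids) != 2) {
    stop_topology("The root must have exactly two child branches.")
  }
  grandkids <- unlist(tree$children[kids])
  if (length(grandkids) > 0) {
    stop_topology("Nested bifurcations are not supported; supply a parent with two leaves.")
  }
  parent <- tree$segments[[tree$root]]
  b1 <- tree$segments[[kids[1]]]
  b2 <- tree$segments[[kids[2]]]
  split <- murray_split(2 * reference_radius(b1), 2 * reference_radius(b2))
  parent_model <- segment_pressure_drop_model(parent, fluid)
  m1 <- segment_pressure_drop_model(b1, fluid)
  m2 <- segment_pressure_drop_model(b2, fluid)

  q_tot <- protocol$flows
  pa_branch <- pmax(config$pd_floor,
                    config$inlet_pressure - delta_p(parent_model, q_tot))
  q1 <- split$q_fraction_1 * q_tot
  q2 <- q_tot - q1 # exact conservation
  out <- list(
    tibble(flow_mls = q1, pa_mmhg = pa_branch,
           pd_mmhg = pmax(config$pd_floor, pa_branch - delta_p(m1, q1))),
    tibble(flow_mls = q2, pa_mmhg = pa_branch,
           pd_mmhg = pmax(config$pd_floor, pa_branch - delta_p(m2, q2)))
  )
  names(out) <- kids
  out
}
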