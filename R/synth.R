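#' Specification of a synthetic membrane-crossing system
#'
#' Defines a 1-D overdamped Langevin system that emulates equilibrium
#' diffusion of point solutes across a symmetric membrane barrier: a
#' periodic box of length `box_z` with a Gaussian potential
#' `U(z) = barrier_height * exp(-z^2 / (2 * barrier_halfwidth^2))` in kT
#' units centred on the membrane midplane. The membrane "edges" reported to
#' the detector are placed at `z = +-2 * barrier_halfwidth`, where the
#' barrier has decayed to ~13% of its height. Only the membrane-normal
#' coordinate is simulated: the counting method depends on z alone, and the
#' 1-D system admits an exact analytic crossing-rate oracle
#' ([analytic_crossing_rate()]).
#'
#' Construction fails if the deterministic drift per step,
#' `D * max|U'| * dt`, exceeds a tenth of the barrier half-width: larger
#' steps cannot resolve the barrier and the Euler integration becomes
#' unreliable.
#'
#' @param barrier_height Barrier height (kT, >= 0).
#' @param barrier_halfwidth Gaussian half-width w (nm).
#' @param diffusion_D Diffusion coefficient (nm^2/ns).
#' @param box_z Periodic box length (nm, default 12).
#' @param n_solutes Number of independent solute copies (default 20).
#' @param dt Integration time step (ns).
#' @param n_steps Number of integration steps.
#' @param temperature Nominal temperature (K, default 440); barrier heights
#'   are expressed in kT so dynamics depend on it only through labelling
#'   and energy-unit conversion.
#' @param seed RNG seed (integer).
#' @param record_stride Store every `record_stride`-th step (default 1).
#' @param label Label for the emitted series.
#' @return Object of class `synthetic_spec`.
#' @examples
#' synthetic_spec(barrier_height = 3, barrier_halfwidth = 0.5,
#'                diffusion_D = 0.5, dt = 0.002, n_steps = 1000, seed = 1)
#' @export
synthetic_spec <- function(barrier_height, barrier_halfwidth = 0.5,
                           diffusion_D = 0.5, box_z = 12, n_solutes = 20,
                           dt = 0.002, n_steps = 1e5, temperature = 440,
                           seed = 1L, record_stride = 1L,
                           label = "synthetic") {
  if (barrier_height < 0) pc_input_error("barrier_height must be >= 0 (kT)")
  if (barrier_halfwidth <= 0 || diffusion_D <= 0 || box_z <= 0 || dt <= 0)
    pc_input_error("all lengths, D and dt must be positive")
  if (n_solutes < 1 || n_steps < 1)
    pc_input_error("n_solutes and n_steps must be positive")
  # max |U'| of the Gaussian barrier sits at z = w: dG/(w e^{1/2})
  max_drift <- diffusion_D * barrier_height /
    (barrier_halfwidth * exp(0.5)) * dt
  if (max_drift > 0.1 * barrier_halfwidth)
    pc_stop(sprintf(
      "unstable dt: drift per step %.3g nm exceeds w/10 = %.3g nm",
      max_drift, barrier_halfwidth / 10), "permcount_stability_error")
  structure(
    list(barrier_height = barrier_height,
         barrier_halfwidth = barrier_halfwidth,
         diffusion_D = diffusion_D, box_z = box_z, n_solutes = n_solutes,
         dt = dt, n_steps = as.integer(n_steps), temperature = temperature,
         seed = as.integer(seed), record_stride = as.integer(record_stride),
         label = label),
    class = "synthetic_spec")
}

# barrier potential in kT and membrane edge of a spec
.synth_U <- function(spec) {
  force(spec)
  function(z) spec$barrier_height * exp(-z^2 / (2 * spec$barrier_halfwidth^2))
}
.synth_edge <- function(spec) 2 * spec$barrier_halfwidth

#' Simulate an overdamped Langevin crossing trajectory
#'
#' Integrates `z <- z - D U'(z) dt + sqrt(2 D dt) eta` for every solute
#' copy, periodic in z, starting from an exact Boltzmann draw of the
#' stationary density (so no equilibration burn-in is needed), and returns
#' the recorded positions as a [zseries()] whose `lipid_ref_z` marks the
#' membrane edges at `+-2 * barrier_halfwidth`. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param wrap If `TRUE` (default) positions are wrapped into the box; set
#'   `FALSE` to keep unwrapped coordinates (meaningful for barrier-free
#'   diffusion, e.g. mean-square-displacement checks).
#' @return A [zseries()] (recentred by construction when `wrap = TRUE`).
#' @examples
#' sp <- synthetic_spec(0, diffusion_D = 0.5, dt = 0.01, n_steps = 500,
#'                      n_solutes = 2, seed = 7)
#' simulate_langevin(sp)
#' @export
simulate_langevin <- function(spec, wrap = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  z0 <- rboltzmann_z(spec, spec$n_solutes)
  zm <- .langevin_kernel(z0, spec$barrier_height, spec$barrier_halfwidth,
                         spec$diffusion_D, spec$box_z, spec$dt,
                         spec$n_steps, spec$record_stride, wrap)
  n_rec <- nrow(zm)
  times <- seq_len(n_rec) * spec$dt * spec$record_stride
  edge <- .synth_edge(spec)
  out <- zseries(times = times, z = zm, box_z = spec$box_z,
                 temperature = spec$temperature,
                 lipid_ref_z = matrix(c(-edge, edge), 1L),
                 label = spec$label, wrapped = wrap)
  if (wrap) {
    jump <- abs(apply(out$z, 2L, function(col) c(0, diff(col)))) >
      spec$box_z / 2
    dim(jump) <- dim(out$z)
    attr(out, "jump") <- jump
  }
  out
}

#' Draw z positions from the stationary Boltzmann density of a spec
#'
#' Rejection sampling from `p(z) proportional to exp(-U(z))` over the box;
#' since `U >= 0`, uniform proposals are accepted with probability
#' `exp(-U(z))`. Used to initialise [simulate_langevin()] in its stationary
#' state and as the independent sampling route for free-energy-profile
#' checks.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of samples.
#' @return Numeric vector of z positions (nm) in `[-box_z/2, box_z/2)`.
#' @export
rboltzmann_z <- function(spec, n) {
  U <- .synth_U(spec)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.5) + 16L
    zz <- runif(m, -spec$box_z / 2, spec$box_z / 2)
    out <- c(out, zz[runif(m) < exp(-U(zz))])
  }
  out[seq_len(n)]
}

#' Analytic crossing rate of the synthetic system
#'
#' Exact stationary rate at which the transition-based counter registers
#' events on the synthetic system: through-passages of the transit interval
#' `[-a, a]`, `a = 2 * barrier_halfwidth + crossing_offset` (the detector's
#' crossing planes). For 1-D diffusion in equilibrium over the periodic box
#' the per-solute rate in each direction is
#' `D / (Z * I)` with `I = integral_{-a}^{a} exp(U(z)/kT) dz` (the
#' Smoluchowski barrier-resistance integral of mean-first-passage theory)
#' and `Z = integral_box exp(-U(z)/kT) dz` the box partition integral, so
#' the total bidirectional counting rate is
#' `k = 2 * n_solutes * D / (Z * I)`. With no barrier and a box equal to
#' the transit interval this reduces to the free-diffusion
#' mean-first-passage structure `k = 2 n D / L^2`. Evaluated by numeric
#' quadrature.
#'
#' @param spec A [synthetic_spec()].
#' @param crossing_offset Crossing-plane offset beyond the membrane edge
#'   (nm, default 1.0), matching the detector configuration.
#' @return Expected event rate (ns^-1) summed over solutes and directions.
#' @examples
#' sp <- synthetic_spec(3, 0.5, 0.5, dt = 0.002, n_steps = 10, seed = 1)
#' analytic_crossing_rate(sp)
#' @export
analytic_crossing_rate <- function(spec, crossing_offset = 1.0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  U <- .synth_U(spec)
  a <- .synth_edge(spec) + crossing_offset
  if (2 * a > spec$box_z)
    pc_input_error("transit interval exceeds the box")
  I <- tryCatch(
    integrate(function(z) exp(U(z)), -a, a, rel.tol = 1e-10)$value,
    error = function(e) pc_stop(paste0("quadrature failed: ",
                                       conditionMessage(e)),
                                "permcount_numeric_error"))
  Z <- integrate(function(z) exp(-U(z)), -spec$box_z / 2, spec$box_z / 2,
                 rel.tol = 1e-10)$value
  2 * spec$n_solutes * spec$diffusion_D / (Z * I)
}

#' Piecewise-linear trajectory with known ground-truth event count
#'
#' Builds a [zseries()] by linear interpolation through scripted `(time, z)`
#' waypoints, sampled at a fixed stride. Waypoint z-coordinates are
#' *unwrapped*: the path is interpolated literally, and a scripted segment
#' that crosses `+-box_z/2` represents travel across the periodic boundary
#' (the emitted, wrapped frames show the corresponding coordinate jump). The
#' number of genuine membrane crossings is computed symbolically from the
#' waypoint region sequence (boundary crossings transfer the bulk
#' assignment without an event) and attached as attribute `"true_events"`,
#' so detector tests know the answer by construction.
#'
#' @param waypoints Data frame or two-column matrix of `(time, z)` in
#'   ns/nm, time strictly increasing; z unwrapped (may exceed the box).
#' @param box_z Box length (nm).
#' @param membrane_edge Membrane surface position (nm); surfaces at
#'   `+-membrane_edge`.
#' @param crossing_offset Crossing-plane offset (nm, default 1.0).
#' @param dt Sampling stride (ns, default 0.1).
#' @param temperature Temperature label (K, default 440).
#' @return A wrapped [zseries()] with attributes `"true_events"` and
#'   `"geometry"` (the matching [membrane_geometry()]).
#' @examples
#' wp <- data.frame(time = c(0, 5), z = c(-4, 4))
#' attr(crafted_trajectory(wp, 12, 2), "true_events")
#' @export
crafted_trajectory <- function(waypoints, box_z, membrane_edge,
                               crossing_offset = 1.0, dt = 0.1,
                               temperature = 440) {
  wp <- as.data.frame(waypoints)
  names(wp)[1:2] <- c("time", "z")
  if (nrow(wp) < 2L) pc_input_error("need at least two waypoints")
  if (any(diff(wp$time) <= 0))
    pc_input_error("waypoint times must be strictly increasing")
  geom <- membrane_geometry(-membrane_edge, membrane_edge, crossing_offset)

  times <- seq(wp$time[1L], wp$time[nrow(wp)], by = dt)
  z_unwrapped <- stats::approx(wp$time, wp$z, xout = times)$y
  z <- .wrap_z(z_unwrapped, box_z)

  # ground truth by symbolic walk over the waypoint region sequence; a
  # segment that changes periodic image crossed the boundary
  image_of <- function(z) floor((z + box_z / 2) / box_z)
  zw <- .wrap_z(wp$z, box_z)
  reg <- function(z) if (z <= geom$lower_plane) 0L else
    if (z >= geom$upper_plane) 2L else 1L
  state <- NA_integer_; jumped <- FALSE; true_events <- 0L
  for (i in seq_len(nrow(wp))) {
    if (i > 1L && image_of(wp$z[i]) != image_of(wp$z[i - 1L]))
      jumped <- TRUE
    ri <- reg(zw[i])
    if (ri == 1L) next
    if (is.na(state)) { state <- ri; jumped <- FALSE }
    else if (ri == state) jumped <- FALSE
    else {
      if (!jumped) true_events <- true_events + 1L
      state <- ri; jumped <- FALSE
    }
  }
  out <- zseries(times, z, box_z, temperature,
                 lipid_ref_z = matrix(c(-membrane_edge, membrane_edge), 1L),
                 label = "crafted", wrapped = TRUE)
  jump <- matrix(c(FALSE, abs(diff(z)) > box_z / 2), ncol = 1L)
  attr(out, "jump") <- jump
  attr(out, "true_events") <- true_events
  attr(out, "geometry") <- geom
  out
}

#' Synthetic compound library with a known calibration line
#'
#' Generates a compound table whose log-log relation between simulated and
#' apparent permeability is linear with Gaussian scatter:
#' `log10(P_sim)` uniform over `log10_psim_range` and
#' `log10(P_app) = m0 * log10(P_sim) + c0 + N(0, noise_sigma)`. With zero
#' noise [fit_loglog()] recovers `(m0, c0)` exactly; with noise it supplies
#' the ground truth for parameter-recovery checks. The default range spans
#' the simulated permeabilities of the packaged 18-compound library
#' (7e-2 to 1.7e1 cm/s).
#'
#' @param m0,c0 True slope and intercept (log10 cm/s).
#' @param noise_sigma Scatter of `log10(P_app)` (log10 units, >= 0).
#' @param n_compounds Library size (>= 3).
#' @param seed RNG seed.
#' @param log10_psim_range Range of `log10(P_sim)` (default
#'   `c(-1.2, 1.25)`).
#' @return Data frame with columns `compound`, `P_sim_167C`, `P_app_exp`.
#' @examples
#' fit_loglog(synthetic_library(1.1, -4.8, 0, 6, seed = 2), "167C")
#' @export
synthetic_library <- function(m0, c0, noise_sigma, n_compounds = 18,
                              seed = 1L,
                              log10_psim_range = c(-1.2, 1.25)) {
  if (noise_sigma < 0) pc_input_error("noise_sigma must be >= 0")
  if (n_compounds < 3L) pc_input_error("need at least 3 compounds")
  set.seed(seed)
  lx <- runif(n_compounds, log10_psim_range[1L], log10_psim_range[2L])
  ly <- m0 * lx + c0 + rnorm(n_compounds, 0, noise_sigma)
  data.frame(compound = sprintf("synth%02d", seq_len(n_compounds)),
             P_sim_167C = 10^lx, P_app_exp = 10^ly,
             stringsAsFactors = FALSE)
}
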