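#' Steady-state crossing rate by the derivative plateau criterion
#'
#' The running rate `k(t)` converges to its steady-state value once the
#' finite difference between consecutive checkpoints falls below a
#' threshold. The plateau onset is the earliest checkpoint from which
#' `|dk/dt| < threshold` holds for *all* later checkpoints; the steady-state
#' rate is the average crossing frequency over the plateau, i.e. events in
#' the plateau window divided by its duration. The window opens at the
#' onset checkpoint (the interval ending there is the last one that failed
#' the criterion, so its events are excluded) and closes at the final
#' checkpoint. With `k` in ns^-1 and checkpoint
#' spacing in ns the threshold carries units ns^-2; the default 0.004 is
#' the convergence criterion used with 10 ns checkpoints.
#'
#' The 1-sigma uncertainty is, by default, the Poisson counting error
#' `sqrt(n_events) / T` over the same window, which is the exact standard
#' deviation of this estimator for a constant-rate process.
#' `sigma_method = "block"` instead splits the plateau into thirds and
#' reports the standard error of the three block rates.
#'
#' @param rates A [rate_series()].
#' @param threshold Plateau threshold on `|dk/dt|` (ns^-2, default 0.004).
#' @param min_plateau_checkpoints Minimum number of checkpoints the plateau
#'   must span (default 5; guards against single-interval false plateaus).
#' @param sigma_method `"poisson"` (default) or `"block"`.
#' @return List with `k_ss` (ns^-1), `k_sigma` (ns^-1), `plateau_onset`
#'   (ns), `n_plateau_events`, and `plateau_checkpoints`.
#' @examples
#' rs <- rate_series(data.frame(end_time = seq(0.5, 100, by = 0.5)),
#'                   total_time = 100, checkpoint_interval = 10)
#' steady_state_rate(rs)$k_ss
#' @export
steady_state_rate <- function(rates, threshold = 0.004,
                              min_plateau_checkpoints = 5,
                              sigma_method = c("poisson", "block")) {
  stopifnot(inherits(rates, "rate_series"))
  sigma_method <- match.arg(sigma_method)
  if (threshold <= 0) pc_input_error("threshold must be positive")
  m <- length(rates$k)
  if (m < min_plateau_checkpoints + 1L)
    pc_converge_error(sprintf(
      "only %d checkpoints; need at least min_plateau_checkpoints + 1 = %d",
      m, min_plateau_checkpoints + 1L))
  ok <- abs(rates$dk_dt[-1L]) < threshold      # ok[i]: interval (i, i+1)
  # onset index: earliest i with all intervals from i onwards below threshold
  bad <- which(!ok)
  onset <- if (length(bad)) max(bad) + 1L else 1L
  if (m - onset + 1L < min_plateau_checkpoints)
    pc_converge_error(sprintf(
      paste0("no steady-state plateau of >= %d checkpoints ",
             "(last |dk/dt| above %.4g at %.6g ns); trajectory too short"),
      min_plateau_checkpoints, threshold,
      rates$checkpoint_times[if (length(bad)) max(bad) + 1L else 1L]))
  idx <- onset:m
  window_start <- rates$checkpoint_times[onset]
  n_ev <- rates$cumulative_events[m] - rates$cumulative_events[onset]
  T_plateau <- rates$checkpoint_times[m] - window_start
  k_ss <- n_ev / T_plateau
  if (sigma_method == "poisson") {
    k_sigma <- sqrt(n_ev) / T_plateau
  } else {
    cuts <- window_start + T_plateau * (0:3) / 3
    cnt <- vapply(1:3, function(b) {
      hi <- sum(rates$checkpoint_times <= cuts[b + 1L] + 1e-9)
      lo <- sum(rates$checkpoint_times <= cuts[b] + 1e-9)
      (if (hi) rates$cumulative_events[hi] else 0L) -
        (if (lo) rates$cumulative_events[lo] else 0L)
    }, numeric(1L))
    k_sigma <- sd(cnt / (T_plateau / 3)) / sqrt(3)
  }
  list(k_ss = k_ss, k_sigma = k_sigma,
       plateau_onset = rates$checkpoint_times[onset],
       n_plateau_events = n_ev, plateau_checkpoints = length(idx))
}

#' Convert a crossing rate to a simulated permeability
#'
#' The crossing rate `k` (events/ns, bidirectional) converts to a molar rate
#' `r = k / N_A` (mol/s after the ns-to-s conversion) and then to the
#' single-bilayer permeability `P_sim = r / (2 A C)` (cm/s), where `A` is
#' the lateral cross-sectional area of the membrane and `C` the solute
#' concentration. The factor 2 accounts for the bidirectional flux counted.
#'
#' @param k_ss Steady-state crossing rate (ns^-1), non-negative.
#' @param area_A Lateral membrane area (nm^2, default 25, a 5 x 5 nm patch).
#' @param concentration_C Solute concentration (mol/cm^3); the default is 20
#'   solute copies in a 5 x 5 x 12 nm box, see [solute_concentration()].
#' @return `P_sim` in cm/s.
#' @examples
#' permeability_from_rate(1, 25, solute_concentration(20, 300))  # 30 cm/s
#' @export
permeability_from_rate <- function(k_ss, area_A = 25,
                                   concentration_C = solute_concentration()) {
  if (any(k_ss < 0)) pc_input_error("k_ss must be non-negative")
  if (area_A <= 0 || concentration_C <= 0)
    pc_input_error("area_A and concentration_C must be positive")
  r <- k_ss * 1e9 / .AVOGADRO            # mol/s
  a_cm2 <- area_A * 1e-14                # nm^2 -> cm^2
  r / (2 * a_cm2 * concentration_C)
}

#' Solute concentration of a simulation box
#'
#' @param n_solutes Number of solute copies (default 20).
#' @param box_volume_nm3 Box volume (nm^3, default 300 = 5 x 5 x 12 nm).
#' @return Concentration in mol/cm^3.
#' @export
solute_concentration <- function(n_solutes = 20, box_volume_nm3 = 300) {
  if (n_solutes <= 0 || box_volume_nm3 <= 0)
    pc_input_error("n_solutes and box_volume_nm3 must be positive")
  n_solutes / .AVOGADRO / (box_volume_nm3 * 1e-21)
}

#' Apparent permeability of a two-membrane barrier
#'
#' A transwell monolayer presents two membranes in series; with fast
#' intracellular transport the measured unidirectional apparent permeability
#' is half the single-bilayer value: `P_app = P_sim / 2`.
#'
#' @param P_sim Single-bilayer permeability (cm/s), non-negative.
#' @return `P_app` in cm/s.
#' @examples
#' apparent_permeability(8.99)
#' @export
apparent_permeability <- function(P_sim) {
  if (any(P_sim < 0)) pc_input_error("P_sim must be non-negative")
  P_sim / 2
}

#' Bundle a steady-state rate into a permeability estimate
#'
#' Convenience constructor combining [steady_state_rate()] output with the
#' geometric and concentration parameters into a single record, propagating
#' the relative rate uncertainty into the permeability.
#'
#' @param ss Output of [steady_state_rate()].
#' @param area_A,concentration_C See [permeability_from_rate()].
#' @param temperature Simulation temperature (K).
#' @param label Compound label.
#' @return Object of class `permeability_estimate` with fields `k_ss`,
#'   `k_sigma` (ns^-1), `molar_rate_r` (mol/s), `area_A` (nm^2),
#'   `concentration_C` (mol/cm^3), `P_sim`, `P_sigma` (cm/s),
#'   `plateau_onset` (ns), `temperature` (K), `label`.
#' @export
permeability_estimate <- function(ss, area_A = 25,
                                  concentration_C = solute_concentration(),
                                  temperature, label = "solute") {
  P_sim <- permeability_from_rate(ss$k_ss, area_A, concentration_C)
  P_sigma <- if (ss$k_ss > 0) P_sim * ss$k_sigma / ss$k_ss else 0
  structure(
    list(k_ss = ss$k_ss, k_sigma = ss$k_sigma,
         molar_rate_r = ss$k_ss * 1e9 / .AVOGADRO,
         area_A = area_A, concentration_C = concentration_C,
         P_sim = P_sim, P_sigma = P_sigma,
         plateau_onset = ss$plateau_onset,
         temperature = temperature, label = label),
    class = "permeability_estimate")
}

#' @export
print.permeability_estimate <- function(x, ...) {
  cat(sprintf(
    paste0("permeability_estimate '%s' (T = %.6g K)\n",
           "  k_ss = %.4g +- %.3g /ns (plateau from %.6g ns)\n",
           "  P_sim = %.4g +- %.3g cm/s;  P_app = P_sim/2 = %.4g cm/s\n"),
    x$label, x$temperature, x$k_ss, x$k_sigma, x$plateau_onset,
    x$P_sim, x$P_sigma, x$P_sim / 2))
  invisible(x)
}

#' Export a permeability estimate as a one-row TSV
#'
#' @param estimate A [permeability_estimate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_estimate_tsv <- function(estimate, path) {
  df <- data.frame(compound = estimate$label, T_K = estimate$temperature,
                   k_ss = estimate$k_ss, k_sigma = estimate$k_sigma,
                   P_sim = estimate$P_sim, P_sigma = estimate$P_sigma)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
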