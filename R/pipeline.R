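#' Configuration for an end-to-end permeability run
#'
#' Validates and freezes every knob of the pipeline so a run is fully
#' reproducible from its logged configuration.
#'
#' @param input Path to a z-series text file ([read_zseries_text()]
#'   dialect) or a trajectory container readable by [load_zseries()].
#' @param topology Optional topology path for container input.
#' @param solute_selector,lipid_selector Selections for container input.
#' @param checkpoint_interval Rate checkpoint spacing (ns, default 10).
#' @param threshold Steady-state `|dk/dt|` threshold (ns^-2, default
#'   0.004).
#' @param min_plateau_checkpoints See [steady_state_rate()].
#' @param crossing_offset Crossing-plane offset (nm, default 1.0).
#' @param area_A Lateral membrane area (nm^2, default 25).
#' @param concentration_C Solute concentration (mol/cm^3); default from
#'   [solute_concentration()].
#' @param calibration `"fit_167C"`/`"fit_127C"` (fit from the packaged
#'   library), or a frozen line: `"167C_full"`, `"127C_full"`, `"eq1"`,
#'   `"eq2"`.
#' @param seed RNG seed recorded with the run.
#' @param output_dir Directory for TSV outputs and the run log.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, topology = NULL, solute_selector = NULL,
                       lipid_selector = NULL, checkpoint_interval = 10,
                       threshold = 0.004, min_plateau_checkpoints = 5,
                       crossing_offset = 1.0, area_A = 25,
                       concentration_C = solute_concentration(),
                       calibration = c("167C_full", "fit_167C", "fit_127C",
                                       "127C_full", "eq1", "eq2"),
                       seed = 1L, output_dir = tempfile("permcount_run_")) {
  calibration <- match.arg(calibration)
  num_ok <- c(checkpoint_interval = checkpoint_interval,
              threshold = threshold, crossing_offset = crossing_offset,
              area_A = area_A, concentration_C = concentration_C,
              min_plateau_checkpoints = min_plateau_checkpoints)
  bad <- names(num_ok)[!is.finite(num_ok) | num_ok <= 0]
  if (length(bad))
    pc_input_error(paste("non-positive config fields:",
                         paste(bad, collapse = ", ")))
  structure(
    list(input = input, topology = topology,
         solute_selector = solute_selector,
         lipid_selector = lipid_selector,
         checkpoint_interval = checkpoint_interval, threshold = threshold,
         min_plateau_checkpoints = min_plateau_checkpoints,
         crossing_offset = crossing_offset, area_A = area_A,
         concentration_C = concentration_C, calibration = calibration,
         seed = as.integer(seed), output_dir = output_dir),
    class = "run_config")
}

# run a stage, tagging any error with the stage name while preserving its
# condition classes (the CLI maps them to exit codes)
.stage <- function(name, expr) {
  tryCatch(expr, permcount_error = function(e) {
    stop(structure(class = class(e),
                   list(message = sprintf("stage '%s': %s", name,
                                          conditionMessage(e)),
                        call = NULL)))
  })
}

#' Run the full counting-to-ranking pipeline on one trajectory
#'
#' Executes load, recentre, membrane-geometry estimation, event detection,
#' running-rate construction, steady-state detection, permeability
#' conversion and 37 C calibration prediction, writing TSV outputs
#' (`events.tsv`, `rates.tsv`, `estimate.tsv`, `prediction.tsv`) and a
#' `run_log.txt` capturing every parameter and seed into
#' `config$output_dir`.
#'
#' @param config A [run_config()].
#' @return Report list (invisibly): `series`, `geometry`, `events`,
#'   `rates`, `estimate` (a [permeability_estimate()]), `P_app_37C`
#'   (predicted cm/s), `calibration` (the model used), `output_dir`.
#' @examples
#' sp <- synthetic_spec(1, 0.5, 0.5, n_solutes = 10, dt = 0.002,
#'                      n_steps = 2e5, record_stride = 10, seed = 3)
#' f <- tempfile(fileext = ".zser")
#' write_zseries_text(simulate_langevin(sp), f)
#' rep <- run_pipeline(run_config(f, min_plateau_checkpoints = 3))
#' rep$estimate$k_ss
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  series <- .stage("load", {
    if (!file.exists(config$input))
      pc_input_error(sprintf("input not found: %s", config$input))
    if (tolower(tools::file_ext(config$input)) %in% c("pdb", "dcd"))
      load_zseries(config$input, config$topology,
                   config$solute_selector, config$lipid_selector)
    else read_zseries_text(config$input)
  })
  geom0 <- .stage("geometry", {
    if (is.null(series$lipid_ref_z))
      pc_input_error("input series carries no lipid reference")
    lip <- series$lipid_ref_z
    mid <- (rowMeans(lip))
    list(midplane = mid)
  })
  series <- .stage("recentre", recentre_and_wrap(series, geom0$midplane))
  geom <- .stage("geometry", estimate_membrane_geometry(
    series, crossing_offset = config$crossing_offset))
  events <- .stage("detect", detect_crossings(series, geom))
  rates <- .stage("rate", rate_series(
    events, checkpoint_interval = config$checkpoint_interval))
  ss <- .stage("steady_state", tryCatch(
    steady_state_rate(rates, config$threshold,
                      config$min_plateau_checkpoints),
    permcount_nonconvergence = function(e) {
      m <- length(rates$dk_dt)
      pc_converge_error(sprintf(
        "%s [trajectory %.6g ns, last dk/dt = %.3g ns^-2]",
        conditionMessage(e), attr(events, "total_time"),
        rates$dk_dt[m]))
    }))
  est <- permeability_estimate(ss, config$area_A, config$concentration_C,
                               temperature = series$temperature,
                               label = series$label)
  model <- .stage("calibrate", switch(
    config$calibration,
    fit_167C = fit_loglog(load_paper_tables(), "167C"),
    fit_127C = fit_loglog(load_paper_tables(), "127C"),
    frozen_calibration(config$calibration)))
  papp37 <- if (est$P_sim > 0) predict_papp(model, est$P_sim) else NA_real_

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$output_dir, f)
  write_events_tsv(events, od("events.tsv"))
  write.table(data.frame(checkpoint_ns = rates$checkpoint_times,
                         cumulative_events = rates$cumulative_events,
                         k_per_ns = rates$k, dk_dt = rates$dk_dt),
              od("rates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_estimate_tsv(est, od("estimate.tsv"))
  write.table(data.frame(compound = est$label, P_sim = est$P_sim,
                         P_app_single_T = est$P_sim / 2,
                         P_app_37C_pred = papp37,
                         calibration = config$calibration,
                         m = model$m, c = model$c),
              od("prediction.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_lines <- c(
    sprintf("permcount run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("input: %s", config$input),
    vapply(setdiff(names(config), c("input")), function(k)
      sprintf("%s: %s", k, paste(format(config[[k]]), collapse = " ")),
      character(1L)),
    sprintf("n_frames: %d; n_solutes: %d; total_ns: %.6g",
            n_frames(series), n_solutes(series),
            attr(events, "total_time")),
    sprintf("events: %d; k_ss: %.6g +- %.3g /ns (plateau %.6g ns)",
            nrow(events), est$k_ss, est$k_sigma, est$plateau_onset),
    sprintf("P_sim: %.6g cm/s; predicted P_app(37C): %.6g cm/s",
            est$P_sim, papp37))
  writeLines(log_lines, od("run_log.txt"))

  invisible(list(series = series, geometry = geom, events = events,
                 rates = rates, estimate = est, P_app_37C = papp37,
                 calibration = model, output_dir = config$output_dir))
}
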