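#' Membrane geometry for transition-based counting
#'
#' The counting rule needs three pieces of geometry in recentred
#' coordinates: the z of the lower and upper leaflet surfaces (headgroup
#' planes) and the offset of the crossing planes beyond them. A translocation
#' event is complete when a solute that was last in bulk on one side is first
#' observed beyond the plane `crossing_offset` nm past the opposite surface.
#'
#' @param lower_boundary,upper_boundary Leaflet surface z (nm); must bracket
#'   zero.
#' @param crossing_offset Distance of the crossing planes beyond the leaflet
#'   surfaces (nm, default 1.0).
#' @return Object of class `membrane_geometry`.
#' @examples
#' membrane_geometry(-2, 2)
#' @export
membrane_geometry <- function(lower_boundary, upper_boundary,
                              crossing_offset = 1.0) {
  if (!(lower_boundary < 0 && upper_boundary > 0))
    pc_stop("leaflet boundaries must bracket z = 0 (recentred coordinates)",
            "permcount_geometry_error")
  if (crossing_offset <= 0)
    pc_stop("crossing_offset must be positive", "permcount_geometry_error")
  structure(
    list(lower_boundary = lower_boundary, upper_boundary = upper_boundary,
         crossing_offset = crossing_offset,
         lower_plane = lower_boundary - crossing_offset,
         upper_plane = upper_boundary + crossing_offset),
    class = "membrane_geometry")
}

#' @export
print.membrane_geometry <- function(x, ...) {
  cat(sprintf(
    "membrane_geometry: surfaces [%.3f, %.3f] nm, crossing planes [%.3f, %.3f] nm\n",
    x$lower_boundary, x$upper_boundary, x$lower_plane, x$upper_plane))
  invisible(x)
}

#' Estimate membrane geometry from the lipid leaflet reference
#'
#' Takes the per-leaflet mean headgroup z stored in a [zseries()] and turns
#' it into a [membrane_geometry()]. In `static` mode (default) the leaflet
#' positions are time-averaged; `per_frame` mode keeps the frame-wise means
#' and additionally returns them as attribute `"per_frame"`. A separation of
#' less than 1 nm between the leaflet means indicates a collapsed or
#' mis-assigned bilayer and is refused.
#'
#' @param series A [zseries()] with `lipid_ref_z` present, recentred.
#' @param mode `"static"` or `"per_frame"`.
#' @param crossing_offset Passed to [membrane_geometry()].
#' @return A [membrane_geometry()].
#' @export
estimate_membrane_geometry <- function(series, mode = c("static", "per_frame"),
                                       crossing_offset = 1.0) {
  stopifnot(inherits(series, "zseries"))
  mode <- match.arg(mode)
  lip <- series$lipid_ref_z
  if (is.null(lip))
    pc_stop("series has no lipid_ref_z; supply membrane_geometry() directly",
            "permcount_geometry_error")
  lo <- mean(lip[, 1L]); up <- mean(lip[, 2L])
  if (up - lo < 1)
    pc_stop(sprintf(
      "degenerate membrane: leaflet means %.3f and %.3f nm are < 1 nm apart",
      lo, up), "permcount_degenerate_membrane")
  geom <- membrane_geometry(lo, up, crossing_offset)
  if (mode == "per_frame") attr(geom, "per_frame") <- lip
  geom
}

# region code per value: 0 = bulk below (z <= lower plane), 1 = membrane
# adjacent, 2 = bulk above (z >= upper plane). Planes are closed: a solute
# exactly on a crossing plane counts as arrived in bulk.
.region_codes <- function(z, geom) {
  r <- matrix(1L, nrow(z), ncol(z))
  r[z <= geom$lower_plane] <- 0L
  r[z >= geom$upper_plane] <- 2L
  r
}

#' Detect complete transbilayer translocation events
#'
#' Implements transition-based counting with a three-region hysteresis rule.
#' Each solute carries a bulk assignment (below / above / none). The
#' assignment changes, and an event is recorded, only when the solute is
#' first observed in the *opposite* bulk region, i.e. at or beyond the
#' crossing plane `crossing_offset` nm past the far leaflet surface.
#' Re-entering the source bulk resets a partial attempt, so boundary
#' recrossings are never double-counted. Frame pairs whose displacement
#' exceeds half the box (periodic jumps, flagged by [recentre_and_wrap()] or
#' recomputed here) transfer the assignment without an event: travelling
#' "around the back" of a periodic box is not a membrane crossing. Solutes
#' that start inside the membrane region remain unassigned until they first
#' reach a bulk region.
#'
#' @param series A recentred [zseries()] (see [recentre_and_wrap()]).
#' @param geom A [membrane_geometry()].
#' @return A data frame of class `crossing_events` with columns
#'   `solute_index`, `start_time` (last time in the source bulk), `end_time`
#'   (first time beyond the far plane), `direction` (`"up"`/`"down"`), and
#'   attribute `"total_time"` (ns).
#' @examples
#' zs <- zseries(0:4, c(-4, -1, 0, 1, 4), box_z = 12, temperature = 440)
#' detect_crossings(zs, membrane_geometry(-2, 2))
#' @export
detect_crossings <- function(series, geom) {
  stopifnot(inherits(series, "zseries"), inherits(geom, "membrane_geometry"))
  if (!series$wrapped)
    pc_input_error("series must be wrapped/recentred before event detection")
  if (!is.null(series$lipid_ref_z)) {
    mid <- mean((series$lipid_ref_z[, 1L] + series$lipid_ref_z[, 2L]) / 2)
    if (abs(mid) > 0.25 * (geom$upper_boundary - geom$lower_boundary))
      pc_input_error(sprintf(
        "series does not look recentred (mean midplane %.3f nm); run recentre_and_wrap()",
        mid))
  }
  z <- series$z
  n <- nrow(z); k <- ncol(z)
  reg <- .region_codes(z, geom)
  jump <- attr(series, "jump")
  if (is.null(jump)) {
    jump <- abs(apply(z, 2L, function(col) c(0, diff(col)))) >
      matrix(series$box_z / 2, n, k)
    dim(jump) <- dim(z)
  }
  out <- vector("list", k)
  for (j in seq_len(k)) {
    r <- reg[, j]; jp <- jump[, j]
    # candidate frames: region changes or flagged jumps; all state updates
    # happen only there because the region is constant in between
    cand <- which(c(TRUE, diff(r) != 0) | jp)
    state <- NA_integer_      # current bulk assignment (0 or 2)
    jumped <- FALSE           # periodic jump since last in source bulk
    last_src <- NA_real_      # last time observed in source bulk
    ev_start <- numeric(0); ev_end <- numeric(0); ev_dir <- character(0)
    for (i in cand) {
      if (jp[i]) jumped <- TRUE
      ri <- r[i]
      # region is constant between candidate frames, so if the previous
      # frame was in the source bulk it is the latest "last seen there"
      if (!is.na(state) && i > 1L && r[i - 1L] == state)
        last_src <- series$times[i - 1L]
      if (ri == 1L) next
      if (is.na(state)) {
        state <- ri; jumped <- FALSE; last_src <- series$times[i]
      } else if (ri == state) {
        jumped <- FALSE; last_src <- series$times[i]  # attempt reset
      } else {
        if (!jumped) {
          ev_start <- c(ev_start, last_src)
          ev_end <- c(ev_end, series$times[i])
          ev_dir <- c(ev_dir, if (ri == 2L) "up" else "down")
        }
        state <- ri; jumped <- FALSE; last_src <- series$times[i]
      }
    }
    out[[j]] <- if (length(ev_end))
      data.frame(solute_index = j, start_time = ev_start,
                 end_time = ev_end, direction = ev_dir,
                 stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(ev))
    ev <- data.frame(solute_index = integer(0), start_time = numeric(0),
                     end_time = numeric(0), direction = character(0),
                     stringsAsFactors = FALSE)
  ev <- ev[order(ev$end_time, ev$solute_index), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("crossing_events", "data.frame")
  attr(ev, "total_time") <- series$times[n] - series$times[1L]
  ev
}

#' Export crossing events as a TSV table
#'
#' @param events A `crossing_events` data frame from [detect_crossings()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(inherits(events, "data.frame"))
  df <- as.data.frame(events)
  names(df) <- c("solute_index", "start_ns", "end_ns", "direction")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Running crossing-rate estimate at regular checkpoints
#'
#' Counts events (regardless of direction: the flux is bidirectional) up to
#' checkpoints placed at multiples of `checkpoint_interval`, and forms the
#' running rate `k(t) = cumulative events / t` together with its finite
#' difference between consecutive checkpoints, the quantity the steady-state
#' criterion of [steady_state_rate()] thresholds.
#'
#' @param events `crossing_events` from [detect_crossings()], or any data
#'   frame with an `end_time` column.
#' @param total_time Trajectory length (ns); defaults to the events'
#'   `total_time` attribute.
#' @param checkpoint_interval Checkpoint spacing (ns, default 10).
#' @return Object of class `rate_series`: a list with `checkpoint_times`
#'   (ns), `cumulative_events`, `k` (ns^-1) and `dk_dt` (ns^-2; `NA` at the
#'   first checkpoint).
#' @examples
#' ev <- data.frame(end_time = cumsum(rep(1, 100)))
#' rate_series(ev, total_time = 100, checkpoint_interval = 10)$k
#' @export
rate_series <- function(events, total_time = attr(events, "total_time"),
                        checkpoint_interval = 10) {
  if (is.null(total_time) || !is.finite(total_time) || total_time <= 0)
    pc_input_error("total_time must be a positive number (ns)")
  if (checkpoint_interval <= 0)
    pc_input_error("checkpoint_interval must be positive (ns)")
  end <- events$end_time
  if (length(end) && max(end) > total_time + 1e-9)
    pc_stop("event end_time beyond total_time", "permcount_inconsistency")
  cp <- seq(checkpoint_interval, total_time, by = checkpoint_interval)
  if (length(cp) == 0L)
    pc_input_error("checkpoint_interval exceeds total_time")
  cum <- vapply(cp, function(t) sum(end <= t + 1e-9), numeric(1L))
  k <- cum / cp
  dk <- c(NA_real_, diff(k) / diff(cp))
  structure(list(checkpoint_times = cp, cumulative_events = cum,
                 k = k, dk_dt = dk),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  m <- length(x$k)
  cat(sprintf(
    "rate_series: %d checkpoints to %.6g ns, %d events, final k = %.6g /ns\n",
    m, x$checkpoint_times[m], x$cumulative_events[m], x$k[m]))
  invisible(x)
}
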