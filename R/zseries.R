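#' z-coordinate time series of membrane-permeant solutes
#'
#' A `zseries` holds everything the counting method needs from a trajectory:
#' the time stamps, one column of z-positions (nm) per solute copy, the
#' per-frame box length along the membrane normal, the simulation
#' temperature, and (optionally) the per-leaflet mean z of the lipid
#' headgroups that defines the membrane surfaces. All lengths are nm, times
#' ns, temperature K; unit conversions happen only at I/O boundaries.
#'
#' @param times Numeric vector of frame times (ns), strictly increasing.
#' @param z Numeric matrix of solute z-positions (nm), one column per solute
#'   copy; a vector is treated as a single column.
#' @param box_z Per-frame box length in z (nm); a scalar is recycled.
#' @param temperature Simulation temperature (K), a positive scalar.
#' @param lipid_ref_z Optional two-column matrix with the per-frame mean
#'   headgroup z of the lower and upper leaflets (nm).
#' @param label Compound name or other identifier.
#' @param wrapped Logical; if `TRUE` (default) every z must lie within
#'   `[-box_z/2, +box_z/2]` for its frame. Set `FALSE` for unwrapped
#'   (free-diffusion) coordinates, e.g. for mean-square-displacement checks.
#'
#' @return An object of class `zseries`: a list with elements `times`, `z`,
#'   `box_z`, `temperature`, `lipid_ref_z`, `label`, `wrapped`.
#' @seealso [read_zseries_text()], [recentre_and_wrap()], [detect_crossings()]
#' @examples
#' zs <- zseries(times = 0:2, z = c(0, 1, 2), box_z = 12, temperature = 440)
#' n_frames(zs)
#' @export
zseries <- function(times, z, box_z, temperature, lipid_ref_z = NULL,
                    label = "solute", wrapped = TRUE) {
  times <- as.numeric(times)
  if (is.null(dim(z))) z <- matrix(as.numeric(z), ncol = 1L)
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  n <- length(times)
  if (n < 1L) pc_input_error("zseries needs at least one frame")
  if (nrow(z) != n)
    pc_input_error("z must have one row per time point")
  if (n > 1L && any(diff(times) <= 0))
    pc_stop("times must be strictly increasing", "permcount_corrupt_input")
  if (length(box_z) == 1L) box_z <- rep(as.numeric(box_z), n)
  if (length(box_z) != n)
    pc_input_error("box_z must be scalar or one value per frame")
  if (any(!is.finite(box_z)) || any(box_z <= 0))
    pc_input_error("box_z must be positive and finite")
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    pc_input_error("temperature must be a positive scalar (K)")
  if (!is.null(lipid_ref_z)) {
    lipid_ref_z <- as.matrix(lipid_ref_z)
    if (nrow(lipid_ref_z) == 1L)
      lipid_ref_z <- lipid_ref_z[rep(1L, n), , drop = FALSE]
    if (nrow(lipid_ref_z) != n || ncol(lipid_ref_z) != 2L)
      pc_input_error("lipid_ref_z must be an n-frame x 2 (lower, upper) matrix")
    colnames(lipid_ref_z) <- c("lower", "upper")
  }
  if (isTRUE(wrapped)) {
    lim <- box_z / 2 + 1e-9
    if (any(abs(z) > lim))
      pc_input_error("wrapped z values must lie within [-box_z/2, +box_z/2]")
  }
  structure(
    list(times = times, z = z, box_z = box_z, temperature = temperature,
         lipid_ref_z = lipid_ref_z, label = as.character(label)[1L],
         wrapped = isTRUE(wrapped)),
    class = "zseries"
  )
}

#' @export
print.zseries <- function(x, ...) {
  cat(sprintf(
    "zseries '%s': %d frames, %d solute(s), %.4g-%.4g ns, T = %.6g K\n",
    x$label, n_frames(x), n_solutes(x), x$times[1L],
    x$times[n_frames(x)], x$temperature))
  cat(sprintf("  box_z: %.6g-%.6g nm; lipid reference: %s; wrapped: %s\n",
              min(x$box_z), max(x$box_z),
              if (is.null(x$lipid_ref_z)) "absent" else "present",
              x$wrapped))
  invisible(x)
}

#' Number of frames / solute copies in a zseries
#' @param series A [zseries()].
#' @return Integer count.
#' @export
n_frames <- function(series) length(series$times)

#' @rdname n_frames
#' @export
n_solutes <- function(series) ncol(series$z)

# wrap values into [-L/2, L/2), vectorised over frames
.wrap_z <- function(z, box_z) {
  ((z + box_z / 2) %% box_z) - box_z / 2
}

#' Recentre a z series on the membrane midplane and wrap into the box
#'
#' Shifts every frame so that the supplied membrane midplane sits at z = 0,
#' wraps all coordinates into `[-box_z/2, +box_z/2)`, and flags frame pairs
#' whose apparent displacement exceeds half the box as periodic jumps. The
#' jump flags (an n-frame x n-solute logical matrix, first row `FALSE`) are
#' attached as attribute `"jump"` and are consumed by [detect_crossings()] to
#' transfer a solute's bulk assignment across the periodic boundary without
#' counting a membrane crossing. The operation is idempotent: recentring an
#' already-centred, wrapped series is a no-op.
#'
#' @param series A [zseries()].
#' @param midplane Membrane midplane z per frame (nm); a scalar is recycled.
#'   Default 0 (series already centred).
#' @return A recentred [zseries()] with attribute `"jump"`.
#' @examples
#' zs <- zseries(0:3, c(5.9, -5.9, -5.5, -5.8), box_z = 12, temperature = 300)
#' attr(recentre_and_wrap(zs), "jump")
#' @export
recentre_and_wrap <- function(series, midplane = 0) {
  stopifnot(inherits(series, "zseries"))
  n <- n_frames(series)
  if (length(midplane) == 1L) midplane <- rep(as.numeric(midplane), n)
  if (length(midplane) != n)
    pc_stop("midplane must be scalar or one value per frame",
            "permcount_geometry_error")
  z <- series$z - midplane
  z <- .wrap_z(z, series$box_z)
  lip <- series$lipid_ref_z
  if (!is.null(lip)) lip <- .wrap_z(lip - midplane, series$box_z)
  out <- zseries(series$times, z, series$box_z, series$temperature,
                 lipid_ref_z = lip, label = series$label, wrapped = TRUE)
  jump <- abs(apply(z, 2L, function(col) c(0, diff(col)))) >
    matrix(series$box_z / 2, n, n_solutes(series))
  dim(jump) <- dim(z)
  attr(out, "jump") <- jump
  out
}

#' Read and write the plain-text z-series interchange format
#'
#' The dialect is a whitespace-separated table preceded by `#`-prefixed
#' header lines. Required header keys: `label`, `temperature_K`,
#' `n_solutes`. Optional key `lipid_ref: yes` announces two leaflet
#' reference columns. Data columns, in order: `time_ns`, `box_z_nm`,
#' (`lipid_lower_nm`, `lipid_upper_nm` when present,) then one z column per
#' solute. `write_zseries_text()` followed by `read_zseries_text()` is the
#' identity on all fields at the written precision (17 significant digits,
#' i.e. bit-level for doubles).
#'
#' @param path File path.
#' @param series A [zseries()].
#' @param digits Significant digits written (default 17, lossless for
#'   doubles).
#' @return `read_zseries_text()` returns a [zseries()];
#'   `write_zseries_text()` returns `path` invisibly.
#' @examples
#' zs <- zseries(0:2, c(0, 1, 2), box_z = 12, temperature = 440, label = "eth")
#' f <- tempfile(fileext = ".zser")
#' write_zseries_text(zs, f)
#' read_zseries_text(f)
#' @export
read_zseries_text <- function(path) {
  if (!file.exists(path)) pc_input_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*\\S)\\s*$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3L) m[2L] else NA_character_,
                 character(1L))
  vals <- vapply(kv, function(m) if (length(m) == 3L) m[3L] else NA_character_,
                 character(1L))
  getkey <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) pc_stop(sprintf("z-series header is missing key '%s'", k),
                          "permcount_dialect_error")
    vals[i]
  }
  label <- getkey("label")
  temperature <- as.numeric(getkey("temperature_K"))
  k <- as.integer(getkey("n_solutes"))
  has_lip <- !is.na(match("lipid_ref", keys)) &&
    tolower(vals[match("lipid_ref", keys)]) %in% c("yes", "true")
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L)
    pc_stop("z-series file contains no data rows", "permcount_dialect_error")
  fields <- strsplit(trimws(body), "\\s+")
  ncols <- lengths(fields)
  expect <- 2L + (if (has_lip) 2L else 0L) + k
  if (any(ncols != expect))
    pc_stop(sprintf("ragged z-series rows: expected %d columns, found %s",
                    expect, paste(unique(ncols), collapse = "/")),
            "permcount_dialect_error")
  m <- matrix(as.numeric(unlist(fields)), nrow = length(body),
              ncol = expect, byrow = TRUE)
  if (anyNA(m))
    pc_stop("non-numeric value in z-series data", "permcount_dialect_error")
  lip <- if (has_lip) m[, 3:4, drop = FALSE] else NULL
  zcols <- (expect - k + 1L):expect
  zseries(times = m[, 1L], z = m[, zcols, drop = FALSE], box_z = m[, 2L],
          temperature = temperature, lipid_ref_z = lip, label = label)
}

#' @rdname read_zseries_text
#' @export
write_zseries_text <- function(series, path, digits = 17) {
  stopifnot(inherits(series, "zseries"))
  has_lip <- !is.null(series$lipid_ref_z)
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  hdr <- c(
    "# permcount z-series v1",
    sprintf("# label: %s", series$label),
    sprintf("# temperature_K: %s", fmt(series$temperature)),
    sprintf("# n_solutes: %d", n_solutes(series)),
    sprintf("# lipid_ref: %s", if (has_lip) "yes" else "no"),
    paste("# columns: time_ns box_z_nm",
          if (has_lip) "lipid_lower_nm lipid_upper_nm" else "",
          paste0("z", seq_len(n_solutes(series)), collapse = " "))
  )
  body <- cbind(series$times, series$box_z,
                if (has_lip) series$lipid_ref_z, series$z)
  rows <- apply(matrix(fmt(body), nrow = nrow(body)), 1L, paste,
                collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
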