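#' Load a z series from a trajectory container
#'
#' Adapter around the bio3d readers for standard structural-biology
#' containers: a multi-model PDB (topology and coordinates in one text file)
#' or a DCD trajectory plus a PDB topology. Only the z coordinate is
#' extracted. Each selected solute residue becomes one solute copy whose
#' position is the mass-weighted centre of the selected atoms (falling back
#' to the geometric centre when element masses cannot be assigned). The
#' lipid selection is split into leaflets by the sign of z relative to the
#' overall lipid mean in each frame, and the per-leaflet mean z is stored as
#' the membrane surface reference.
#'
#' Coordinates are converted from Angstrom to nm and frame times from the
#' recording interval `dt_ps` to ns. The core pipeline does not require this
#' adapter: the plain-text dialect of [read_zseries_text()] is the package's
#' interchange format.
#'
#' @param path Trajectory file: `.pdb` (multi-model) or `.dcd`.
#' @param topology PDB topology file; required for DCD input, ignored for
#'   PDB input.
#' @param solute_selector,lipid_selector Atom selections: either a list of
#'   arguments for `bio3d::atom.select()` (e.g. `list(resid = "ETH")`) or an
#'   integer vector of atom indices. The lipid selector is optional.
#' @param stride Keep every `stride`-th frame (default 1). With `n` frames
#'   on file, `ceiling(n / stride)` frames are returned.
#' @param dt_ps Recording interval between stored frames (ps/frame,
#'   default 1).
#' @param temperature Simulation temperature (K).
#' @param box_z Box length along z (nm); when `NULL`, taken from the PDB
#'   CRYST1 record.
#' @param label Compound label; defaults to the file name.
#' @return A [zseries()].
#' @export
load_zseries <- function(path, topology = NULL,
                         solute_selector, lipid_selector = NULL,
                         stride = 1L, dt_ps = 1, temperature = 310,
                         box_z = NULL, label = NULL) {
  if (!file.exists(path)) pc_input_error(sprintf("no such file: %s", path))
  if (!requireNamespace("bio3d", quietly = TRUE))
    pc_input_error("the bio3d package is required to read trajectory containers")
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("pdb", "dcd"))
    pc_stop(sprintf(
      "unsupported trajectory format '.%s' (supported: .pdb multi-model, .dcd + PDB topology)",
      ext), "permcount_format_error")
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
  } else {
    if (is.null(topology))
      pc_input_error("a PDB topology is required to read a DCD trajectory")
    pdb <- bio3d::read.pdb(topology)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nfr_all <- nrow(xyz)
  keep <- seq(1L, nfr_all, by = as.integer(stride))
  xyz <- xyz[keep, , drop = FALSE]
  nfr <- nrow(xyz)

  if (is.null(box_z)) {
    # bio3d does not expose CRYST1; take the c axis from the record itself
    src <- if (ext == "pdb") path else topology
    head_lines <- readLines(src, n = 200L, warn = FALSE)
    cry <- grep("^CRYST1", head_lines, value = TRUE)
    c_axis <- if (length(cry))
      suppressWarnings(as.numeric(substr(cry[1L], 25L, 33L))) else NA_real_
    if (!is.finite(c_axis) || c_axis <= 0)
      pc_input_error("box_z not given and no CRYST1 record in the topology")
    box_z <- c_axis / 10
  }

  sel_idx <- function(sel, what) {
    if (is.numeric(sel)) {
      idx <- as.integer(sel)
    } else if (is.list(sel)) {
      idx <- do.call(bio3d::atom.select,
                     c(list(pdb), sel, list(verbose = FALSE)))$atom
    } else {
      pc_input_error(sprintf("%s selector must be a list or atom indices", what))
    }
    if (length(idx) == 0L)
      pc_stop(sprintf("%s selection matches no atoms", what),
              "permcount_selection_error")
    idx
  }

  z_of <- function(idx) xyz[, 3L * idx, drop = FALSE] / 10  # Angstrom -> nm

  sol_idx <- sel_idx(solute_selector, "solute")
  atoms <- pdb$atom[sol_idx, , drop = FALSE]
  copy_id <- paste(atoms$chain, atoms$resno, sep = "_")
  masses <- tryCatch(bio3d::atom2mass(atoms$elety),
                     error = function(e) rep(1, length(sol_idx)),
                     warning = function(w) rep(1, length(sol_idx)))
  zsol_atoms <- z_of(sol_idx)
  copies <- unique(copy_id)
  zsol <- vapply(copies, function(cp) {
    cols <- which(copy_id == cp)
    w <- masses[cols] / sum(masses[cols])
    as.numeric(zsol_atoms[, cols, drop = FALSE] %*% w)
  }, numeric(nfr))
  if (is.null(dim(zsol))) zsol <- matrix(zsol, nrow = nfr)

  lip <- NULL
  if (!is.null(lipid_selector)) {
    lip_idx <- sel_idx(lipid_selector, "lipid")
    zl <- z_of(lip_idx)
    lip <- t(apply(zl, 1L, function(row) {
      lower <- row < mean(row)
      if (all(lower) || !any(lower))
        return(c(NA_real_, NA_real_))
      c(mean(row[lower]), mean(row[!lower]))
    }))
    if (anyNA(lip))
      pc_stop("could not assign lipid atoms to two leaflets",
              "permcount_geometry_error")
  }

  zseries(times = (keep - 1L) * dt_ps / 1000, z = zsol, box_z = box_z,
          temperature = temperature, lipid_ref_z = lip,
          label = if (is.null(label)) basename(path) else label,
          wrapped = FALSE)
}
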