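# Frozen MD5 checksums of the packaged fixture tables; loading verifies
# them so silent fixture corruption surfaces as an integrity error.
.FIXTURE_MD5 <- c(
  "table1_kinetics.csv"    = "1e8c74bf33f82027cdf167711564993c",
  "table2_predictions.csv" = "62a6ac09aefee657251d1b563fb59f1c",
  "table3_reference.csv"   = "96b0c532de1bb9776c99225aecd76250"
)

.fixture_path <- function(file, verify = TRUE) {
  path <- system.file("extdata", file, package = "permcount")
  if (path == "" || !file.exists(path))
    pc_stop(sprintf("packaged fixture %s not found", file),
            "permcount_integrity_error")
  if (verify) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(.FIXTURE_MD5[file])))
      pc_stop(sprintf("fixture %s fails its checksum (%s)", file, md5),
              "permcount_integrity_error")
  }
  path
}

#' Load the packaged compound reference tables
#'
#' Joins the packaged kinetics table (crossing rates and simulated
#' permeabilities of the 18-compound CNS library at 127 C and 167 C, with
#' 1-sigma uncertainties) with the experimental reference table
#' (transwell/PAMPA apparent permeabilities with literature provenance, the
#' published rounded-line prediction, and a provenance-only Arrhenius
#' extrapolation column). Thirteen compounds carry converged 127 C values;
#' the remaining five are `NA` there. File checksums are verified on load.
#'
#' @param verify Verify fixture checksums (default `TRUE`).
#' @return Data frame with one row per compound: `index`, `compound`,
#'   `k_127C`, `k_sigma_127C`, `k_167C`, `k_sigma_167C`, `P_sim_127C`,
#'   `P_sim_sigma_127C`, `P_sim_167C`, `P_sim_sigma_167C` (ns^-1 / cm/s),
#'   `P_app_exp` (cm/s), `reference`, `eq1_prediction`, `arrhenius_37C`
#'   (cm/s, provenance only), `oom_error_printed`.
#' @examples
#' recs <- load_paper_tables()
#' nrow(recs)
#' sum(is.na(recs$P_sim_127C))
#' @export
load_paper_tables <- function(verify = TRUE) {
  t1 <- read.csv(.fixture_path("table1_kinetics.csv", verify),
                 comment.char = "#", stringsAsFactors = FALSE)
  t3 <- read.csv(.fixture_path("table3_reference.csv", verify),
                 comment.char = "#", stringsAsFactors = FALSE)
  out <- merge(t1, t3, by = "compound", sort = FALSE)
  out <- out[order(out$index), ]
  rownames(out) <- NULL
  if (nrow(out) != 18L)
    pc_stop(sprintf("expected 18 compounds, found %d", nrow(out)),
            "permcount_integrity_error")
  out
}

#' Load the packaged prediction benchmark table
#'
#' The published per-compound prediction benchmark: training rows (nine per
#' simulation temperature) with the simulated-permeability inputs,
#' experimental values, published predictions and published
#' order-of-magnitude errors, plus four provenance-only validation rows
#' whose simulated inputs are not public. Training rows are recomputable
#' with [frozen_calibration()] + [predict_papp()]; validation rows are not.
#'
#' @param verify Verify the fixture checksum (default `TRUE`).
#' @return Data frame with columns `dataset` (`training_167C`,
#'   `training_127C`, `validation`), `compound`, `P_sim_input`,
#'   `P_app_exp`, `prediction_printed`, `oom_error_printed`.
#' @examples
#' b <- load_benchmark_predictions()
#' table(b$dataset)
#' @export
load_benchmark_predictions <- function(verify = TRUE) {
  read.csv(.fixture_path("table2_predictions.csv", verify),
           comment.char = "#", stringsAsFactors = FALSE)
}
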