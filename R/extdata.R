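#' Load a bundled reference summary table
#'
#' The package ships, as plain CSV under `extdata`, the published summary
#' tables of the ISSR survey of *Metarhizium rileyi* from Yunnan corn fields
#' that this pipeline re-implements (the raw band matrix and larval survival
#' records were not published):
#' \describe{
#'   \item{`primer_band_counts`}{amplified and polymorphic band counts for
#'     the 7 ISSR primers (54 bands, 51 polymorphic).}
#'   \item{`diversity_partition`}{across-locus mean and SD of total (HT) and
#'     within-population (HS) gene diversity, with the reported GST and Nm.}
#'   \item{`population_identity_distance`}{Nei genetic identity and distance
#'     for all 28 pairs of the 8 analyzable geographic populations.}
#'   \item{`virulence_summary`}{per-strain probit regression coefficients
#'     (a, b), correlation r, mean final mortality and mycosis percentages
#'     with standard errors over 3 replicates of 30 larvae, and the reported
#'     LT50 (NA where mortality stayed below 50\%).}
#' }
#' These serve as worked-example inputs and consistency anchors for the
#' statistics the package computes.
#'
#' @param name table name, see above.
#' @return data.frame.
#' @export
reference_table <- function(name = c("primer_band_counts",
                                     "diversity_partition",
                                     "population_identity_distance",
                                     "virulence_summary")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "issrpop",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
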