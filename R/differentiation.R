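#' Total and within-population gene diversity at one locus
#'
#' For a biallelic dominant locus with band-allele frequency p_k in each of K
#' populations: the total diversity HT is the expected heterozygosity at the
#' unweighted mean frequency, HT = 1 - (pbar^2 + qbar^2), and the
#' subpopulation diversity HS is the unweighted mean of the per-population
#' heterozygosities 1 - p_k^2 - q_k^2.
#'
#' @param p numeric vector of per-population band-allele frequencies
#'   (length >= 2).
#' @return named list with `HT` and `HS`.
#' @export
ht_hs_per_locus <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  if (length(p) < 2L)
    stop("need frequencies from at least 2 populations", call. = FALSE)
  pbar <- mean(p)
  list(HT = 2 * pbar * (1 - pbar), HS = mean(2 * p * (1 - p)))
}

#' Coefficient of genetic differentiation
#'
#' GST = (HT - HS)/HT, the among-population share of the total gene
#' diversity. Undefined for a monomorphic locus (HT = 0).
#'
#' @param HT total gene diversity (> 0).
#' @param HS mean within-population gene diversity.
#' @return GST, clipped into `[0, 1]` against floating-point round-off.
#' @export
gst <- function(HT, HS) {
  stopifnot(is.numeric(HT), is.numeric(HS))
  if (HT <= 0)
    stop("GST undefined: locus monomorphic (HT = 0)", call. = FALSE)
  min(max((HT - HS) / HT, 0), 1)
}

#' Gene flow from the differentiation coefficient
#'
#' Nm = c (1 - GST)/GST, the effective number of migrants per generation at
#' drift-migration equilibrium. The coefficient c is 0.5 for haploid data and
#' 0.25 for diploid biparental data. Nm < 1 is conventionally read as limited
#' gene exchange between populations.
#'
#' @param GST differentiation coefficient in `(0, 1]`.
#' @param coefficient 0.5 (haploid, default) or 0.25 (diploid).
#' @return list with `Nm`, `coefficient`, `limited_exchange` (Nm < 1).
#' @export
gene_flow <- function(GST, coefficient = 0.5) {
  stopifnot(coefficient %in% c(0.5, 0.25))
  if (GST <= 0)
    stop("Nm infinite: GST = 0 (no differentiation)", call. = FALSE)
  if (GST > 1) stop("GST must lie in (0, 1]", call. = FALSE)
  nm <- coefficient * (1 - GST) / GST
  list(Nm = nm, coefficient = coefficient, limited_exchange = nm < 1)
}

#' Gene-diversity partition across populations
#'
#' Computes per-locus HT and HS over all loci polymorphic in the pooled
#' collection, their across-locus means and standard deviations, the overall
#' GST = (mean HT - mean HS)/mean HT, the gene flow Nm, and the variance
#' partition (percent among = 100 GST, percent within = 100 (1 - GST)).
#' Population frequencies enter unweighted, matching the convention of
#' classical dominant-marker surveys with unequal group sizes.
#'
#' @param m a [band_matrix].
#' @param mode allele-frequency mode, see [estimate_allele_frequency()].
#' @param min_n minimum isolates for a population to enter.
#' @param nm_coefficient 0.5 (haploid) or 0.25 (diploid).
#' @return list of class `differentiation_summary`: `per_locus` data.frame
#'   (`locus`, `HT`, `HS`, `GST`), `mean_HT`, `mean_HS`, `sd_HT`, `sd_HS`,
#'   `GST`, `Nm`, `nm_coefficient`, `percent_among`, `percent_within`,
#'   `n_populations`, `n_loci_used`.
#' @export
differentiation_summary <- function(m, mode = c("haploid", "dominant-diploid"),
                                    min_n = 2L, nm_coefficient = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "band_matrix"))
  part <- partition_populations(m, min_n)
  keep <- part$population[part$analyzable]
  if (length(keep) < 2L)
    stop("need at least 2 analyzable populations", call. = FALSE)
  idx <- attr(part, "indices")
  freqs <- sapply(keep, function(g)
    locus_frequencies(m$values[idx[[g]], , drop = FALSE], mode))
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1L)  # single locus
  # freqs: loci x populations
  per <- t(apply(freqs, 1L, function(p) unlist(ht_hs_per_locus(p))))
  use <- per[, "HT"] > 0
  if (!any(use))
    stop("all loci monomorphic across populations: differentiation undefined",
         call. = FALSE)
  per_locus <- data.frame(locus = colnames(m$values)[use],
                          HT = per[use, "HT"], HS = per[use, "HS"],
                          row.names = NULL)
  per_locus$GST <- (per_locus$HT - per_locus$HS) / per_locus$HT
  mean_HT <- mean(per_locus$HT)
  mean_HS <- mean(per_locus$HS)
  G <- gst(mean_HT, mean_HS)
  Nm <- if (G > 0) gene_flow(G, nm_coefficient)$Nm else Inf
  structure(list(per_locus = per_locus,
                 mean_HT = mean_HT, mean_HS = mean_HS,
                 sd_HT = stats::sd(per_locus$HT), sd_HS = stats::sd(per_locus$HS),
                 GST = G, Nm = Nm, nm_coefficient = nm_coefficient,
                 percent_among = 100 * G, percent_within = 100 - 100 * G,
                 n_populations = length(keep), n_loci_used = nrow(per_locus)),
            class = "differentiation_summary")
}

#' @export
print.differentiation_summary <- function(x, ...) {
  cat(sprintf(paste0("Gene-diversity partition over %d loci, %d populations\n",
                     "  mean HT = %.4f (SD %.4f), mean HS = %.4f (SD %.4f)\n",
                     "  GST = %.4f  Nm = %.4f (c = %.2f)\n",
                     "  variation among groups %.2f%%, within groups %.2f%%\n"),
              x$n_loci_used, x$n_populations, x$mean_HT, x$sd_HT, x$mean_HS,
              x$sd_HS, x$GST, x$Nm, x$nm_coefficient, x$percent_among,
              x$percent_within))
  invisible(x)
}
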