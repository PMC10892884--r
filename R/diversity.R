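#' Band-allele frequency at a dominant locus
#'
#' For haploid clonal organisms the band frequency is the allele frequency, so
#' `mode = "haploid"` estimates p as the proportion of band-present isolates
#' among those scored. For diploid outcrossers a dominant band hides the
#' heterozygote, and `mode = "dominant-diploid"` uses the null-homozygote
#' square-root estimator under Hardy-Weinberg: q = sqrt(freq of band-absent
#' phenotype), p = 1 - q.
#'
#' @param band_column vector of 0/1/`NA` scores for one locus.
#' @param mode `"haploid"` (default) or `"dominant-diploid"`.
#' @return list of class `allele_frequency`: `p`, `q`, `n_obs`, `mode`.
#' @export
estimate_allele_frequency <- function(band_column,
                                      mode = c("haploid", "dominant-diploid")) {
  mode <- match.arg(mode)
  x <- band_column[!is.na(band_column)]
  n <- length(x)
  if (n == 0L)
    stop("cannot estimate allele frequency: all values missing", call. = FALSE)
  if (!all(x %in% c(0, 1)))
    stop("band scores must be 0, 1 or NA", call. = FALSE)
  p <- if (mode == "haploid") sum(x == 1) / n else 1 - sqrt(sum(x == 0) / n)
  structure(list(p = p, q = 1 - p, n_obs = n, mode = mode),
            class = "allele_frequency")
}

#' Per-locus diversity statistics for a biallelic locus
#'
#' Given the band-allele frequency p (absence allele q = 1 - p) returns the
#' observed allele number Na, effective allele number Ne = 1/(p^2 + q^2),
#' Nei's gene diversity He = 1 - (p^2 + q^2), and the Shannon information
#' index Is = -(p ln p + q ln q) with 0 ln 0 = 0. A locus is polymorphic when
#' both states are observed (0 < p < 1).
#'
#' @param f an `allele_frequency`, or a bare frequency in `[0, 1]`.
#' @return list of class `locus_diversity`: `Na`, `Ne`, `He`, `Is`,
#'   `polymorphic`.
#' @export
locus_diversity <- function(f) {
  p <- if (inherits(f, "allele_frequency")) f$p else f
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  q <- 1 - p
  hom <- p^2 + q^2
  xlogx <- function(z) ifelse(z > 0, z * log(z), 0)
  structure(list(Na = sum(c(p, q) > 0),
                 Ne = 1 / hom,
                 He = 1 - hom,
                 Is = -(xlogx(p) + xlogx(q)),
                 polymorphic = p > 0 && p < 1),
            class = "locus_diversity")
}

locus_frequencies <- function(values, mode) {
  apply(values, 2L, function(col) estimate_allele_frequency(col, mode)$p)
}

diversity_row <- function(p) {
  q <- 1 - p
  hom <- p^2 + q^2
  xlogx <- function(z) ifelse(z > 0, z * log(z), 0)
  data.frame(Na = mean((p > 0) + (q > 0)),
             Ne = mean(1 / hom),
             He = mean(1 - hom),
             Is = mean(-(xlogx(p) + xlogx(q))),
             P_percent = 100 * mean(p > 0 & p < 1),
             n_loci = length(p))
}

#' Diversity summary over loci, per population or pooled
#'
#' Unweighted means over loci of Na, Ne, He, Is, plus the percentage of
#' polymorphic loci. With `scope = "population"` one row per analyzable group
#' (size >= `min_n`) is returned; singleton groups are excluded because their
#' within-group diversity is not estimable. `scope = "pooled"` treats the
#' whole collection as one population.
#'
#' @param m a [band_matrix].
#' @param scope `"population"` or `"pooled"`.
#' @param mode allele-frequency mode, see [estimate_allele_frequency()].
#' @param min_n minimum group size for per-population rows.
#' @return data.frame with columns `group`, `n`, `Na`, `Ne`, `He`, `Is`,
#'   `P_percent`, `n_loci`.
#' @export
diversity_summary <- function(m, scope = c("population", "pooled"),
                              mode = c("haploid", "dominant-diploid"),
                              min_n = 2L) {
  scope <- match.arg(scope)
  mode <- match.arg(mode)
  stopifnot(inherits(m, "band_matrix"))
  if (scope == "pooled") {
    row <- diversity_row(locus_frequencies(m$values, mode))
    return(cbind(data.frame(group = "pooled", n = nrow(m$values)), row))
  }
  part <- partition_populations(m, min_n)
  keep <- part$population[part$analyzable]
  if (length(keep) == 0L)
    stop("no analyzable population (all groups are singletons)", call. = FALSE)
  idx <- attr(part, "indices")
  rows <- lapply(keep, function(g) {
    p <- locus_frequencies(m$values[idx[[g]], , drop = FALSE], mode)
    cbind(data.frame(group = g, n = length(idx[[g]])), diversity_row(p))
  })
  do.call(rbind, rows)
}

#' Per-primer band and polymorphism counts
#'
#' Locus IDs of the form `<primer>_<k>` are grouped by primer; the table
#' counts amplified bands, polymorphic bands (both states observed in the
#' pooled collection) and their percentage, with a totals row.
#'
#' @param m a [band_matrix].
#' @param mode allele-frequency mode.
#' @return data.frame with columns `primer`, `bands`, `polymorphic`,
#'   `percent`; last row `Total`.
#' @export
per_primer_polymorphism <- function(m, mode = c("haploid", "dominant-diploid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "band_matrix"))
  p <- locus_frequencies(m$values, mode)
  poly <- p > 0 & p < 1
  ids <- colnames(m$values)
  primer <- ifelse(grepl("_", ids), sub("_[^_]*$", "", ids), "unknown")
  per <- lapply(split(poly, primer), function(v)
    data.frame(bands = length(v), polymorphic = sum(v)))
  out <- do.call(rbind, per)
  out <- data.frame(primer = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(primer = "Total", bands = sum(out$bands),
                               polymorphic = sum(out$polymorphic)))
  out$percent <- 100 * out$polymorphic / out$bands
  out
}
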