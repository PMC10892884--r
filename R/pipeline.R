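#' Run the full marker + bioassay analysis pipeline
#'
#' Drives every analysis stage over the given inputs and writes a report
#' bundle: per-primer polymorphism and diversity tables, the gene-diversity
#' partition (HT, HS, GST, Nm, variance percentages), Nei identity/distance
#' matrices, UPGMA Newick trees at population and individual level, a
#' bioassay table (regression coefficients, r, mortality and mycosis with
#' standard errors, probit and Kaplan-Meier LT50), and a run log recording
#' all options. Stages for absent inputs are skipped.
#'
#' @param marker either a [band_matrix] or a path to a band-matrix file.
#' @param bioassay either [bioassay_records] or a path to a bioassay CSV;
#'   `NULL` to skip the virulence stage.
#' @param out_dir output directory (created if needed).
#' @param mode allele-frequency mode.
#' @param nm_coefficient 0.5 or 0.25.
#' @param similarity individual-level similarity coefficient.
#' @param min_n minimum population size for subpopulation statistics.
#' @return invisibly, a named list of the objects written.
#' @export
run_full_pipeline <- function(marker = NULL, bioassay = NULL, out_dir,
                              mode = c("haploid", "dominant-diploid"),
                              nm_coefficient = 0.5,
                              similarity = c("dice", "jaccard",
                                             "simple-matching"),
                              min_n = 2L) {
  mode <- match.arg(mode)
  similarity <- match.arg(similarity)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  log_lines <- c(sprintf("mode=%s nm_coefficient=%s similarity=%s min_n=%d",
                         mode, format(nm_coefficient), similarity, min_n))
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (!is.null(marker)) {
    m <- if (inherits(marker, "band_matrix")) marker else
      read_band_matrix(marker)
    log_lines <- c(log_lines,
                   sprintf("markers: %d isolates, %d loci", nrow(m$values),
                           ncol(m$values)))
    results$primer_polymorphism <- per_primer_polymorphism(m, mode)
    wtsv(results$primer_polymorphism, "primer_polymorphism.tsv")

    div_pop <- diversity_summary(m, "population", mode, min_n)
    div_all <- diversity_summary(m, "pooled", mode)
    results$diversity <- rbind(div_pop, div_all)
    wtsv(results$diversity, "diversity.tsv")

    ds <- differentiation_summary(m, mode, min_n, nm_coefficient)
    results$differentiation <- ds
    diff_tab <- data.frame(
      statistic = c("mean_HT", "sd_HT", "mean_HS", "sd_HS", "GST", "Nm",
                    "percent_among", "percent_within"),
      value = c(ds$mean_HT, ds$sd_HT, ds$mean_HS, ds$sd_HS, ds$GST, ds$Nm,
                ds$percent_among, ds$percent_within))
    wtsv(diff_tab, "differentiation.tsv")

    idm <- identity_distance_matrix(m, mode, min_n)
    results$identity_distance <- idm
    # Table-7 layout: identity above the diagonal, distance below
    comb <- idm$distance
    comb[upper.tri(comb)] <- idm$identity[upper.tri(comb)]
    diag(comb) <- NA
    utils::write.csv(round(comb, 4), file.path(out_dir,
                                               "identity_distance.csv"),
                     na = "")
    pop_tree <- upgma(idm$distance)
    results$population_tree <- pop_tree
    writeLines(to_newick(pop_tree), file.path(out_dir, "population_upgma.nwk"))

    sim <- individual_similarity(m, similarity)
    results$individual_similarity <- sim
    utils::write.csv(round(sim, 4), file.path(out_dir,
                                              "individual_similarity.csv"))
    ind_tree <- upgma(1 - sim)
    results$individual_tree <- ind_tree
    writeLines(to_newick(ind_tree), file.path(out_dir, "individual_upgma.nwk"))
  }

  if (!is.null(bioassay)) {
    rec <- if (inherits(bioassay, "bioassay_records")) bioassay else
      read_bioassay(bioassay)
    log_lines <- c(log_lines,
                   sprintf("bioassay: %d strains", length(unique(rec$strain))))
    results$bioassay <- bioassay_table(rec)
    wtsv(results$bioassay, "bioassay.tsv")
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

#' Per-strain virulence summary table
#'
#' One row per strain: probit regression equation (intercept a, slope b,
#' correlation r), mean final mortality and mycosis percentages with
#' standard errors across replicates, the probit LT50 and the Kaplan-Meier
#' median lethal time. LT50 entries are NA where mortality never reached 50%.
#'
#' @param records [bioassay_records] for any number of strains.
#' @return data.frame, one row per strain.
#' @export
bioassay_table <- function(records) {
  strains <- unique(records$strain)
  rows <- lapply(strains, function(s) {
    rec <- records[records$strain == s, , drop = FALSE]
    ms <- mortality_summary(rec)
    pm <- pooled_mortality(rec)
    fit <- tryCatch(fit_probit(pm$day, pm$mortality),
                    error = function(e) NULL)
    km <- kaplan_meier(rec)
    data.frame(strain = s,
               a = if (is.null(fit)) NA_real_ else fit$a,
               b = if (is.null(fit)) NA_real_ else fit$b,
               r = if (is.null(fit)) NA_real_ else fit$r,
               mortality = ms$mortality_mean, mortality_se = ms$mortality_se,
               mycosis = ms$mycosis_mean, mycosis_se = ms$mycosis_se,
               lt50_probit = if (is.null(fit)) NA_real_ else fit$LT50,
               lt50_km = km$median)
  })
  do.call(rbind, rows)
}
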