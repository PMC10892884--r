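#' Configuration for the F-model marker simulator
#'
#' The F-model draws, for each locus, an ancestral band-allele frequency
#' p-bar, then per-population frequencies
#' p_k ~ Beta(p-bar (1-F)/F, (1-p-bar)(1-F)/F), whose expected
#' among-population differentiation equals F; isolate band scores are
#' Bernoulli(p_k). This directly parameterizes the quantity (GST) the
#' pipeline estimates, so simulated data make parameter-recovery checks
#' possible.
#'
#' @param sizes integer vector of per-population sample sizes; names become
#'   population labels (default `pop1..popK`).
#' @param n_loci number of dominant loci.
#' @param F differentiation parameter in (0, 1).
#' @param ancestral range `c(lo, hi)` of the uniform ancestral-frequency
#'   distribution; draws are clamped to `[0.05, 0.95]` to avoid degenerate
#'   beta shapes.
#' @param locus_primers optional character vector (length `n_loci`) of primer
#'   tags; locus IDs become `<primer>_<k>`.
#' @param seed mandatory integer seed.
#' @return list of class `marker_sim_config`.
#' @export
marker_sim_config <- function(sizes, n_loci, F = 0.35,
                              ancestral = c(0.1, 0.9), locus_primers = NULL,
                              seed) {
  stopifnot(F > 0, F < 1, all(sizes >= 1), n_loci >= 1,
            length(ancestral) == 2L, ancestral[1] <= ancestral[2])
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(names(sizes))) names(sizes) <- paste0("pop", seq_along(sizes))
  if (!is.null(locus_primers)) stopifnot(length(locus_primers) == n_loci)
  structure(list(sizes = sizes, n_loci = n_loci, F = F, ancestral = ancestral,
                 locus_primers = locus_primers, seed = as.integer(seed)),
            class = "marker_sim_config")
}

#' Study-shaped marker simulation preset
#'
#' Mirrors the collection analysed in the package vignette: 8 multi-isolate
#' geographic groups with sizes 3, 8, 2, 2, 3, 2, 3, 3 plus 5 singleton
#' groups (31 isolates in total) and 54 dominant loci from 7 ISSR primers
#' (808: 7, 866: 7, 891: 10, M11: 8, M12: 8, P12: 5, P25: 9 bands). The
#' default differentiation F = 0.35 matches the level of among-population
#' structure the pipeline is meant to detect.
#'
#' @param F differentiation parameter.
#' @param seed mandatory integer seed.
#' @return a [marker_sim_config].
#' @export
study_marker_config <- function(F = 0.35, seed) {
  sizes <- c(Kunming = 3, Qujing = 8, Lincang = 2, Puer = 2, Baoshan = 3,
             Honghe = 2, Xishuangbanna = 3, Dali = 3,
             Dehong = 1, Yuxi = 1, Chuxiong = 1, Zhaotong = 1, Wenshan = 1)
  primers <- rep(c("808", "866", "891", "M11", "M12", "P12", "P25"),
                 times = c(7, 7, 10, 8, 8, 5, 9))
  marker_sim_config(sizes = sizes, n_loci = 54L, F = F,
                    locus_primers = primers, seed = seed)
}

#' Simulate a band-presence matrix under the F-model
#'
#' @param cfg a [marker_sim_config].
#' @return a [band_matrix], bit-for-bit reproducible for a fixed seed, with
#'   attributes `true_freq` (loci x populations matrix of the simulated
#'   per-population frequencies) and `ancestral_freq` carrying the simulation
#'   truth for parameter-recovery checks.
#' @export
simulate_marker_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "marker_sim_config"))
  set.seed(cfg$seed)
  K <- length(cfg$sizes)
  L <- cfg$n_loci
  F <- cfg$F
  pbar <- stats::runif(L, cfg$ancestral[1], cfg$ancestral[2])
  pbar <- pmin(pmax(pbar, 0.05), 0.95)
  pk <- matrix(0, L, K)  # loci x populations
  for (l in seq_len(L))
    pk[l, ] <- stats::rbeta(K, pbar[l] * (1 - F) / F,
                            (1 - pbar[l]) * (1 - F) / F)
  N <- sum(cfg$sizes)
  values <- matrix(0L, N, L)
  pops <- rep(names(cfg$sizes), cfg$sizes)
  row <- 0L
  for (k in seq_len(K)) for (i in seq_len(cfg$sizes[k])) {
    row <- row + 1L
    values[row, ] <- stats::rbinom(L, 1L, pk[, k])
  }
  locus_ids <- if (is.null(cfg$locus_primers)) paste0("L", seq_len(L)) else
    paste0(cfg$locus_primers, "_",
           stats::ave(seq_len(L), cfg$locus_primers, FUN = seq_along))
  isolate_ids <- paste0(pops, "_", stats::ave(seq_len(N), pops, FUN = seq_along))
  m <- band_matrix(values, populations = pops, isolate_ids = isolate_ids,
                   locus_ids = locus_ids)
  # simulation truth, for parameter-recovery checks
  dimnames(pk) <- list(locus_ids, names(cfg$sizes))
  attr(m, "true_freq") <- pk
  attr(m, "ancestral_freq") <- stats::setNames(pbar, locus_ids)
  m
}

#' Configuration for the bioassay simulator
#'
#' Death times follow the log-normal model underlying probit-on-log-time
#' analysis: the probability that a larva is dead by day t is
#' Phi(b (log10 t - log10 LT50)), i.e. log10 death time ~
#' Normal(log10 LT50, 1/b). A larva dying in (t-1, t] is recorded on day t
#' (daily observation); survivors past `n_days` are censored. Each dead larva
#' is mycosed with probability `p_mycosis`.
#'
#' @param strains data.frame with columns `strain`, `lt50` (days, > 0), `b`
#'   (probit slope, > 0) and optionally `p_mycosis`.
#' @param n_exposed larvae per replicate (default 30).
#' @param replicates replicates per strain (default 3).
#' @param n_days observation days (default 10).
#' @param p_mycosis default mycosis probability given death.
#' @param seed mandatory integer seed.
#' @return list of class `bioassay_sim_config`.
#' @export
bioassay_sim_config <- function(strains, n_exposed = 30L, replicates = 3L,
                                n_days = 10L, p_mycosis = 0.5, seed) {
  stopifnot(is.data.frame(strains), all(c("strain", "lt50", "b") %in%
                                        names(strains)),
            all(strains$lt50 > 0), all(strains$b > 0), n_days >= 1L,
            n_exposed >= 1L, replicates >= 1L)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(strains$p_mycosis)) strains$p_mycosis <- p_mycosis
  structure(list(strains = strains, n_exposed = as.integer(n_exposed),
                 replicates = as.integer(replicates),
                 n_days = as.integer(n_days), seed = as.integer(seed)),
            class = "bioassay_sim_config")
}

#' Simulate daily bioassay records
#'
#' @param cfg a [bioassay_sim_config].
#' @return [bioassay_records] data.frame, one row per strain x replicate x
#'   day; reproducible for a fixed seed.
#' @export
simulate_bioassay <- function(cfg) {
  stopifnot(inherits(cfg, "bioassay_sim_config"))
  set.seed(cfg$seed)
  out <- list()
  for (s in seq_len(nrow(cfg$strains))) {
    st <- cfg$strains[s, ]
    for (r in seq_len(cfg$replicates)) {
      z <- stats::rnorm(cfg$n_exposed)
      tdeath <- 10^(log10(st$lt50) + z / st$b)
      day <- pmax(ceiling(tdeath), 1L)
      dead_by <- vapply(seq_len(cfg$n_days), function(t) sum(day <= t),
                        integer(1))
      n_dead <- dead_by[cfg$n_days]
      mycosed <- stats::rbinom(1L, n_dead, st$p_mycosis)
      out[[length(out) + 1L]] <- data.frame(
        strain = st$strain, replicate = r, n_exposed = cfg$n_exposed,
        day = seq_len(cfg$n_days), cum_dead = dead_by, mycosed = mycosed)
    }
  }
  bioassay_records(do.call(rbind, out))
}
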