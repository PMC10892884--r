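#' Assemble and validate bioassay records
#'
#' Long-format daily mortality records for a fungal virulence assay: one row
#' per strain x replicate x observation day, with the cumulative number of
#' dead larvae on that day, plus (on any row of the replicate) the final
#' count of mycosed cadavers — dead larvae showing fungal outgrowth, the
#' confirmation that death was caused by infection.
#'
#' @param df data.frame with columns `strain`, `replicate`, `n_exposed`,
#'   `day`, `cum_dead`, `mycosed` (final mycosed count, repeated or on the
#'   last day).
#' @return validated data.frame of class `bioassay_records`.
#' @export
bioassay_records <- function(df) {
  need <- c("strain", "replicate", "n_exposed", "day", "cum_dead", "mycosed")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("bioassay records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$strain, df$replicate, df$day), , drop = FALSE]
  for (key in split(seq_len(nrow(df)), list(df$strain, df$replicate),
                    drop = TRUE)) {
    cd <- df$cum_dead[key]
    if (any(diff(cd) < 0))
      stop(sprintf("cumulative deaths decrease for strain '%s' replicate %s",
                   df$strain[key[1L]], df$replicate[key[1L]]), call. = FALSE)
    if (cd[length(cd)] > df$n_exposed[key[1L]])
      stop(sprintf("more deaths than exposed for strain '%s' replicate %s",
                   df$strain[key[1L]], df$replicate[key[1L]]), call. = FALSE)
    if (max(df$mycosed[key]) > cd[length(cd)])
      stop(sprintf("more mycosed cadavers than deaths for strain '%s' replicate %s",
                   df$strain[key[1L]], df$replicate[key[1L]]), call. = FALSE)
  }
  class(df) <- c("bioassay_records", "data.frame")
  df
}

#' Read bioassay records from CSV
#' @param path CSV with columns strain, replicate, n_exposed, day, cum_dead,
#'   mycosed.
#' @return a [bioassay_records] data.frame.
#' @export
read_bioassay <- function(path) {
  bioassay_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Final mortality and mycosis summary for one strain
#'
#' Per replicate, final mortality percent = 100 x final deaths / exposed and
#' mycosis percent = 100 x mycosed cadavers / exposed; returns the means and
#' standard errors (sd / sqrt(replicates)) across replicates.
#'
#' @param records [bioassay_records] rows for a single strain.
#' @return list: `mortality_mean`, `mortality_se`, `mycosis_mean`,
#'   `mycosis_se`, `n_replicates`.
#' @export
mortality_summary <- function(records) {
  stopifnot(nrow(records) > 0L)
  if (length(unique(records$strain)) != 1L)
    stop("mortality_summary expects records for a single strain", call. = FALSE)
  reps <- split(records, records$replicate, drop = TRUE)
  if (length(unique(records$n_exposed)) > 1L)
    warning("n_exposed differs across replicates", call. = FALSE)
  mort <- vapply(reps, function(r)
    100 * r$cum_dead[which.max(r$day)] / r$n_exposed[1L], numeric(1))
  myc <- vapply(reps, function(r)
    100 * max(r$mycosed) / r$n_exposed[1L], numeric(1))
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  list(mortality_mean = mean(mort), mortality_se = se(mort),
       mycosis_mean = mean(myc), mycosis_se = se(myc),
       n_replicates = length(reps))
}

#' Empirical probit transform
#'
#' Classical probit scale with the +5 offset: Y = Phi^-1(m) + 5, so 50%
#' mortality maps to probit 5. Undefined at 0 and 1; such observation days
#' are excluded from probit regression.
#'
#' @param m mortality proportion strictly between 0 and 1.
#' @return probit value.
#' @export
empirical_probit <- function(m) {
  if (any(m <= 0 | m >= 1))
    stop("probit undefined at 0% or 100% mortality", call. = FALSE)
  stats::qnorm(m) + 5
}

#' Probit-on-log-time regression and LT50
#'
#' Ordinary least squares of the empirical probit of cumulative mortality on
#' X = log10(day): Y = a + b X. Days with 0% or 100% mortality carry no
#' probit information and are dropped (optionally replaced by the
#' Bartlett-adjusted proportions (d + 0.375)/(n + 0.75)). The median lethal
#' time is LT50 = 10^((5 - a)/b), reported only when the slope is positive
#' and the observed mortality reached 50%.
#'
#' @param days observation days.
#' @param mortality cumulative mortality proportions (pooled across
#'   replicates), same length as `days`.
#' @param n_total total larvae behind each proportion; needed only for
#'   `adjust = "bartlett"`.
#' @param adjust `"none"` (default) or `"bartlett"`.
#' @return list of class `probit_fit`: `a`, `b`, `r`, `LT50` (NA when not
#'   estimable), `points_used`, `max_mortality`.
#' @export
fit_probit <- function(days, mortality, n_total = NULL,
                       adjust = c("none", "bartlett")) {
  adjust <- match.arg(adjust)
  stopifnot(length(days) == length(mortality), all(days > 0),
            all(mortality >= 0 & mortality <= 1))
  m <- mortality
  if (adjust == "bartlett") {
    if (is.null(n_total)) stop("bartlett adjustment needs n_total", call. = FALSE)
    d <- m * n_total
    m <- (d + 0.375) / (n_total + 0.75)
  }
  use <- m > 0 & m < 1
  x <- log10(days[use])
  y <- empirical_probit(m[use])
  if (sum(use) < 2L || length(unique(x)) < 2L)
    stop("probit fit needs >= 2 usable days with distinct log-times",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)[1L])
  b <- unname(stats::coef(fit)[2L])
  r <- suppressWarnings(stats::cor(x, y))  # NA when probits are constant
  lt50 <- if (b > 1e-8 && max(mortality) >= 0.5) 10^((5 - a) / b) else NA_real_
  structure(list(a = a, b = b, r = r, LT50 = lt50, points_used = sum(use),
                 max_mortality = max(mortality)),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit fit: Y = %.2f + %.2f X  (r = %.2f, %d days used)\n",
              x$a, x$b, x$r, x$points_used))
  cat(if (is.na(x$LT50)) "  LT50 not estimable\n"
      else sprintf("  LT50 = %.2f d\n", x$LT50))
  invisible(x)
}

#' Pooled daily mortality proportions for one strain
#'
#' Sums cumulative deaths and exposed larvae across replicates per day,
#' giving the proportions fed to [fit_probit()]. One regression per strain,
#' not per replicate.
#'
#' @param records [bioassay_records] rows for a single strain.
#' @return data.frame with `day`, `dead`, `n`, `mortality`.
#' @export
pooled_mortality <- function(records) {
  if (length(unique(records$strain)) != 1L)
    stop("pooled_mortality expects records for a single strain", call. = FALSE)
  days <- sort(unique(records$day))
  out <- lapply(days, function(t) {
    rows <- records[records$day == t, , drop = FALSE]
    data.frame(day = t, dead = sum(rows$cum_dead), n = sum(rows$n_exposed))
  })
  out <- do.call(rbind, out)
  out$mortality <- out$dead / out$n
  out
}

#' Kaplan-Meier survival estimate from daily mortality records
#'
#' Converts cumulative counts into individual event times (a larva first
#' counted dead on day t died on day t), censors survivors at `censor_day`,
#' and applies the product-limit estimator. The median lethal time is the
#' smallest event time at which the survival curve drops to 0.5 or below.
#'
#' @param records [bioassay_records] rows (typically one strain, all
#'   replicates).
#' @param censor_day last observation day; defaults to the last day present.
#' @return list of class `km_estimate`: `time`, `surv`, `n_risk`, `n_event`,
#'   `median` (NA when survival never reaches 0.5), `n`.
#' @export
kaplan_meier <- function(records, censor_day = max(records$day)) {
  times <- integer(0)
  status <- integer(0)
  for (key in split(seq_len(nrow(records)), list(records$strain,
                                                 records$replicate),
                    drop = TRUE)) {
    rows <- records[key, , drop = FALSE]
    rows <- rows[order(rows$day), , drop = FALSE]
    deaths <- diff(c(0L, rows$cum_dead))
    dtimes <- rep(rows$day, deaths)
    surv_n <- rows$n_exposed[1L] - sum(deaths)
    times <- c(times, dtimes, rep(censor_day, surv_n))
    status <- c(status, rep(1L, length(dtimes)), rep(0L, surv_n))
  }
  fit <- survival::survfit(survival::Surv(times, status) ~ 1)
  s <- summary(fit, censored = FALSE)
  below <- which(fit$surv <= 0.5 + 1e-9 & fit$n.event > 0)
  med <- if (length(below) > 0L) fit$time[min(below)] else NA_real_
  structure(list(time = s$time, surv = s$surv, n_risk = s$n.risk,
                 n_event = s$n.event, median = med, n = length(times)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate on %d larvae, %d event times\n",
              x$n, length(x$time)))
  cat(if (is.na(x$median)) "  median lethal time not reached\n"
      else sprintf("  median lethal time = %g d\n", x$median))
  invisible(x)
}
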