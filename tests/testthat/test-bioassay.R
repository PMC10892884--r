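make_records <- function(finals, n = 30, days = 10, mycosed = 0) {
  # one strain, one replicate per element of finals; deaths all on day 1
  do.call(rbind, lapply(seq_along(finals), function(r)
    data.frame(strain = "S", replicate = r, n_exposed = n, day = seq_len(days),
               cum_dead = rep(finals[r], days), mycosed = mycosed)))
}

test_that("record validation enforces the counting invariants", {
  df <- data.frame(strain = "S", replicate = 1, n_exposed = 30, day = 1:3,
                   cum_dead = c(5, 3, 8), mycosed = 0)
  expect_error(bioassay_records(df), "decrease")
  df2 <- transform(df, cum_dead = c(5, 10, 40))
  expect_error(bioassay_records(df2), "more deaths than exposed")
  df3 <- transform(df, cum_dead = c(5, 6, 8), mycosed = 9)
  expect_error(bioassay_records(df3), "mycosed")
  expect_s3_class(bioassay_records(transform(df, cum_dead = c(5, 6, 8))),
                  "bioassay_records")
  expect_error(bioassay_records(df[, -4]), "missing columns")
})

test_that("mortality and mycosis summaries use mean and standard error", {
  rec <- bioassay_records(make_records(c(30, 30, 30)))
  s <- mortality_summary(rec)
  expect_equal(s$mortality_mean, 100)
  expect_equal(s$mortality_se, 0)
  rec2 <- bioassay_records(make_records(c(21, 24, 27)))  # 70, 80, 90%
  s2 <- mortality_summary(rec2)
  expect_equal(s2$mortality_mean, 80)
  expect_equal(s2$mortality_se, 10 / sqrt(3), tolerance = 1e-12)
  expect_equal(s2$mortality_se, 5.77, tolerance = 1e-2)
  rec0 <- bioassay_records(make_records(c(0, 0, 0)))
  s0 <- mortality_summary(rec0)
  expect_equal(s0$mortality_mean, 0)
  expect_equal(s0$mortality_se, 0)
  # mycosis is counted out of exposed larvae
  rec3 <- bioassay_records(make_records(c(30, 30, 30), mycosed = 15))
  expect_equal(mortality_summary(rec3)$mycosis_mean, 50)
  expect_warning(mortality_summary(bioassay_records(
    data.frame(strain = "S", replicate = c(1, 2), n_exposed = c(30, 20),
               day = 1, cum_dead = c(3, 2), mycosed = 0))), "n_exposed")
})

test_that("empirical probit is the normal quantile plus five", {
  expect_equal(empirical_probit(0.5), 5)
  expect_equal(empirical_probit(pnorm(1)), 6, tolerance = 1e-12)
  expect_error(empirical_probit(0), "undefined")
  expect_error(empirical_probit(1), "undefined")
})

test_that("probit regression recovers an exact probit line", {
  # days reach past LT50 so the 50%-mortality reporting condition is met
  t <- 2:12
  m <- pnorm((2 + 3 * log10(t)) - 5)
  fit <- fit_probit(t, m)
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$b, 3, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$LT50, 10, tolerance = 1e-9)
  expect_equal(fit$points_used, length(t))
})

test_that("degenerate mortality patterns leave LT50 undefined", {
  fit <- fit_probit(1:8, rep(0.5, 8))
  expect_equal(fit$b, 0, tolerance = 1e-12)
  expect_true(is.na(fit$LT50))
  # mortality never reaches 50% -> no LT50 even with a positive slope
  t <- 2:9
  m_low <- pnorm((2 + 3 * log10(t)) - 5) * 0.6
  fit_low <- fit_probit(t, m_low)
  expect_true(fit_low$b > 0)
  expect_true(max(m_low) < 0.5)
  expect_true(is.na(fit_low$LT50))
  # all-0/all-1 days carry no probit information
  expect_error(fit_probit(1:5, c(0, 0, 1, 1, 1)), "usable days")
})

test_that("rescaling time shifts the intercept and scales LT50", {
  t <- 2:9
  m <- pnorm((1 + 4 * log10(t)) - 5)
  f1 <- fit_probit(t, m)
  cfac <- 2.5
  f2 <- fit_probit(cfac * t, m)
  expect_equal(f2$b, f1$b, tolerance = 1e-9)
  expect_equal(f2$a, f1$a - f1$b * log10(cfac), tolerance = 1e-9)
  expect_equal(f2$LT50, cfac * f1$LT50, tolerance = 1e-9)
})

test_that("the Bartlett adjustment pulls extreme days into the fit", {
  t <- 1:6
  m <- c(0, 0.2, 0.4, 0.6, 0.9, 1)
  plain <- fit_probit(t, m)
  adj <- fit_probit(t, m, n_total = rep(90, 6), adjust = "bartlett")
  expect_equal(plain$points_used, 4L)
  expect_equal(adj$points_used, 6L)
  expect_error(fit_probit(t, m, adjust = "bartlett"), "n_total")
})

test_that("Kaplan-Meier matches the textbook worked example", {
  df <- data.frame(strain = "S", replicate = 1, n_exposed = 4, day = 1:4,
                   cum_dead = 1:4, mycosed = 0)
  km <- kaplan_meier(bioassay_records(df))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  # no deaths: survival stays at 1, median undefined
  df0 <- data.frame(strain = "S", replicate = 1, n_exposed = 10, day = 1:5,
                    cum_dead = 0, mycosed = 0)
  km0 <- kaplan_meier(bioassay_records(df0))
  expect_true(all(km0$surv == 1) || length(km0$surv) == 0)
  expect_true(is.na(km0$median))
})

test_that("without censoring Kaplan-Meier equals the empirical survival curve", {
  set.seed(101)
  for (rep in 1:10) {
    death_day <- sample(1:6, 40, replace = TRUE)
    cum <- vapply(1:6, function(t) sum(death_day <= t), integer(1))
    df <- data.frame(strain = "S", replicate = 1, n_exposed = 40, day = 1:6,
                     cum_dead = cum, mycosed = 0)
    km <- kaplan_meier(bioassay_records(df))
    expect_equal(km$surv, empirical_survival(death_day, km$time),
                 tolerance = 1e-12)
  }
})

test_that("KM median lands near the true median of a simulated cohort", {
  set.seed(111)
  death_day <- pmax(ceiling(rexp(300, rate = log(2) / 4)), 1)  # median 4 d
  censor <- 30L
  cum <- vapply(1:censor, function(t) sum(death_day <= t), integer(1))
  df <- data.frame(strain = "S", replicate = 1, n_exposed = 300,
                   day = 1:censor, cum_dead = cum, mycosed = 0)
  km <- kaplan_meier(bioassay_records(df))
  expect_lte(abs(km$median - 4), 0.5)
})

test_that("bioassay records survive a CSV round trip", {
  rec <- simulate_bioassay(bioassay_sim_config(
    data.frame(strain = c("S1", "S2"), lt50 = c(4, 6), b = c(8, 5)),
    seed = 19))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, path, row.names = FALSE)
  back <- read_bioassay(path)
  rownames(back) <- rownames(rec) <- NULL
  expect_equal(as.data.frame(back), as.data.frame(rec))
})
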