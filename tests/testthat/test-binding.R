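test_that("fraction bound is the nitrocellulose share of total counts", {
  expect_equal(fraction_bound(300, 700), 0.30)
  expect_equal(fraction_bound(500, 0), 1.0)
  expect_equal(fraction_bound(0, 800), 0.0)
  expect_error(fraction_bound(0, 0), "undefined")
  expect_error(fraction_bound(-1, 10), "non-negative")
})

test_that("the model halves the plateau at the dissociation constant", {
  expect_equal(binding_model(22.2, kd = 22.2, max_pct = 0.8), 0.4)
  expect_equal(binding_model(0, 5, 0.9), 0)
})

test_that("noiseless titrations are recovered to numerical precision", {
  d <- simulate_binding(22.2, 0.8, noise_sd = 0, seed = 1)[[1]]
  f <- fit_binding(d)
  expect_lt(abs(f$kd - 22.2) / 22.2, 1e-6)
  expect_lt(abs(f$max_pct - 0.8), 1e-6)
  expect_lt(f$rss, 1e-12)
  expect_false(f$censored)
  expect_error(fit_binding(data.frame(conc = c(1, 2, 4), fb = c(.1, .2, .3))),
               "4 distinct")
})

test_that("count-space input reproduces the fraction-bound path", {
  d <- simulate_binding(45, 0.8, noise_sd = 0, seed = 2,
                        counts_total = 100000)[[1]]
  f <- fit_binding(data.frame(conc = d$conc, counts_nc = d$counts_nc,
                              counts_nylon = d$counts_nylon))
  expect_lt(abs(f$kd - 45) / 45, 0.01)
})

test_that("fitting is scale-equivariant in concentration", {
  d <- simulate_binding(20, 0.7, noise_sd = 0.02, seed = 3)[[1]]
  f1 <- fit_binding(d)
  for (k in c(0.1, 10)) {
    fk <- fit_binding(data.frame(conc = d$conc * k, fb = d$fb))
    expect_equal(fk$kd, f1$kd * k, tolerance = 1e-6)
    expect_equal(fk$max_pct, f1$max_pct, tolerance = 1e-6)
  }
})

test_that("the fitted RSS never exceeds the generating parameters' RSS", {
  set.seed(4)
  for (kd in c(5, 45, 220)) {
    d <- simulate_binding(kd, 0.8, noise_sd = 0.03, seed = kd)[[1]]
    f <- fit_binding(d)
    rss_truth <- sum((d$fb - binding_model(d$conc, kd, 0.8))^2)
    expect_lte(f$rss, rss_truth + 1e-12)
  }
})

test_that("noisy titrations recover K_D across the reported regime", {
  # the affinity range spans the published leader-S15 interactions
  for (kd in c(5, 20, 45, 220)) {
    reps <- simulate_binding(kd, 0.8, noise_sd = 0.03, n_reps = 50,
                             seed = 100 + kd)
    kds <- vapply(reps, function(d) fit_binding(d)$kd, numeric(1))
    expect_lt(abs(mean(kds) - kd) / kd, 0.10)
  }
})

test_that("weak binders beyond the assayed range are censored", {
  d <- simulate_binding(2000, 0.8, concs = 500 / 2^(10:0),
                        noise_sd = 0, seed = 5)[[1]]
  f <- fit_binding(d, max_conc = 500)
  expect_true(f$censored)
  expect_equal(f$kd_bound, 500)
})

test_that("replicate aggregation follows the censoring rules", {
  mkfit <- function(kd, censored = FALSE, bound = NA_real_) {
    structure(list(kd = kd, max_pct = 0.8, rss = 0, censored = censored,
                   kd_bound = bound, n = 12), class = "binding_fit")
  }
  agg <- aggregate_fits(list(mkfit(20), mkfit(22), mkfit(24)))
  expect_equal(agg$kd_mean, 22)
  expect_equal(agg$kd_sd, 2)
  expect_false(agg$censored)
  # one censored replicate censors the aggregate
  agg2 <- aggregate_fits(list(mkfit(20), mkfit(22),
                              mkfit(600, TRUE, 500)))
  expect_true(agg2$censored)
  expect_equal(agg2$kd_bound, 500)
  expect_match(agg2$label, ">500")
  # a single fit warns and reports no SD
  expect_warning(agg3 <- aggregate_fits(list(mkfit(20))), "fewer than")
  expect_true(is.na(agg3$kd_sd))
  expect_equal(agg3$n, 1L)
  # order invariance
  agg4 <- aggregate_fits(list(mkfit(24), mkfit(20), mkfit(22)))
  expect_equal(agg4$kd_mean, agg$kd_mean)
  expect_equal(agg4$kd_sd, agg$kd_sd)
})

test_that("reporter statistics normalise, fold and star correctly", {
  dat <- data.frame(condition = rep(c("uninduced", "induced"), each = 3),
                    gfp = c(8, 8, 8, 2, 2, 2),
                    od600 = c(2, 2, 2, 2, 2, 2))
  rs <- reporter_stats(dat)
  expect_equal(rs$fold_change, 4.0)
  expect_equal(unname(rs$relative_fluorescence["uninduced"]), 4.0)
  expect_true(is.na(rs$p_value))   # zero within-group variance
  # identical conditions: fold 1, p = 1
  dat2 <- data.frame(condition = rep(c("uninduced", "induced"), each = 3),
                     gfp = rep(c(4.0, 4.1, 3.9), 2), od600 = 1)
  rs2 <- reporter_stats(dat2)
  expect_equal(rs2$fold_change, 1.0)
  expect_equal(rs2$p_value, 1.0)
  expect_equal(rs2$stars, "")
  # under 3 replicates the test is suppressed but means survive
  dat3 <- data.frame(condition = c("uninduced", "uninduced", "induced",
                                   "induced"),
                     gfp = c(4, 4, 1, 1), od600 = 1)
  rs3 <- reporter_stats(dat3)
  expect_true(is.na(rs3$p_value))
  expect_equal(rs3$fold_change, 4.0)
  expect_error(reporter_stats(data.frame(condition = "induced", gfp = 1,
                                         od600 = 0)), "positive")
})

test_that("strong repression is detected by the Welch test", {
  # simulation oracle: 10-fold repression, sd 10% of the mean, n = 3;
  # the heavy-tailed low-df Welch statistic detects it in ~90% of runs
  set.seed(11)
  hits <- vapply(1:500, function(r) {
    dat <- data.frame(
      condition = rep(c("uninduced", "induced"), each = 3),
      gfp = c(rnorm(3, 10, 1), rnorm(3, 1, 0.1)),
      od600 = 1
    )
    reporter_stats(dat)$p_value < 0.01
  }, logical(1))
  expect_equal(mean(hits), 0.906, tolerance = 0.001)
  expect_gte(mean(hits), 0.85)
})
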