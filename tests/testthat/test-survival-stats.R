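make_cohort <- function(time, event, group = "g") {
  survival_cohort(data.frame(
    subject_id = paste0(group, "_", seq_along(time), "_", seq_along(time)),
    group = group, time_days = time, event = event))
}

bind_cohorts <- function(...) {
  recs <- do.call(rbind, lapply(list(...), function(x) x$records))
  recs$subject_id <- paste0(recs$subject_id, "_", seq_len(nrow(recs)))
  survival_cohort(recs)
}

test_that("KM reduces to empirical survival without censoring", {
  co <- make_cohort(c(1, 2, 3, 4), c(1, 1, 1, 1))
  s <- km_estimate(co, "g")
  expect_equal(s$km_survival, c(0.75, 0.5, 0.25, 0))
  all_cens <- make_cohort(c(5, 6, 7), c(0, 0, 0))
  s2 <- km_estimate(all_cens, "g")
  expect_true(all(s2$km_survival == 1))
})

test_that("KM with mixed censoring matches the product-limit oracle", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    time <- sample(1:25, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    co <- make_cohort(time, event)
    s <- km_estimate(co, "g")
    ora <- oracle_km(time, event)
    at_event <- match(ora$time, s$km_times)
    expect_equal(s$km_survival[at_event], ora$surv, tolerance = 1e-12)
  }
})

test_that("median survival is the smallest t with S(t) <= 0.5", {
  co <- make_cohort(c(10, 22, 22, 35), rep(1, 4))
  s <- km_estimate(co, "g")
  expect_equal(median_survival(s), 22)
  cured <- make_cohort(c(10, 100, 100, 100), c(1, 0, 0, 0))
  expect_true(is.na(median_survival(km_estimate(cured, "g"))))
})

test_that("simulated exponential cohort recovers its median", {
  co <- generate_cohort(cohort_spec(
    n_per_group = 200,
    groups = list(list(name = "g", median_days = 30, cure_fraction = 0)),
    end_of_study_day = 1000, seed = 40))
  med <- median_survival(km_estimate(co, "g"))
  expect_lt(abs(med - 30) / 30, 0.15)
})

test_that("printed survival percentages are reproduced from printed inputs", {
  expect_equal(percent_median_increase(30, 22), 37L)
  expect_equal(percent_median_increase(73.5, 55), 34L)
  expect_equal(percent_median_increase(25, 25), 0L)
  expect_error(percent_median_increase(NA, 22), "undefined")
  expect_equal(cure_rate(3, 8), 38L)
  expect_equal(cure_rate(0, 10), 0L)
  expect_equal(cure_rate(10, 10), 100L)
  expect_error(cure_rate(5, 0), "> 0")
  expect_error(cure_rate(9, 8), "survivors")
})

test_that("log-rank: identical groups give chi2 = 0, p = 1", {
  a <- make_cohort(c(3, 5, 8, 13), c(1, 1, 0, 1), "a")
  b <- make_cohort(c(3, 5, 8, 13), c(1, 1, 0, 1), "b")
  lr <- logrank_test(bind_cohorts(a, b), "a", "b")
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
})

test_that("log-rank chi2 matches the explicit O/E/V tabulation", {
  set.seed(27)
  for (i in 1:8) {
    na <- sample(5:20, 1); nb <- sample(5:20, 1)
    a <- make_cohort(sample(1:15, na, TRUE), rbinom(na, 1, 0.8), "a")
    b <- make_cohort(sample(1:15, nb, TRUE), rbinom(nb, 1, 0.8), "b")
    co <- bind_cohorts(a, b)
    if (sum(co$records$event) == 0) next
    lr <- logrank_test(co, "a", "b")
    want <- oracle_logrank_chi2(co$records$time_days, co$records$event,
                                co$records$group)
    expect_equal(lr$chi2, want, tolerance = 1e-9)
  }
})

test_that("log-rank separates strongly different exponential groups", {
  set.seed(29)
  a <- make_cohort(rexp(50, 1), rep(1, 50), "a")
  b <- make_cohort(rexp(50, 4), rep(1, 50), "b")
  lr <- logrank_test(bind_cohorts(a, b), "a", "b")
  expect_lt(lr$p, 0.001)
})

test_that("log-rank with no events anywhere is reported as undefined", {
  a <- make_cohort(c(5, 6), c(0, 0), "a")
  b <- make_cohort(c(7, 8), c(0, 0), "b")
  lr <- logrank_test(bind_cohorts(a, b), "a", "b")
  expect_true(is.na(lr$chi2))
  expect_match(lr$note, "undefined")
})

test_that("Holm adjustments match step-down hand computation", {
  expect_equal(holm_adjust(0.03, "bonferroni"), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 4), "bonferroni"), rep(1, 4))
  # agreement with the reference step-down implementation
  set.seed(31)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    expect_equal(holm_adjust(p, "bonferroni"), p.adjust(p, "holm"),
                 tolerance = 1e-12)
  }
  # Sidak flavor: hand computation for a 3-vector
  p <- c(0.01, 0.04, 0.03)
  want <- c(1 - (1 - 0.01)^3,
            max(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2),
            max(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2, 1 - (1 - 0.04)^1))
  expect_equal(holm_adjust(p, "sidak"), want[c(1, 3, 2)], tolerance = 1e-12)
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm outputs dominate raw p-values and respect ordering", {
  set.seed(33)
  for (method in c("bonferroni", "sidak")) {
    p <- runif(12)
    adj <- holm_adjust(p, method)
    expect_true(all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("one-way ANOVA matches the textbook sum-of-squares oracle", {
  set.seed(35)
  for (i in 1:8) {
    groups <- lapply(1:3, function(g) rnorm(sample(4:12, 1), mean = g * 0.3))
    got <- anova_oneway(groups)
    expect_equal(got$F, oracle_anova_F(groups), tolerance = 1e-10)
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(37)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  got <- anova_oneway(list(x, y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$p, tt$p.value, tolerance = 1e-10)
})

test_that("degenerate ANOVA input gives F = 0", {
  got <- anova_oneway(list(c(2, 2, 2), c(2, 2)))
  expect_equal(got$F, 0)
  expect_equal(got$p, 1)
})

test_that("cohort constructor validates records", {
  expect_error(survival_cohort(data.frame(subject_id = c("a", "a"),
                                          group = "g", time_days = c(1, 2),
                                          event = c(1, 0))), "duplicate")
  expect_error(survival_cohort(data.frame(subject_id = "a", group = "g",
                                          time_days = -1, event = 1)),
               "positive")
  expect_error(survival_cohort(data.frame(subject_id = "a", group = "g",
                                          time_days = 1, event = 2)),
               "0 or 1")
  expect_error(km_estimate(make_cohort(1, 1), "missing"), "empty")
})
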