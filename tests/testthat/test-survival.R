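test_that("Kaplan-Meier reproduces hand-computed product-limit values", {
  km <- km_estimate(tibble::tibble(time = c(1, 2, 3), event = 1))
  expect_equal(km_survival_at(km, c(1, 2, 3)), c(2 / 3, 1 / 3, 0))

  all_cens <- km_estimate(tibble::tibble(time = c(2, 5, 9), event = 0))
  expect_equal(km_survival_at(all_cens, c(1, 5, 100)), c(1, 1, 1))

  mixed <- km_estimate(tibble::tibble(time = c(5, 10), event = c(1, 0)))
  expect_equal(km_survival_at(mixed, 5), 0.5)

  # matches the independent hand oracle on a random fixture
  set.seed(31)
  tt <- round(rexp(30, 0.1), 3); ee <- rbinom(30, 1, 0.7)
  km2 <- km_estimate(tibble::tibble(time = tt, event = ee))
  orc <- oracle_km(tt, ee)
  expect_equal(km_survival_at(km2, as.numeric(names(orc))), unname(orc))

  gl <- glance(km2)
  expect_equal(gl$n, 30)
  expect_equal(gl$n_events, sum(ee))
  expect_equal(nrow(tidy(km2)), length(unique(tt)))
})

test_that("the log-rank statistic agrees with survival::survdiff", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(c(20, 50, 95), 1)
    d <- tibble::tibble(time = round(rexp(n, 0.05), 2),
                        event = rbinom(n, 1, 0.7),
                        group = sample(c("a", "b"), n, replace = TRUE))
    if (length(unique(d$group)) < 2 || sum(d$event) == 0) next
    ours <- logrank_test(d, method = "chisq")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                             data = as.data.frame(d))
    expect_equal(ours$statistic, unname(sd$chisq), tolerance = 1e-10)
    expect_equal(ours$p, stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("identical groups give statistic 0 and p 1; no events give NA", {
  rec <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = 1,
                        group = rep(c("a", "b"), each = 3))
  res <- logrank_test(rec)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  none <- tibble::tibble(time = c(1, 2, 3, 4), event = 0,
                         group = c("a", "a", "b", "b"))
  expect_true(is.na(logrank_test(none)$p))
})

test_that("the small-sample exact p equals the full permutation distribution", {
  # separated groups, n = 6: exact p = 2 / choose(6, 3) = 0.1
  rec <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12), event = 1,
                        group = rep(c("a", "b"), each = 3))
  res <- logrank_test(rec)
  expect_equal(res$method_used, "exact")
  expect_equal(res$p, 2 / choose(6, 3))

  # and matches an independently coded exhaustive enumeration
  combos <- utils::combn(6, 3)
  obs <- oracle_logrank_stat(rec$time, rec$event, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  all_stats <- apply(combos, 2, function(idx) {
    oracle_logrank_stat(rec$time, rec$event, seq_len(6) %in% idx)
  })
  expect_equal(res$p, mean(all_stats >= obs - 1e-12, na.rm = TRUE))
})

test_that("survival association dichotomizes at the median with ties to low", {
  set.seed(55)
  n <- 100
  psi_vals <- runif(n)
  samples <- sprintf("s%03d", 1:n)
  # doubled hazard for the high-PSI half
  rate <- ifelse(psi_vals > median(psi_vals), 0.10, 0.05)
  surv <- tibble::tibble(sample_id = samples, time = rexp(n, rate), event = 1L)
  psi <- tibble::tibble(event_id = "e1", sample_id = samples, psi = psi_vals)
  res <- survival_association(psi, surv)
  expect_lt(res$logrank_p, 0.05)
  expect_equal(res$n_high + res$n_low, n)
  expect_lte(res$n_high, res$n_low)  # ties (none here) and the median go low

  # constant PSI: degenerate split, NA p
  const <- tibble::tibble(event_id = "e2", sample_id = samples, psi = 0.5)
  res2 <- survival_association(const, surv)
  expect_true(is.na(res2$logrank_p))

  # too little overlap is an error
  expect_error(survival_association(psi[1:3, ], surv[1:3, ]), "shared")
})

test_that("survival association is calibrated under the null", {
  set.seed(404)
  n <- 95; n_events <- 1000
  samples <- sprintf("s%03d", 1:n)
  surv <- tibble::tibble(sample_id = samples,
                         time = rexp(n, 0.02),
                         event = rbinom(n, 1, 0.7))
  psi <- tidyr::crossing(event_id = sprintf("e%04d", 1:n_events),
                         sample_id = samples) |>
    dplyr::mutate(psi = runif(dplyr::n()))
  res <- survival_association(psi, surv)
  fpr <- mean(res$logrank_p < 0.05, na.rm = TRUE)
  expect_gte(fpr, 0.03)
  expect_lte(fpr, 0.07)
})
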