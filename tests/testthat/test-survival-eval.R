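# SVM class prediction, Kaplan-Meier estimation, log-rank testing, and the
# marker-count sweep.

test_that("classifier separates resubstituted linearly separable groups", {
  cfg <- cohort_config(n_samples = 100, n_tfs = 6, n_targets = 30,
                       n_background = 0, n_signature = 12, noise_sd = 0.1,
                       group_shift = 3, seed = 2)
  st <- simulate_study(cfg, "one")
  co <- st$cohorts$one
  pred <- classify_cohort(co$expr, co$labels, co$expr, st$truth$tf_ids)
  expect_gte(mean(pred == co$labels[names(pred)]), 0.95)

  expect_error(classify_cohort(co$expr, setNames(rep("good", length(co$labels)),
                                                 names(co$labels)),
                               co$expr, st$truth$tf_ids), "both classes")
  expect_error(suppressWarnings(
    classify_cohort(co$expr, co$labels, co$expr, c("NOPE1", "NOPE2"))),
    "no markers")
  expect_warning(classify_cohort(co$expr, co$labels, co$expr,
                                 c(st$truth$tf_ids, "NOPE")), "NOPE")
})

test_that("held-out prediction recovers planted groups at moderate shift", {
  accs <- vapply(1:20, function(seed) {
    cfg <- cohort_config(n_samples = 200, n_tfs = 10, n_targets = 60,
                         n_background = 0, n_signature = 25, noise_sd = 0.2,
                         group_shift = 1.0, seed = seed)
    st <- simulate_study(cfg)
    mk <- c(st$truth$tf_ids, st$truth$signature$gene)
    pred <- classify_cohort(st$cohorts[[1]]$expr, st$cohorts[[1]]$labels,
                            st$cohorts[[2]]$expr, mk)
    mean(pred == st$cohorts[[2]]$labels[names(pred)])
  }, 0)
  expect_gte(median(accs), 0.9)
})

test_that("Kaplan-Meier estimate matches the product-limit hand computation", {
  surv <- survival_table(c("a", "b", "c"), c(1, 2, 3), c(1, 1, 1))
  km <- km_estimate(surv, c(a = "good", b = "good", c = "good"))
  expect_equal(km$good$surv, c(2 / 3, 1 / 3, 0))

  # all censored: flat at 1
  surv0 <- survival_table(c("a", "b", "c"), c(1, 2, 3), c(0, 0, 0))
  km0 <- km_estimate(surv0, c(a = "g", b = "g", c = "g"))
  expect_true(all(km0$g$surv == 1))

  # a censored record removes a subject from the risk set without a drop:
  # times 1(event), 2(censor), 3(event) -> S = 2/3 then 2/3 * 1/1... at t=3
  surv1 <- survival_table(c("a", "b", "c"), c(1, 2, 3), c(1, 0, 1))
  km1 <- km_estimate(surv1, c(a = "g", b = "g", c = "g"))
  ev <- km1$g[km1$g$n_event > 0, ]
  expect_equal(ev$surv, c(2 / 3, 0))
  expect_equal(ev$n_risk, c(3, 1))

  expect_error(km_estimate(surv, c(zz = "good")), "zz")
})

test_that("log-rank matches the hand-computed two-group example and symmetry", {
  surv <- survival_table(c("a1", "a2", "b1", "b2"), c(1, 2, 3, 4), rep(1L, 4))
  g <- c(a1 = "good", a2 = "good", b1 = "poor", b2 = "poor")
  r <- logrank_test(surv, g)
  # O_good = 2, E_good = 1/2 + 1/3 = 5/6, V = 17/36: chi = (7/6)^2/(17/36)
  expect_equal(r$chi_square, (7 / 6)^2 / (17 / 36), tolerance = 1e-6)
  expect_equal(r$p_value, 0.0896, tolerance = 1e-3)
  expect_equal(sum(r$observed - r$expected), 0, tolerance = 1e-9)

  swapped <- setNames(ifelse(g == "good", "poor", "good"), names(g))
  expect_equal(logrank_test(surv, swapped)$chi_square, r$chi_square)

  # identical survival experience in both groups: chi ~ 0, p ~ 1
  surv2 <- survival_table(c("a1", "a2", "b1", "b2"), c(5, 9, 5, 9),
                          c(1, 0, 1, 0))
  r2 <- logrank_test(surv2, g)
  expect_lt(r2$chi_square, 1e-9)
  expect_equal(r2$p_value, 1, tolerance = 1e-6)

  expect_error(logrank_test(survival_table("a", 1, 0), c(a = "good")), "two")
})

test_that("log-rank agrees with the brute-force event-time loop", {
  for (case in 1:100) {
    d <- withr::with_seed(5000 + case, {
      n <- sample(10:40, 1)
      list(time = round(rexp(n, 0.1), 1) + 0.1,
           event = rbinom(n, 1, 0.7),
           group = sample(c("good", "poor"), n, TRUE))
    })
    if (sum(d$event) == 0 || length(unique(d$group)) < 2) next
    ids <- sprintf("s%02d", seq_along(d$time))
    surv <- survival_table(ids, d$time, d$event)
    ours <- logrank_test(surv, setNames(d$group, ids))$chi_square
    brute <- oracle_logrank_chisq(d$time, d$event, d$group)
    expect_equal(ours, brute, tolerance = 1e-9)
  }
})

test_that("log-rank is invariant to record order", {
  d <- withr::with_seed(77, {
    list(time = rexp(30, 0.05), event = rbinom(30, 1, 0.6),
         group = sample(c("good", "poor"), 30, TRUE))
  })
  ids <- sprintf("s%02d", 1:30)
  surv <- survival_table(ids, d$time, d$event)
  g <- setNames(d$group, ids)
  base <- logrank_test(surv, g)$chi_square
  perm <- withr::with_seed(3, sample(30))
  surv2 <- survival_table(ids[perm], d$time[perm], d$event[perm])
  expect_equal(logrank_test(surv2, g[perm])$chi_square, base)
})

test_that("equal-hazard survival gives uniform log-rank p-values", {
  # n chosen large enough that the 1-df chi-square null is accurate; at
  # small n the discreteness of the statistic is detectable by KS
  ps <- vapply(1:1000, function(s) withr::with_seed(s, {
    n <- 100
    time <- rexp(n, 0.05)
    event <- as.integer(time <= 60)
    time <- pmin(time, 60)
    grp <- rep(c("good", "poor"), n / 2)
    ids <- sprintf("s%02d", 1:n)
    tryCatch(logrank_test(survival_table(ids, time, event),
                          setNames(grp, ids))$p_value,
             error = function(e) NA_real_)
  }), 0)
  ps <- ps[!is.na(ps)]
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("marker sweep is consistent with direct evaluation and truncates", {
  st <- cached("sweep-study", function() {
    cfg <- cohort_config(n_samples = 120, n_tfs = 6, n_targets = 40,
                         n_background = 0, n_signature = 16, noise_sd = 0.2,
                         group_shift = 1.2, seed = 17)
    simulate_study(cfg)
  })
  ord <- list(tfs = st$truth$tf_ids)
  full <- size_sweep(ord, length(st$truth$tf_ids),
                     st$cohorts[[1]]$expr, st$cohorts[[1]]$labels,
                     st$cohorts[[2]]$expr, st$cohorts[[2]]$survival)
  direct <- logrank_test(
    st$cohorts[[2]]$survival,
    classify_cohort(st$cohorts[[1]]$expr, st$cohorts[[1]]$labels,
                    st$cohorts[[2]]$expr, st$truth$tf_ids))$p_value
  expect_equal(full[1, 1], direct)
  expect_warning(tr <- size_sweep(ord, 99, st$cohorts[[1]]$expr,
                                  st$cohorts[[1]]$labels, st$cohorts[[2]]$expr,
                                  st$cohorts[[2]]$survival), "truncated")
  expect_equal(tr[1, 1], direct)
})

test_that("informative markers accumulate prognostic signal in the sweep", {
  good_runs <- 0
  for (seed in 1:10) {
    cfg <- cohort_config(n_samples = 150, n_tfs = 8, n_targets = 40,
                         n_background = 0, n_signature = 16, noise_sd = 0.2,
                         group_shift = 1.2, hazard_good = 0.01,
                         hazard_poor = 0.05, seed = 300 + seed)
    st <- simulate_study(cfg)
    sizes <- c(2, 4, 8)
    ps <- size_sweep(list(tfs = st$truth$tf_ids), sizes,
                     st$cohorts[[1]]$expr, st$cohorts[[1]]$labels,
                     st$cohorts[[2]]$expr, st$cohorts[[2]]$survival)
    ps <- ps[1, ]
    if (all(is.na(ps))) next
    # more informative markers should not be clearly worse than two markers
    if (min(ps, na.rm = TRUE) <= ps[1] + 1e-12) good_runs <- good_runs + 1
  }
  expect_gte(good_runs, 8)
})
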