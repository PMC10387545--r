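# Conditional ML item estimation, weighted likelihood person estimation,
# anchoring, and the RSM-vs-PCM likelihood-ratio test.

test_that("two dichotomous items: location difference is ln(n10/n01)", {
  set.seed(42)
  x <- cbind(I1 = rbinom(120, 1, 0.6), I2 = rbinom(120, 1, 0.45))
  it <- estimate_items(response_matrix(x, item_max = c(1, 1)), se = FALSE)
  n10 <- sum(x[, 1] == 1 & x[, 2] == 0)
  n01 <- sum(x[, 1] == 0 & x[, 2] == 1)
  expect_equal(it$I2$location - it$I1$location, log(n10 / n01),
               tolerance = 1e-6)
  # symmetric counts give equal locations
  xs <- rbind(matrix(c(1, 0), 10, 2, byrow = TRUE),
              matrix(c(0, 1), 10, 2, byrow = TRUE),
              matrix(c(1, 1), 5, 2, byrow = TRUE),
              matrix(c(0, 0), 6, 2, byrow = TRUE))
  colnames(xs) <- c("A", "B")
  its <- estimate_items(response_matrix(xs, item_max = c(1, 1)), se = FALSE)
  expect_equal(its$A$location, its$B$location, tolerance = 1e-7)
})

test_that("estimates equal brute-force conditional likelihood maximisation", {
  # 3 dichotomous items x 30 persons, full enumeration oracle
  set.seed(11)
  th <- rnorm(30)
  x <- sapply(c(-0.7, 0.2, 0.9), function(d) rbinom(30, 1, plogis(th - d)))
  colnames(x) <- c("A", "B", "C")
  oracle <- bruteforce_cml_dich(x)
  est <- coef(estimate_items(response_matrix(x, item_max = c(1, 1, 1)),
                             se = FALSE))
  expect_equal(unname(est), unname(oracle), tolerance = 1e-4)
})

test_that("item locations mean-center to zero", {
  est <- coef(estimate_items(conforming_sim, se = FALSE))
  expect_equal(mean(est), 0, tolerance = 1e-8)
})

test_that("threshold estimates recover the generating values within 3 SEs", {
  items <- spread_items(6, 3, c(-1, 1), 2)
  truth <- unlist(lapply(items, function(i) i$thresholds))
  covered <- c()
  for (r in 1:4) {
    x <- simulate_responses(sim_design(700, items, seed = 4000 + r))
    f <- estimate_items(x, se = TRUE)
    est <- unlist(lapply(f, function(i) i$thresholds))
    se <- unlist(lapply(f, function(i) i$threshold_se))
    covered <- c(covered, abs(est - truth) <= 3 * se)
  }
  expect_gte(mean(covered), 0.95)
})

test_that("disconnected designs and degenerate items are reported", {
  x <- matrix(NA_integer_, 40, 4, dimnames = list(NULL, paste0("I", 1:4)))
  set.seed(1)
  x[1:20, 1:2] <- rbinom(40, 1, 0.5)
  x[21:40, 3:4] <- rbinom(40, 1, 0.5)
  expect_error(estimate_items(response_matrix(x, item_max = rep(1, 4))),
               "disconnected")
  y <- cbind(A = rbinom(50, 1, 0.5), B = rbinom(50, 1, 0.5), C = rep(1L, 50))
  expect_warning(est <- estimate_items(response_matrix(y, item_max = c(1, 1, 1)),
                                       se = FALSE),
                 "degenerate")
  expect_setequal(names(est), c("A", "B"))
})

test_that("raw score is sufficient: equal scores give equal person estimates", {
  f <- conforming_fit
  pm <- f$persons
  for (r in unique(pm$raw_score)) {
    ests <- pm$estimate[pm$raw_score == r]
    expect_lt(diff(range(ests)), 1e-12)
  }
  # identical response vectors give identical estimate and SE
  expect_equal(length(unique(pm$se[pm$raw_score == pm$raw_score[1]])), 1L)
})

test_that("person estimates are finite and flagged for extreme scores", {
  x <- rbind(rep(0L, 8), rep(3L, 8), matrix(1L, 4, 8))
  colnames(x) <- names(conforming_items)
  pm <- person_measures(response_matrix(x, item_max = rep(3, 8)),
                        conforming_items)
  expect_true(all(is.finite(pm$estimate)))
  expect_true(all(pm$se > 0))
  expect_identical(pm$extreme[1:2], c(TRUE, TRUE))
  expect_false(any(pm$extreme[-(1:2)]))
  expect_lt(pm$estimate[1], min(pm$estimate[-(1:2)]))
  expect_gt(pm$estimate[2], max(pm$estimate[-(1:2)]))
})

test_that("estimated person distribution recovers the generating mean", {
  x <- simulate_responses(sim_design(800, spread_items(9, 3),
                                     theta_mean = 0.5, seed = 77))
  f <- rasch_fit(x, se = FALSE)
  pm <- f$persons[!f$persons$extreme, ]
  expect_equal(mean(pm$estimate), 0.5,
               tolerance = 4 * sd(pm$estimate) / sqrt(nrow(pm)) + 0.05)
})

test_that("anchoring is idempotent and links cohorts onto one metric", {
  f <- conforming_fit
  pa <- anchored_estimates(conforming_sim, f$items)
  expect_equal(pa$estimate, f$persons$estimate)
  expect_equal(pa$se, f$persons$se)
  # two cohorts differing by a known mean, anchored on a pooled calibration
  items <- spread_items(8, 3)
  xa <- simulate_responses(sim_design(300, items, theta_mean = 0, seed = 21))
  xb <- simulate_responses(sim_design(300, items, theta_mean = 0.8, seed = 22))
  pooled_mat <- rbind(unclass(xa), unclass(xb))
  rownames(pooled_mat) <- NULL
  pooled <- response_matrix(pooled_mat, item_max = item_maxima_test(items))
  cal <- estimate_items(pooled, se = FALSE)
  ma <- anchored_estimates(xa, cal); mb <- anchored_estimates(xb, cal)
  d <- mean(mb$estimate) - mean(ma$estimate)
  realized <- mean(attr(xb, "truth")$theta) - mean(attr(xa, "truth")$theta)
  expect_lt(abs(d - realized), 0.12)
  # anchor not covering any administered item errors
  alien <- rasch_items(list(Z1 = c(-1, 0, 1)))
  expect_error(anchored_estimates(xa, alien), "parameters")
})

test_that("specific objectivity: item calibration invariant to person sample", {
  x <- simulate_responses(sim_design(700, spread_items(7, 3, c(-0.8, 0.8), 1.6),
                                     seed = 88))
  f <- rasch_fit(x, se = FALSE)
  med <- stats::median(f$persons$estimate)
  lo <- which(f$persons$estimate <= med)
  hi <- which(f$persons$estimate > med)
  f1 <- estimate_items(subset_rm(x, lo), se = TRUE)
  f2 <- estimate_items(subset_rm(x, hi), se = TRUE)
  se_loc <- function(f) vapply(f, function(i) i$location_se, numeric(1))
  z <- (coef(f1) - coef(f2)) / sqrt(se_loc(f1)^2 + se_loc(f2)^2)
  expect_true(all(abs(z) < 3))
})

test_that("likelihood-ratio test separates rating scale from partial credit", {
  # shared step spacings: RSM recommended
  x <- simulate_responses(sim_design(500, spread_items(6, 3), seed = 61))
  lr <- rsm_vs_pcm(x)
  expect_s3_class(lr, "rasch_lr_test")
  expect_equal(lr$df, (6 - 1) * (3 - 1))
  expect_gt(lr$p.value, 0.001)  # no strong evidence against RSM
  # strongly item-varying spacings: PCM recommended
  th <- list(A = c(-2, -1.5, 2), B = c(-0.1, 0, 0.1), C = c(-2.5, 0, 2.5),
             D = c(-1, 1, 1.2), E = c(-2, 1.8, 1.9), F = c(-0.4, 0.1, 0.5))
  y <- simulate_responses(sim_design(500, rasch_items(th), seed = 62))
  lr2 <- rsm_vs_pcm(y)
  expect_lt(lr2$p.value, 0.05)
  expect_equal(lr2$recommended, "pcm")
  # degenerate cases are skipped with PCM returned
  z <- simulate_responses(sim_design(200, spread_items(4, 1), seed = 63))
  expect_warning(lr3 <- rsm_vs_pcm(z), "skipped")
  expect_equal(lr3$recommended, "pcm")
})

test_that("rsm fit reproduces shared spacings and nests inside pcm", {
  x <- simulate_responses(sim_design(600, spread_items(5, 3), seed = 64))
  rsm <- estimate_items(x, "rsm", se = FALSE)
  steps <- lapply(rsm, function(i) i$thresholds - i$location)
  for (j in 2:length(steps)) expect_equal(steps[[j]], steps[[1]], tolerance = 1e-6)
  pcm <- estimate_items(x, "pcm", se = FALSE)
  expect_lte(attr(rsm, "logLik_cond"), attr(pcm, "logLik_cond") + 1e-6)
})
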