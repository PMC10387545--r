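# Residuals, INFIT/OUTFIT and corrected intervals, class-interval tests,
# person fit, threshold ordering and rescoring.

test_that("Smith's corrected INFIT interval reproduces the printed values", {
  expect_equal(unname(smith_interval(200)), c(0.86, 1.14))
  expect_equal(unname(smith_interval(45)), c(0.70, 1.30))
  expect_equal(unname(smith_interval(1e12)), c(1, 1))
  expect_error(smith_interval(0), ">= 1")
  # smallest n whose corrected interval sits inside the fixed 0.7-1.3 band
  n_min <- which(vapply(1:100, function(n) {
    b <- smith_interval(n, rounded = FALSE)
    b[1] >= 0.7 && b[2] <= 1.3
  }, logical(1)))[1]
  expect_equal(n_min, 45)
})

test_that("standardized residuals are +/-1 for a person at the item location", {
  # dichotomous item answered by a person located exactly at delta
  it <- rasch_items(list(A = 0))
  E <- expected_score(0, it$A); W <- score_variance(0, it$A)
  expect_equal((1 - E) / sqrt(W), 1)
  expect_equal((0 - E) / sqrt(W), -1)
})

test_that("residual moments are calibrated on conforming data", {
  z <- residuals(conforming_fit)
  expect_equal(mean(z), 0, tolerance = 0.03)
  expect_equal(stats::sd(as.vector(z)), 1, tolerance = 0.07)
  # observed minus expected sums to ~0 at the converged estimates
  E <- attr(z, "expected")
  x <- unclass(conforming_fit$responses)[
    !conforming_fit$persons$extreme, , drop = FALSE]
  expect_lt(abs(sum(x - E)) / length(E), 0.01)
})

test_that("a duplicated item yields identical residual columns and low OUTFIT", {
  base <- simulate_responses(sim_design(400, spread_items(5, 3), seed = 1311))
  dup <- cbind(unclass(base), DUP = unclass(base)[, "I5"])
  f <- rasch_fit(response_matrix(dup, item_max = rep(3, 6)), se = FALSE)
  z <- residuals(f)
  expect_equal(unname(z[, "I5"]), unname(z[, "DUP"]), tolerance = 1e-10)
  ifit <- item_fit(f)
  expect_lt(ifit$outfit_mnsq[ifit$item == "I5"], 1)
  expect_lt(ifit$outfit_mnsq[ifit$item == "DUP"], 1)
})

test_that("class intervals follow the equal-count rule and merge tiny groups", {
  # n = 188 non-extreme persons -> G = 3 (the df = 2 convention)
  wh <- whodas_like_data(seed = 3)
  f <- rasch_fit(wh$responses, se = FALSE)
  ci <- class_intervals(f)
  expect_equal(attr(ci, "G"), 3L)
  tab <- table(ci)
  expect_lt(diff(range(tab)), max(tab) * 0.2)
  ifit <- item_fit(f)
  expect_true(all(ifit$chi_df == 2))
})

test_that("item fit flags a group-dependent ordering violation", {
  # one item responds to a different trait ordering for half the sample:
  # simulate its responses with reversed ability for group B
  items <- spread_items(8, 3)
  set.seed(991)
  th <- rnorm(600)
  x <- sapply(items, function(it) {
    p <- category_probability(th, it)
    u <- runif(600)
    max.col(u < t(apply(p, 1, cumsum)), ties.method = "first") - 1L
  })
  bad_theta <- th
  bad_theta[301:600] <- -th[301:600]          # homogeneity breach on I4
  p <- category_probability(bad_theta, items[["I4"]])
  u <- runif(600)
  x[, "I4"] <- max.col(u < t(apply(p, 1, cumsum)), ties.method = "first") - 1L
  f <- rasch_fit(response_matrix(x, item_max = rep(3, 8)), se = FALSE)
  ifit <- item_fit(f)
  expect_true(ifit$chi_flag[ifit$item == "I4"] || ifit$infit_flag[ifit$item == "I4"])
  expect_gt(ifit$infit_mnsq[ifit$item == "I4"], max(ifit$infit_mnsq[ifit$item != "I4"]))
})

test_that("degenerate all-identical responses error cleanly, no crash", {
  x <- matrix(2L, 30, 5, dimnames = list(NULL, paste0("I", 1:5)))
  expect_error(suppressWarnings(rasch_fit(response_matrix(x, item_max = rep(4, 5)))),
               "items")
})

test_that("person fit flags a Guttman-reversed responder", {
  items <- spread_items(9, 3, c(-2, 2), 1.5)
  x <- simulate_responses(sim_design(300, items, seed = 441))
  # adversary: maximum on the 4 hardest items, minimum on the 5 easiest
  locs <- rank(vapply(items, function(i) i$location, numeric(1)))
  adv <- ifelse(locs > 5, 3L, 0L)
  xx <- rbind(unclass(x), adv)
  f <- rasch_fit(response_matrix(xx, item_max = rep(3, 9)), se = FALSE)
  pf <- person_fit(f)
  adv_row <- pf[pf$person_id == rownames(f$responses)[nrow(f$responses)], ]
  expect_gt(adv_row$fit_residual, 2.5)
  expect_true(adv_row$flag)
  # conforming persons are flagged at roughly the two-sided tail rate
  rate <- mean(pf$flag[-nrow(pf)])
  expect_lt(rate, 0.08)
})

test_that("a single-item person carries no fit information and is unflagged", {
  items <- conforming_items
  x <- unclass(conforming_sim)
  x1 <- x[1:50, ]
  x1[1, 1] <- 2L                      # non-extreme single response
  x1[1, -1] <- NA_integer_
  f <- rasch_fit(response_matrix(x1, item_max = rep(3, 8)), se = FALSE)
  pf <- person_fit(f)
  expect_false(pf$flag[pf$person_id == "P1"])
})

test_that("threshold ordering is diagnosed per transition", {
  it <- rasch_items(list(ok = c(-1, 0, 1), bad = c(0, -0.5, 1)))
  rep <- threshold_order(it)
  expect_equal(rep$status, c("ordered", "disordered"))
  expect_equal(rep$offending[2], "2")
  # testletized items are exempt from interpretation
  rep2 <- threshold_order(it, testletized = "bad")
  expect_equal(rep2$status[2], "not interpretable")
})

test_that("rescoring collapses categories conservatively", {
  x <- simulate_responses(sim_design(120, spread_items(4, 4), seed = 17))
  before <- table(unclass(x)[, 2])
  r <- rescore_item(x, 2, c(0, 1, 1, 2, 3))
  expect_equal(attr(r, "item_max")[[2]], 3)
  after <- table(unclass(r)[, 2])
  expect_equal(sum(after), sum(before))
  expect_equal(unname(after["1"]), unname(before["1"] + before["2"]))
  expect_equal(attr(r, "provenance"), "rescored")
  # identity mapping leaves the matrix untouched
  ri <- rescore_item(x, 2, 0:4)
  expect_identical(unclass(ri)[, 2], unclass(x)[, 2])
  # non-monotone or gapped mappings are rejected
  expect_error(rescore_item(x, 2, c(0, 2, 1, 3, 4)), "order-preserving")
  expect_error(rescore_item(x, 2, c(0, 2, 2, 3, 4)), "contiguous")
})

test_that("rescoring a disordered item restores threshold order", {
  # a sparse middle category produces disorder; collapsing it repairs order
  th <- list(A = c(-1.5, 1.3, -0.9, 1.6), B = c(-1.5, -0.5, 0.5, 1.5),
             C = c(-2, -0.6, 0.4, 1.8), D = c(-1, -0.2, 0.9, 1.9))
  restored <- 0
  for (r in 1:3) {
    x <- simulate_responses(sim_design(500, rasch_items(th), seed = 600 + r))
    f <- estimate_items(x, se = FALSE)
    stat <- threshold_order(f)
    expect_equal(stat$status[1], "disordered")
    x2 <- rescore_item(x, "A", c(0, 1, 1, 2, 3))
    f2 <- estimate_items(x2, se = FALSE)
    restored <- restored + (threshold_order(f2)$status[1] == "ordered")
  }
  expect_gte(restored, 2)
})
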