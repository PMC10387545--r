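# Group invariance: residual-ANOVA DIF, item splitting, substantive DIF.

make_dif_data <- function(n = 500, shift = 0.5, item = "I5", seed = 1,
                          slope = 1) {
  items <- spread_items(11, 4)
  grp <- rep(c("a", "b"), length.out = n)
  spec <- if (shift != 0 || slope != 1)
    data.frame(item = item, factor = "g", group = "b", shift = shift,
               slope = slope) else NULL
  x <- simulate_responses(sim_design(n, items, dif_specs = spec,
                                     covariates = data.frame(g = grp),
                                     seed = seed))
  list(x = x, grp = grp)
}

test_that("null DIF simulations produce roughly uniform p-values", {
  ps <- c()
  for (r in 1:5) {
    d <- make_dif_data(shift = 0, seed = 3000 + r)
    tab <- dif_anova(rasch_fit(d$x, se = FALSE), d$grp)
    ps <- c(ps, tab$uniform_p)
    expect_lte(sum(tab$uniform_flag), 1)
  }
  # 55 null tests: the pre-Bonferroni rejection rate stays near 5%
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.08)
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
})

test_that("a 0.5-logit uniform shift is detected with high power", {
  hits <- 0
  for (r in 1:5) {
    d <- make_dif_data(shift = 0.5, seed = 3100 + r)
    tab <- dif_anova(rasch_fit(d$x, se = FALSE), d$grp)
    hits <- hits + tab$uniform_flag[tab$item == "I5"]
  }
  expect_gte(hits / 5, 0.8)
})

test_that("non-uniform DIF loads on the interaction term", {
  # one group responds to a strongly damped trait on I5
  d <- make_dif_data(shift = 0, slope = 0.2, seed = 3200)
  tab <- dif_anova(rasch_fit(d$x, se = FALSE), d$grp)
  expect_true(tab$nonuniform_flag[tab$item == "I5"])
})

test_that("a permuted grouping erases the DIF signal", {
  d <- make_dif_data(shift = 0.8, seed = 3300)
  set.seed(3301)
  perm <- sample(d$grp)
  tab <- dif_anova(rasch_fit(d$x, se = FALSE), perm)
  expect_lte(sum(tab$uniform_flag), 1)
})

test_that("single-group factors are rejected; small groups warned", {
  expect_error(dif_anova(conforming_fit, rep("only", 400)), "single group")
  g <- c(rep("a", 395), rep("b", 5))
  expect_warning(dif_anova(conforming_fit, g), "fewer than")
})

test_that("splitting an item is information-conserving and reversible", {
  d <- make_dif_data(shift = 1, seed = 3400)
  sp <- split_item(d$x, "I5", d$grp)
  expect_equal(ncol(sp), 12)
  expect_equal(attr(sp, "provenance"), "split")
  # per-person observed counts unchanged
  expect_equal(rowSums(!is.na(sp)), rowSums(!is.na(d$x)), ignore_attr = TRUE)
  # merging the split columns recovers the original column
  merged <- rowSums(unclass(sp)[, c("I5@a", "I5@b")], na.rm = TRUE)
  expect_equal(merged, unclass(d$x)[, "I5"], ignore_attr = TRUE)
  # a group with no observations on the item errors
  empty_grp <- d$grp; empty_grp[] <- "a"
  expect_error(split_item(d$x, "I5", factor(empty_grp, levels = c("a", "b"))),
               "no observations")
})

verdict_rule <- function(p, es) {
  if (p >= 0.05) "no DIF"
  else if (es >= 0.1) "substantive (use split)"
  else "non-substantive (retain unsplit)"
}

test_that("substantive DIF verdicts follow the significance + effect-size rule", {
  # no injected DIF: verdict no DIF and effect near zero
  d0 <- make_dif_data(shift = 0, seed = 3500)
  s0 <- substantive_dif(d0$x, "I5", d0$grp,
                        anchor_items = paste0("I", c(1:4, 6:11)))
  expect_lt(s0$effect_size, 0.05)
  expect_equal(s0$verdict, verdict_rule(s0$p, s0$effect_size))
  # strong DIF, minority group, tight anchor: clearly significant, and the
  # measurement-bias effect size lands in the non-negligible band (this is
  # the same order as seen in published stroke data, where a split testlet
  # gave 0.050 and the unsplit solution was retained)
  items <- spread_items(11, 4)
  grp <- rep(c("a", "b"), times = c(350, 150))
  x1 <- simulate_responses(sim_design(
    500, items,
    dif_specs = data.frame(item = "I5", factor = "g", group = "b",
                           shift = 1.5, slope = 1),
    covariates = data.frame(g = grp), seed = 3501))
  s1 <- substantive_dif(x1, "I5", grp, anchor_items = c("I1", "I2"))
  expect_lt(s1$p, 0.05)
  expect_gt(s1$effect_size, 0.015)
  expect_true(s1$non_negligible)
  expect_equal(s1$verdict, verdict_rule(s1$p, s1$effect_size))
  # missing anchor errors with guidance
  expect_error(substantive_dif(x1, "I5", grp, anchor_items = "I5"),
               "anchor")
})

test_that("mild DIF is significant but non-substantive at large n", {
  d <- make_dif_data(n = 900, shift = 0.22, seed = 3600)
  s <- substantive_dif(d$x, "I5", d$grp,
                       anchor_items = paste0("I", c(1:4, 6:11)))
  if (s$p < 0.05) {
    expect_lt(s$effect_size, 0.1)
    expect_equal(s$verdict, "non-substantive (retain unsplit)")
  } else {
    expect_equal(s$verdict, "no DIF")
  }
})

test_that("anchored metrics agree for persons touching only anchor items", {
  d <- make_dif_data(shift = 1, seed = 3700)
  x <- unclass(d$x)
  # persons observed only on anchor items (I5 missing)
  x[1:40, "I5"] <- NA_integer_
  rm <- response_matrix(x, item_max = attr(d$x, "item_max"))
  sp <- split_item(rm, "I5", d$grp)
  f_split <- rasch_fit(sp, se = FALSE)
  anchor <- setdiff(colnames(rm), "I5")
  # fix unsplit estimation at the split solution's anchor parameters
  f_unsplit <- rasch_fit(rm, anchor = f_split$items[anchor], se = FALSE)
  common <- intersect(f_split$persons$person_id[1:40],
                      f_unsplit$persons$person_id[1:40])
  a <- f_split$persons$estimate[match(common, f_split$persons$person_id)]
  b <- f_unsplit$persons$estimate[match(common, f_unsplit$persons$person_id)]
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("iterative resolution leaves no artificial DIF trail", {
  # one strong-DIF item can push opposite bias onto others; after splitting
  # the worst item, remaining items should be clean
  d <- make_dif_data(shift = 1.2, seed = 3800)
  f0 <- rasch_fit(d$x, se = FALSE)
  t0 <- dif_anova(f0, d$grp)
  worst <- t0$item[which.min(t0$uniform_p)]
  expect_equal(worst, "I5")
  sp <- split_item(d$x, worst, d$grp)
  f1 <- rasch_fit(sp, se = FALSE)
  keep <- setdiff(colnames(sp), c("I5@a", "I5@b"))
  t1 <- dif_anova(f1, d$grp)
  t1 <- t1[t1$item %in% keep, ]
  expect_lte(sum(t1$uniform_flag), 1)
})
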