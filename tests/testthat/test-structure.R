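# Local dependency detection, testlets, ECV and the unidimensionality test.

test_that("duplicated items show residual correlation near +1", {
  base <- simulate_responses(sim_design(300, spread_items(5, 3), seed = 2001))
  dup <- cbind(unclass(base), DUP = unclass(base)[, "I2"])
  f <- rasch_fit(response_matrix(dup, item_max = rep(3, 6)), se = FALSE)
  rc <- residual_cor(f)
  expect_gt(rc$matrix["I2", "DUP"], 0.95)
  fl <- flag_lid(rc)
  expect_true(any(fl$item1 == "I2" & fl$item2 == "DUP"))
})

test_that("conforming unidimensional data have a negative average correlation", {
  rc <- residual_cor(conforming_fit)
  expect_lt(rc$average, 0)
})

test_that("the flag rule is relative to the average correlation", {
  fake <- function(avg, cors) {
    pairs <- data.frame(item1 = "A", item2 = letters[seq_along(cors)],
                        cor = cors, n = 100, margin = cors - avg,
                        flag = FALSE, low_n = FALSE)
    structure(list(matrix = NULL, average = avg, pairs = pairs, offset = 0.2),
              class = "residual_cor")
  }
  # average -0.092: a pair at 0.604 is far above average + 0.2
  expect_equal(nrow(flag_lid(fake(-0.092, c(0.604, 0.05)))), 1L)
  # average -0.225: any positive correlation is above average + 0.2
  expect_equal(nrow(flag_lid(fake(-0.225, c(0.01, 0.1, -0.1)))), 2L)
  # all correlations equal: nothing exceeds average + 0.2
  expect_equal(nrow(flag_lid(fake(0.1, rep(0.1, 4)))), 0L)
})

test_that("testlets conserve totals and produce the right score range", {
  x <- simulate_responses(sim_design(150, spread_items(6, 4),
                                     seed = 2100))
  tl <- make_testlets(x, list(T1 = c("I1", "I2"), T2 = c("I3", "I4")))
  expect_equal(ncol(tl), 4)
  expect_equal(attr(tl, "item_max")[["T1"]], 8)  # two 5-category items: 0-8
  expect_equal(rowSums(unclass(tl)), rowSums(unclass(x)))
  expect_equal(attr(tl, "provenance"), "testletized")
  # all-singleton map is the identity
  ident <- make_testlets(x, list())
  expect_equal(unclass(ident), unclass(x), ignore_attr = TRUE)
  # overlapping groups rejected
  expect_error(make_testlets(x, list(A = c("I1", "I2"), B = c("I2", "I3"))),
               "overlapping")
  # missing member makes the super-item score missing
  xm <- unclass(x); xm[1, "I1"] <- NA
  tlm <- make_testlets(response_matrix(xm, item_max = rep(4, 6)),
                       list(T1 = c("I1", "I2")))
  expect_true(is.na(unclass(tlm)[1, "T1"]))
})

test_that("injected dependencies are recovered and clean pairs stay quiet", {
  items <- spread_items(11, 4)
  lid <- data.frame(source = c("I2", "I7"), dependent = c("I3", "I8"),
                    d = c(0.5, 0.6))
  hits <- 0; clean_flags <- 0; clean_pairs <- 0
  for (r in 1:3) {
    x <- simulate_responses(sim_design(500, items, lid_links = lid,
                                       seed = 2200 + r))
    fl <- flag_lid(rasch_fit(x, se = FALSE))
    hit1 <- any(fl$item1 == "I2" & fl$item2 == "I3")
    hit2 <- any(fl$item1 == "I7" & fl$item2 == "I8")
    hits <- hits + hit1 + hit2
    clean_flags <- clean_flags + (nrow(fl) - hit1 - hit2)
    clean_pairs <- clean_pairs + (choose(11, 2) - 2)
  }
  expect_gte(hits / 6, 0.9)                  # sensitivity
  expect_lte(clean_flags / clean_pairs, 0.05)  # false flags
})

test_that("ECV separates unidimensional from two-dimensional structures", {
  items <- spread_items(8, 3)
  dims <- rep(c("a", "b"), each = 4)
  map <- list(A = paste0("I", 1:4), B = paste0("I", 5:8))
  # unidimensional: arbitrary grouping keeps ECV high
  x1 <- simulate_responses(sim_design(400, items, seed = 2301))
  e1 <- explained_common_variance(x1, map)
  expect_gt(e1$ecv, 0.9)
  expect_equal(e1$band, "unidimensional")
  # two uncorrelated dimensions aligned with the grouping: ECV low
  x2 <- simulate_responses(sim_design(400, items, dimension_map = dims,
                                      dim_cor = 0, seed = 2302))
  e2 <- explained_common_variance(x2, map)
  expect_lt(e2$ecv, 0.7)
  expect_equal(e2$band, "multidimensional")
  # single testlet is undefined
  expect_error(explained_common_variance(x1, list(ALL = paste0("I", 1:8))),
               "single testlet")
})

test_that("identical duplicated testlets leave no specific variance", {
  x <- simulate_responses(sim_design(300, spread_items(4, 3), seed = 2400))
  dup <- cbind(unclass(x), unclass(x))
  colnames(dup) <- paste0("I", 1:8)
  e <- explained_common_variance(response_matrix(dup, item_max = rep(3, 8)),
                                 list(A = paste0("I", 1:4),
                                      B = paste0("I", 5:8)))
  expect_gt(e$ecv, 0.95)
})

test_that("unidimensionality t-test calibrates and detects", {
  # unidimensional data: verdict unidimensional
  x <- simulate_responses(sim_design(500, spread_items(10, 3), seed = 2501))
  ud <- unidim_ttest(rasch_fit(x, se = FALSE))
  expect_equal(ud$verdict, "unidimensional")
  expect_lte(ud$ci_lower, 5)
  # two correlated dimensions: percent above threshold, verdict reversed
  dims <- rep(c("a", "b"), each = 5)
  x2 <- simulate_responses(sim_design(500, spread_items(10, 3),
                                      dimension_map = dims, dim_cor = 0.4,
                                      seed = 2502))
  ud2 <- unidim_ttest(rasch_fit(x2, se = FALSE))
  expect_gt(ud2$percent_significant, 5)
  expect_equal(ud2$verdict, "multidimensional")
  # the PCA split recovers the simulated dimensions
  split_a <- ud2$subsets$positive
  expect_true(setequal(split_a, paste0("I", 1:5)) ||
                setequal(split_a, paste0("I", 6:10)))
})

test_that("reliability is inflated by dependency and falls after testletization", {
  items <- spread_items(8, 3)
  lid <- data.frame(source = c("I1", "I3", "I5"),
                    dependent = c("I2", "I4", "I6"), d = 0.5)
  x <- simulate_responses(sim_design(400, items, lid_links = lid, seed = 2601))
  f_items <- rasch_fit(x, se = FALSE)
  a_items <- reliability(f_items)$alpha
  tl <- make_testlets(x, list(T1 = c("I1", "I2"), T2 = c("I3", "I4"),
                              T3 = c("I5", "I6")))
  f_tl <- rasch_fit(tl, se = FALSE)
  a_tl <- reliability(f_tl)$alpha
  expect_gt(a_items, a_tl)
})
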