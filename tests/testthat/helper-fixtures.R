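# Shared fixtures, computed once per test run. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# a conforming mid-sized dataset + fit reused across files
conforming_items <- spread_items(8, 3, c(-1.2, 1.2), 2)
conforming_sim <- simulate_responses(sim_design(400, conforming_items, seed = 7101))
conforming_fit <- rasch_fit(conforming_sim, model = "pcm", se = FALSE)

# brute-force full conditional likelihood for dichotomous items (oracle):
# enumerate all response patterns per raw-score group
bruteforce_cml_dich <- function(x) {
  I <- ncol(x)
  pats <- as.matrix(expand.grid(rep(list(0:1), I)))
  negll <- function(dfree) {
    d <- c(dfree, -sum(dfree))
    ll <- 0
    for (p in seq_len(nrow(x))) {
      r <- sum(x[p, ])
      if (r == 0 || r == I) next
      grp <- pats[rowSums(pats) == r, , drop = FALSE]
      ll <- ll + (-sum(d * x[p, ])) - log(sum(exp(-grp %*% d)))
    }
    -ll
  }
  o <- stats::optim(numeric(I - 1), negll, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 1000))
  c(o$par, -sum(o$par))
}

# direct (non-model) draw of one PCM response vector for adversarial cases
pcm_draw <- function(theta, items, seed) {
  set.seed(seed)
  vapply(items, function(it) {
    p <- category_probability(theta, it)
    sample(0:(ncol(p) - 1L), 1, prob = p)
  }, integer(1))
}

item_maxima_test <- function(items) {
  vapply(items, function(i) length(i$thresholds), integer(1))
}

subset_rm <- function(x, persons) {
  response_matrix(unclass(x)[persons, , drop = FALSE],
                  item_max = attr(x, "item_max"))
}
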