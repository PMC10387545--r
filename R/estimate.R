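# Conditional maximum likelihood estimation for the partial credit /
# rating scale Rasch models.
#
# The conditional likelihood of a response pattern given the person's raw
# score is free of the person parameter (raw-score sufficiency), so item
# thresholds are estimated without any assumption about the trait
# distribution. The normalising constants ("gamma" functions, elementary
# symmetric function analogues for polytomous items) are built by dynamic
# programming over items; all accumulation is in log space.

row_lse <- function(m) {
  mx <- as.vector(do.call(pmax, c(asplit(m, 2), list(na.rm = FALSE))))
  out <- ifelse(is.finite(mx), mx + log(rowSums(exp(m - mx))), mx)
  out
}

# log-space convolution of two score-generating vectors
# la over totals 0..(length(la)-1), lb likewise
log_conv <- function(la, lb) {
  Ta <- length(la); Tb <- length(lb)
  m <- matrix(-Inf, Ta + Tb - 1L, Tb)
  for (k in seq_len(Tb)) m[k:(k + Ta - 1L), k] <- la + lb[k]
  row_lse(m)
}

# persons grouped by observation pattern; per group sufficient counts
build_cml_groups <- function(responses) {
  x <- unclass(responses)
  obs <- !is.na(x)
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  idx <- split(seq_len(nrow(x)), key)
  lapply(idx, function(rows) {
    items <- which(obs[rows[1], ])
    sub <- x[rows, items, drop = FALSE]
    r <- rowSums(sub)
    im <- item_max_of(responses)[items]
    cnt <- lapply(seq_along(items), function(j)
      tabulate(sub[, j] + 1L, nbins = im[j] + 1L))
    score_tab <- table(r)
    list(items = items, item_max = im, counts = cnt,
         scores = as.integer(names(score_tab)),
         n_scores = as.numeric(score_tab), n = length(rows))
  })
}

# negative conditional log-likelihood and analytic gradient in the
# cumulative-threshold (eta) parameterisation; eta_list[[i]] has length m_i.
cml_objective <- function(eta_list, groups) {
  nll <- 0
  grad <- lapply(eta_list, function(e) numeric(length(e)))
  for (g in groups) {
    S <- g$items
    logb <- lapply(seq_along(S), function(j) c(0, -eta_list[[S[j]]]))
    nI <- length(S)
    fwd <- vector("list", nI + 1L); fwd[[1]] <- 0
    for (j in seq_len(nI)) fwd[[j + 1L]] <- log_conv(fwd[[j]], logb[[j]])
    bwd <- vector("list", nI + 1L); bwd[[nI + 1L]] <- 0
    for (j in rev(seq_len(nI))) bwd[[j]] <- log_conv(bwd[[j + 1L]], logb[[j]])
    loggam <- fwd[[nI + 1L]]
    # data part: sum over cells of eta_{i,x} plus sum over scores of log gamma
    for (j in seq_len(nI))
      nll <- nll + sum(g$counts[[j]][-1L] * eta_list[[S[j]]])
    nll <- nll + sum(g$n_scores * loggam[g$scores + 1L])
    for (j in seq_len(nI)) {
      loggam_mi <- log_conv(fwd[[j]], bwd[[j + 1L]])
      m_j <- g$item_max[j]
      gj <- g$counts[[j]][-1L]          # counts of categories 1..m_j
      for (ri in seq_along(g$scores)) {
        r <- g$scores[ri]
        a <- seq_len(m_j)
        ok <- r - a >= 0 & r - a <= (length(loggam_mi) - 1L)
        p <- numeric(m_j)
        p[ok] <- exp(-eta_list[[S[j]]][a[ok]] +
                       loggam_mi[r - a[ok] + 1L] - loggam[r + 1L])
        gj <- gj - g$n_scores[ri] * p
      }
      grad[[S[j]]] <- grad[[S[j]]] + gj
    }
  }
  list(nll = nll, grad = grad)
}

split_par <- function(par, m) {
  idx <- rep(seq_along(m), m)
  split(par, idx)
}

# starting thresholds from adjacent-category frequency logits
start_thresholds <- function(responses) {
  im <- item_max_of(responses)
  x <- unclass(responses)
  lapply(seq_len(ncol(x)), function(i) {
    cnt <- tabulate(x[, i] + 1L, nbins = im[i] + 1L) + 0.5
    log(cnt[-length(cnt)]) - log(cnt[-1L])
  })
}

#' Estimate item parameters by conditional maximum likelihood
#'
#' Item thresholds are estimated by maximising the likelihood of the
#' response patterns conditional on each person's raw score, which removes
#' the person parameters entirely (raw-score sufficiency). The metric is
#' identified by constraining the mean item location to zero; standard
#' errors come from the curvature (observed information) of the conditional
#' log-likelihood. Persons with different missing-data patterns are grouped
#' and conditioned within pattern.
#'
#' Items observed in fewer than two categories are excluded with a warning;
#' unused categories are collapsed (with a warning) before estimation, since
#' a never-observed category carries no information about its threshold.
#'
#' @param responses a [response_matrix()] (or coercible matrix).
#' @param model_form `"pcm"` (item-specific threshold spacing) or `"rsm"`
#'   (one shared spacing pattern; requires equal category counts).
#' @param anchor optional [rasch_items()]: parameters held fixed (no
#'   re-centering is applied, the anchor defines the metric); remaining items
#'   are estimated relative to it.
#' @param se compute standard errors (numerical curvature; skip to save time
#'   in large simulations).
#' @return A [rasch_items()] object with attributes `logLik_cond` (maximised
#'   conditional log-likelihood), `convergence`, `npar`.
#' @export
estimate_items <- function(responses, model_form = c("pcm", "rsm"),
                           anchor = NULL, se = TRUE) {
  model_form <- match.arg(model_form)
  responses <- as_response_matrix(responses)
  responses <- drop_degenerate(responses)
  responses <- collapse_unused_categories(responses)
  check_connectivity(responses)
  im <- item_max_of(responses)
  ids <- colnames(responses)
  groups <- build_cml_groups(responses)

  anchored_idx <- integer(0)
  anchor_eta <- list()
  if (!is.null(anchor)) {
    hit <- intersect(names(anchor), ids)
    if (length(hit) == 0)
      stop("anchor does not cover any administered item")
    bad <- hit[vapply(hit, function(id)
      length(anchor[[id]]$thresholds) != im[match(id, ids)], logical(1))]
    if (length(bad))
      stop("anchor/item category mismatch for: ", paste(bad, collapse = ", "))
    anchored_idx <- match(hit, ids)
    anchor_eta <- lapply(anchor[hit], function(it) cumsum(it$thresholds))
    names(anchor_eta) <- hit
  }
  free_idx <- setdiff(seq_along(ids), anchored_idx)

  if (model_form == "rsm" && length(unique(im)) != 1L)
    stop("rating scale model requires all items to share one category count")

  full_eta <- function(par) {
    eta <- vector("list", length(ids))
    if (length(anchored_idx))
      eta[anchored_idx] <- anchor_eta[ids[anchored_idx]]
    if (model_form == "pcm") {
      eta[free_idx] <- split_par(par, im[free_idx])
      eta[free_idx] <- lapply(eta[free_idx], unname)
    } else {
      m <- im[1]
      nfree <- length(free_idx)
      delta <- par[seq_len(nfree)]
      kap <- if (m > 1) par[nfree + seq_len(m - 1L)] else numeric(0)
      kap <- c(kap, -sum(kap))            # centred shared steps
      scum <- cumsum(kap)
      eta[free_idx] <- lapply(delta, function(d) (1:m) * d + scum)
    }
    eta
  }

  center_penalty <- length(anchored_idx) == 0L
  lambda <- 1000
  objective <- function(par) {
    eta <- full_eta(par)
    o <- cml_objective(eta, groups)
    val <- o$nll
    gr_eta <- o$grad
    if (center_penalty) {
      locs <- vapply(seq_along(eta), function(i) eta[[i]][im[i]] / im[i], numeric(1))
      s <- sum(locs)
      val <- val + lambda * s^2
      for (i in seq_along(eta))
        gr_eta[[i]][im[i]] <- gr_eta[[i]][im[i]] + 2 * lambda * s / im[i]
    }
    if (model_form == "pcm") {
      gr <- unlist(gr_eta[free_idx], use.names = FALSE)
    } else {
      m <- im[1]
      gd <- vapply(free_idx, function(i) sum((1:m) * gr_eta[[i]]), numeric(1))
      gk <- numeric(m - 1L)
      if (m > 1) {
        for (j in seq_len(m - 1L)) {
          # d eta_ik / d kappa_j = 1{j <= k < m}
          gk[j] <- sum(vapply(free_idx, function(i)
            sum(gr_eta[[i]][j:(m - 1L)]), numeric(1)))
        }
      }
      gr <- c(gd, gk)
    }
    list(value = val, gradient = gr)
  }

  cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    o <- objective(par); cache$par <- par; cache$o <- o; o$value
  }
  gr <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$o$gradient)
    objective(par)$gradient
  }

  tau0 <- start_thresholds(responses)
  c0 <- mean(vapply(tau0, mean, numeric(1)))
  tau0 <- lapply(tau0, function(t) t - c0)
  if (model_form == "pcm") {
    par0 <- unlist(lapply(tau0[free_idx], cumsum), use.names = FALSE)
  } else {
    m <- im[1]
    d0 <- vapply(tau0[free_idx], mean, numeric(1))
    par0 <- c(d0, numeric(max(m - 1L, 0L)))
  }

  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = -25, upper = 25,
                      control = list(maxit = 500, factr = 1e5, pgtol = 1e-9))
  gnorm <- sqrt(sum(gr(opt$par)^2))
  n_total <- sum(vapply(groups, function(g) g$n, numeric(1)))
  converged <- opt$convergence == 0 && gnorm < 1e-4 * max(1, n_total)
  if (!converged && gnorm > 1)
    warning("conditional ML estimation may not have converged (|grad| = ",
            signif(gnorm, 3), ")")

  eta <- full_eta(opt$par)
  if (center_penalty) {
    cc <- mean(vapply(seq_along(eta), function(i) eta[[i]][im[i]] / im[i], numeric(1)))
    eta <- lapply(seq_along(eta), function(i) eta[[i]] - (1:im[i]) * cc)
  }
  tau <- lapply(eta, function(e) diff(c(0, e)))
  names(tau) <- ids

  tau_se <- NULL
  loc_se <- rep(NA_real_, length(ids))
  if (se && length(free_idx)) {
    H <- num_hessian(function(p) objective(p)$gradient, opt$par)
    V <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    tau_se <- lapply(seq_along(ids), function(i) rep(NA_real_, im[i]))
    if (!is.null(V) && model_form == "pcm") {
      offs <- c(0, cumsum(im[free_idx]))
      for (jj in seq_along(free_idx)) {
        i <- free_idx[jj]
        sel <- offs[jj] + seq_len(im[i])
        Vi <- V[sel, sel, drop = FALSE]
        # tau_k = eta_k - eta_{k-1}
        D <- diag(im[i]); if (im[i] > 1) D[cbind(2:im[i], 1:(im[i] - 1))] <- -1
        vt <- diag(D %*% Vi %*% t(D))
        tau_se[[i]] <- sqrt(pmax(vt, 0))
        # location = eta_m / m
        loc_se[i] <- sqrt(max(Vi[im[i], im[i]], 0)) / im[i]
      }
    } else if (!is.null(V) && model_form == "rsm") {
      nfree <- length(free_idx)
      for (jj in seq_len(nfree)) {
        tau_se[[free_idx[jj]]] <- rep(sqrt(max(V[jj, jj], 0)), im[free_idx[jj]])
        loc_se[free_idx[jj]] <- sqrt(max(V[jj, jj], 0))
      }
    }
    names(tau_se) <- ids
  }

  out <- rasch_items(tau, se = tau_se,
                     model_form = if (model_form == "rsm") "rating_scale"
                                  else if (all(im == 1L)) "dichotomous"
                                  else "partial_credit")
  for (i in seq_along(out)) out[[i]]$location_se <- loc_se[i]
  attr(out, "logLik_cond") <- -cml_objective(eta, groups)$nll
  attr(out, "convergence") <- list(converged = converged, grad_norm = gnorm,
                                   counts = opt$counts)
  attr(out, "npar") <- length(par0) - as.integer(center_penalty)
  attr(out, "rescore_log") <- attr(responses, "rescore_log")
  out
}

num_hessian <- function(gradfun, par, h = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h
    H[, j] <- (gradfun(par + e) - gradfun(par - e)) / (2 * h)
  }
  H
}

as_response_matrix <- function(responses) {
  if (inherits(responses, "response_matrix")) responses
  else response_matrix(responses)
}

drop_degenerate <- function(responses) {
  bad <- degenerate_items(responses)
  if (ncol(responses) - length(bad) < 2L)
    stop("fewer than 2 non-degenerate items")
  if (length(bad)) {
    warning("excluding degenerate item(s) with <2 observed categories: ",
            paste(colnames(responses)[bad], collapse = ", "))
    responses <- subset_responses(responses, items = setdiff(seq_len(ncol(responses)), bad))
  }
  if (ncol(responses) < 2L) stop("fewer than 2 non-degenerate items")
  responses
}

# drop categories that are never used (they carry no threshold information)
collapse_unused_categories <- function(responses) {
  im <- item_max_of(responses)
  x <- unclass(responses)
  log <- list()
  for (i in seq_len(ncol(x))) {
    used <- sort(unique(x[!is.na(x[, i]), i]))
    if (length(used) == im[i] + 1L) next
    map <- match(x[, i], used) - 1L
    log[[colnames(x)[i]]] <- stats::setNames(seq_along(used) - 1L, used)
    x[, i] <- map
    im[i] <- length(used) - 1L
  }
  if (length(log)) {
    warning("collapsed unused categories for item(s): ",
            paste(names(log), collapse = ", "))
  }
  out <- response_matrix(x, item_max = im, provenance = attr(responses, "provenance"))
  attr(out, "rescore_log") <- if (length(log)) log else NULL
  attr(out, "truth") <- attr(responses, "truth")
  out
}

check_connectivity <- function(responses) {
  obs <- !is.na(unclass(responses))
  I <- ncol(obs)
  adj <- crossprod(obs) > 0
  comp <- rep(NA_integer_, I); cur <- 0L
  for (s in seq_len(I)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L; queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur; queue <- c(queue, nb)
    }
  }
  if (max(comp) > 1L) {
    parts <- split(colnames(responses), comp)
    stop("design is disconnected; item components: ",
         paste(vapply(parts, paste, "", collapse = "+"), collapse = " | "))
  }
  invisible(TRUE)
}
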