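# Independent oracles used across the suite. These deliberately avoid the
# package's computation paths: the partial likelihood is written out
# naively in R, linkage is merged by exhaustive pairwise search, and rank
# scores are enumerated by hand.

# Naive Efron partial log-likelihood for a single covariate.
efron_loglik_oracle <- function(beta, time, status, x) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(w[R]) - (l / d) * sum(w[D]))
    }
  }
  ll
}

# Same formula evaluated for a whole vector of betas at once (the naive
# per-event-time loop, vectorized across the grid only).
efron_loglik_grid_oracle <- function(betas, time, status, x) {
  W <- exp(outer(x, betas)) # n x G
  ll <- numeric(length(betas))
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(x[D]) * betas
    WD <- colSums(W[D, , drop = FALSE])
    WR <- colSums(W[R, , drop = FALSE])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(WR - (l / d) * WD)
    }
  }
  ll
}

# Brute-force maximization over [-5, 5]: full 0.01-step sweep, then a
# 1e-4-step sweep around the coarse argmax (the partial likelihood is
# concave in beta, so the refinement is exact at 1e-4 resolution).
grid_max_oracle <- function(time, status, x) {
  coarse <- seq(-5, 5, by = 0.01)
  ll <- efron_loglik_grid_oracle(coarse, time, status, x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(max(-5, b0 - 0.02), min(5, b0 + 0.02), by = 1e-4)
  llf <- efron_loglik_grid_oracle(fine, time, status, x)
  fine[which.max(llf)]
}

# Exhaustive complete-linkage agglomeration on a distance matrix:
# returns the sorted merge heights.
complete_linkage_heights_oracle <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# Rank-z set score by explicit enumeration (per sample loops).
rank_set_score_oracle <- function(expr, genes_up, genes_down = NULL) {
  out <- numeric(ncol(expr))
  for (s in seq_len(ncol(expr))) {
    r <- rank(expr[, s], ties.method = "average")
    z <- (r - mean(r)) / sd(r)
    names(z) <- rownames(expr)
    out[s] <- mean(z[genes_up])
    if (!is.null(genes_down)) out[s] <- out[s] - mean(z[genes_down])
  }
  out
}

# Small cohort with a single step-effect marker, used by several tests.
toy_step_cohort <- function(n = 200, hr = 3, cut_q = 0.5, seed = 1,
                            baseline = 0.15, censor = 0.08) {
  cfg <- sim_config(
    n_patients = max(n, 20),
    marker_names = "marker",
    target_corr = matrix(1, 1, 1, dimnames = list("marker", "marker")),
    clinical_spec = list(
      sex = c(Male = 142, Female = 55) / 197,
      cisplatin = c(">=200" = 126, "<200" = 67) / 193
    ),
    true_effects = list(LRC = c(marker = log(hr),
                                "cisplatin:<200" = log(2.57))),
    true_cutoffs = c(marker = cut_q),
    baseline_hazard = c(LRC = baseline, DM = 0.02),
    death_rate = 0.05, censor_rate = censor, follow_up_years = 9,
    seed = seed)
  simulate_cohort(cfg, n = n)
}

# exhaustive all-subsets AIC oracle (<= 2^k fits)
exhaustive_aic_oracle <- function(d, time, event, vars) {
  null_aic <- NULL
  best <- list(vars = NULL, aic = Inf)
  k <- length(vars)
  for (mask in 0:(2^k - 1)) {
    sub <- vars[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    if (length(sub) == 0) {
      f <- fit_cox(d, time, event, vars)
      aic <- -2 * f$loglik_null
    } else {
      f <- tryCatch(suppressWarnings(fit_cox(d, time, event, sub)),
                    error = function(e) NULL)
      aic <- if (is.null(f) || !f$converged) Inf else f$aic
    }
    if (aic < best$aic) best <- list(vars = sort(sub), aic = aic)
  }
  best
}

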