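# Independent brute-force oracles used to validate the implementation
# paths. These deliberately use naive double loops / exhaustive
# enumeration, not the package's vectorized code.

# Direct-formula single-sample enrichment scores (naive loops).
naive_gsva <- function(mat, panel_genes, kernel = "gaussian", tau = 1,
                       bandwidth_floor = 1e-8) {
  p <- nrow(mat); n <- ncol(mat)
  z <- matrix(NA_real_, p, n)
  for (i in seq_len(p)) {
    for (j in seq_len(n)) {
      if (kernel == "gaussian") {
        h <- max(sd(mat[i, ]) / 4, bandwidth_floor)
        acc <- 0
        for (k in seq_len(n)) acc <- acc + pnorm((mat[i, j] - mat[i, k]) / h)
        z[i, j] <- acc / n
      } else if (kernel == "poisson") {
        acc <- 0
        for (k in seq_len(n)) acc <- acc + ppois(mat[i, j], mat[i, k] + 0.5)
        z[i, j] <- acc / n
      } else z[i, j] <- mat[i, j]
    }
  }
  member <- rownames(mat) %in% panel_genes
  out <- numeric(n)
  for (j in seq_len(n)) {
    rho <- rank(-z[, j], ties.method = "average")
    r <- abs(p / 2 - rho)
    ord <- order(rho, seq_len(p))
    m <- member[ord]; w <- r[ord]^tau
    denom <- sum(w[m])
    nu <- numeric(p); run <- 0
    for (l in seq_len(p)) {
      run <- run + if (m[l]) {
        if (denom > 0) w[l] / denom else 1 / sum(m)
      } else -1 / (p - sum(m))
      nu[l] <- run
    }
    out[j] <- max(0, max(nu)) + min(0, min(nu))
  }
  out
}

# Walk score for one explicit placement, by plain loop.
naive_walk <- function(r, in_panel, tau = 1) {
  p <- length(r); k <- sum(in_panel)
  w <- r^tau
  denom <- sum(w[in_panel])
  run <- 0; lo <- 0; hi <- 0
  for (l in seq_len(p)) {
    run <- run + if (in_panel[l]) {
      if (denom > 0) w[l] / denom else 1 / k
    } else -1 / (p - k)
    hi <- max(hi, run); lo <- min(lo, run)
  }
  hi + lo
}

# Fisher 2x2 p-values by explicit enumeration with binomial
# coefficients (no dhyper).
enum_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(ks, function(k)
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)),
    numeric(1))
  p_obs <- pr[match(a, ks)]
  list(p_two = min(1, sum(pr[pr <= p_obs * (1 + 1e-7)])),
       p_one = min(1, sum(pr[ks >= a])))
}

# Lower conditional-exact CI bound by bisection on the upper tail of
# the noncentral hypergeometric distribution (independent of uniroot).
bisect_exact_lo <- function(a, b, c, d, alpha = 0.025,
                            iter = 60) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  base <- dhyper(ks, r1, r2, c1)
  tail_ge <- function(psi) {
    w <- base * psi^(ks - min(ks))
    sum(w[ks >= a]) / sum(w)
  }
  lo <- 1e-8; hi <- 1e8
  for (i in seq_len(iter)) {
    mid <- sqrt(lo * hi)
    if (tail_ge(mid) < alpha) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# Closed-form OLS + t-statistics via lm(), the reference path for
# mlm_activity.
lm_activity_oracle <- function(expr, weights) {
  shared <- intersect(rownames(expr), rownames(weights))
  W <- weights[shared, , drop = FALSE]
  t(vapply(seq_len(ncol(expr)), function(j) {
    fit <- summary(lm(expr[shared, j] ~ W))
    tv <- fit$coefficients[-1, "t value"]
    names(tv) <- colnames(W)
    tv
  }, numeric(ncol(W))))
}
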