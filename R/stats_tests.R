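# Exact and resampling inference: Fisher 2x2 with two odds-ratio CI
# flavors, Wilcoxon / t / Cohen's d wrappers, the Jonckheere-Terpstra
# ordered trend test, and a seeded permutation association test.

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop("expected a 2x2 table")
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m != round(m)))
    stop("table cells must be non-negative integers")
  if (sum(m) < 1) stop("all-zero table")
  m
}

# Hypergeometric support and probabilities for fixed margins.
hyper_support <- function(m) {
  r1 <- m[1, 1] + m[1, 2]; r2 <- m[2, 1] + m[2, 2]
  c1 <- m[1, 1] + m[2, 1]
  k <- max(0, c1 - r2):min(r1, c1)
  list(k = k, prob = stats::dhyper(k, r1, r2, c1), x = m[1, 1])
}

#' Fisher's exact test for a 2x2 table
#'
#' Rows are exposure (EDY/LOY vs not), columns outcome (yes/no). The
#' one-sided p-value is the upper hypergeometric tail ("greater"); the
#' two-sided p-value uses the minimum-likelihood convention: the sum of
#' all table probabilities not exceeding the observed one (relative
#' tolerance 1e-7). The sample odds ratio is the cross-product
#' `ad / bc` (`Inf` when `bc = 0` and `ad > 0`). Both the Woolf
#' (log-normal) and the conditional-exact confidence interval are
#' reported.
#'
#' @param table 2x2 matrix, or the first of four counts `a, b, c, d`
#'   given row-wise.
#' @param b,c,d remaining counts when `table` is scalar `a`.
#' @param level confidence level for both intervals.
#' @param ci compute the two confidence intervals (default); `FALSE`
#'   returns p-values and the odds ratio only.
#' @return list of class `ContingencyResult`: `table`, `p_two_sided`,
#'   `p_one_sided`, `or_sample`, `ci_woolf`, `ci_conditional_exact`.
#' @export
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL,
                             level = 0.95, ci = TRUE) {
  if (length(table) == 1L)
    table <- matrix(c(table, b, c, d), nrow = 2, byrow = TRUE)
  m <- as_2x2(table)
  h <- hyper_support(m)
  p_obs <- h$prob[match(h$x, h$k)]
  p_two <- sum(h$prob[h$prob <= p_obs * (1 + 1e-7)])
  p_one <- sum(h$prob[h$k >= h$x])
  ad <- m[1, 1] * m[2, 2]; bc <- m[1, 2] * m[2, 1]
  or <- if (bc == 0) { if (ad > 0) Inf else NaN } else ad / bc
  structure(list(table = m,
                 p_two_sided = min(p_two, 1),
                 p_one_sided = min(p_one, 1),
                 or_sample = or,
                 ci_woolf = if (ci) suppressWarnings(
                   woolf_ci(m, level = level)) else c(NA_real_, NA_real_),
                 ci_conditional_exact = if (ci) tryCatch(
                   conditional_exact_ci(m, level = level),
                   error = function(e) c(NA_real_, NA_real_))
                 else c(NA_real_, NA_real_)),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  print(x$table)
  cat(sprintf("two-sided p = %.4g, one-sided p = %.4g\n",
              x$p_two_sided, x$p_one_sided))
  cat(sprintf("OR (cross-product) = %.4g, Woolf %s CI (%.4g, %.4g)\n",
              x$or_sample, "95%", x$ci_woolf[1], x$ci_woolf[2]))
  cat(sprintf("conditional-exact CI (%.4g, %.4g)\n",
              x$ci_conditional_exact[1], x$ci_conditional_exact[2]))
  invisible(x)
}

#' Woolf confidence interval for the odds ratio
#'
#' Normal approximation on the log odds ratio,
#' `exp(log(ad/bc) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell
#' is zero the Haldane-Anscombe correction (+0.5 to every cell) is
#' applied with a warning.
#'
#' @inheritParams fisher_exact_2x2
#' @return length-2 numeric vector `(lo, hi)`.
#' @export
woolf_ci <- function(table, b = NULL, c = NULL, d = NULL, level = 0.95) {
  if (length(table) == 1L)
    table <- matrix(c(table, b, c, d), nrow = 2, byrow = TRUE)
  m <- as_2x2(table)
  if (any(m == 0)) {
    warning("zero cell: applying Haldane-Anscombe +0.5 correction")
    m <- m + 0.5
  }
  lor <- log(m[1, 1] * m[2, 2] / (m[1, 2] * m[2, 1]))
  se <- sqrt(sum(1 / m))
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(lor + c(-1, 1) * z * se)
}

# Tail probabilities of Fisher's noncentral hypergeometric distribution
# at odds ratio psi, conditional on the observed margins.
noncentral_tail <- function(h, psi, lower) {
  # weights on log scale for stability at extreme psi
  lw <- log(h$prob) + h$k * log(psi)
  lw <- lw - max(lw)
  w <- exp(lw); w <- w / sum(w)
  if (lower) sum(w[h$k <= h$x]) else sum(w[h$k >= h$x])
}

#' Conditional-exact confidence interval for the odds ratio
#'
#' Inverts the tails of Fisher's noncentral hypergeometric distribution
#' given the table margins: the lower bound solves
#' `P(X >= x_obs | psi) = alpha/2` (0 when `x_obs` is minimal on the
#' support) and the upper bound solves `P(X <= x_obs | psi) = alpha/2`
#' (`Inf` when `x_obs` is maximal).
#'
#' @inheritParams fisher_exact_2x2
#' @param tol root-finding tolerance on log(psi).
#' @return length-2 numeric vector `(lo, hi)`; bounds may be 0 or `Inf`.
#' @export
conditional_exact_ci <- function(table, b = NULL, c = NULL, d = NULL,
                                 level = 0.95, tol = 1e-6) {
  if (length(table) == 1L)
    table <- matrix(c(table, b, c, d), nrow = 2, byrow = TRUE)
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate margins: a row or column of the table is empty")
  h <- hyper_support(m)
  alpha <- (1 - level) / 2
  solve_psi <- function(lower) {
    f <- function(lpsi) noncentral_tail(h, exp(lpsi), lower) - alpha
    lo <- -1; hi <- 1
    while (f(lo) * f(hi) > 0 && hi < 700) { lo <- lo - 5; hi <- hi + 5 }
    exp(stats::uniroot(f, c(lo, hi), tol = tol)$root)
  }
  lo <- if (h$x == min(h$k)) 0 else solve_psi(lower = FALSE)
  hi <- if (h$x == max(h$k)) Inf else solve_psi(lower = TRUE)
  c(lo, hi)
}

#' Wilcoxon rank-sum test p-value
#'
#' Exact null distribution for combined n <= 20 without ties; normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value)
}

#' Student's t-test
#'
#' @param x,y numeric samples, each with >= 2 values.
#' @param pooled use the pooled-variance (classic Student) form; `FALSE`
#'   gives Welch.
#' @return list with `t` and `p`.
#' @export
students_t <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  res <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(res$statistic), p = res$p.value)
}

#' Cohen's d with pooled standard deviation
#'
#' @inheritParams students_t
#' @return effect size `(mean(x) - mean(y)) / sd_pooled`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 values")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (sp2 == 0) stop("zero pooled variance")
  (mean(x) - mean(y)) / sqrt(sp2)
}

jt_statistic <- function(groups) {
  jt <- 0
  g <- length(groups)
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      cmp <- outer(groups[[i]], groups[[j]], "<")
      tie <- outer(groups[[i]], groups[[j]], "==")
      jt <- jt + sum(cmp) + 0.5 * sum(tie)
    }
  }
  jt
}

# enumerate all assignments of pooled values to ordered groups
jt_exact_p <- function(values, sizes, observed, increasing = TRUE) {
  n <- length(values)
  assign_rec <- function(remaining_idx, sizes_left) {
    if (length(sizes_left) == 1L)
      return(list(list(remaining_idx)))
    first <- utils::combn(remaining_idx, sizes_left[[1L]],
                          simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- assign_rec(setdiff(remaining_idx, f), sizes_left[-1L])
      out <- c(out, lapply(rest, function(r) c(list(f), r)))
    }
    out
  }
  parts <- assign_rec(seq_len(n), sizes)
  stats_all <- vapply(parts, function(p)
    jt_statistic(lapply(p, function(idx) values[idx])), numeric(1))
  if (increasing) mean(stats_all >= observed - 1e-12)
  else mean(stats_all <= observed + 1e-12)
}

#' Jonckheere-Terpstra ordered trend test
#'
#' Tests for a monotone trend across ordered groups using the sum of
#' pairwise Mann-Whitney counts (ties count one half). The default is
#' the normal approximation with tie-corrected variance; with
#' `exact = TRUE` (forced on when total n <= 12 and `exact = NULL`)
#' the permutation null is enumerated exhaustively.
#'
#' @param groups list of numeric vectors in increasing group order.
#' @param alternative `"increasing"` (default) or `"decreasing"`.
#' @param exact logical or `NULL` (auto: exact when total n <= 12).
#' @return list of class `TrendResult`: `jt_statistic`, `z`,
#'   `p_one_sided`, `method`.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("increasing",
                                                "decreasing"),
                                exact = NULL) {
  alternative <- match.arg(alternative)
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 ordered groups")
  if (any(!lengths(groups))) stop("every group must be non-empty")
  sizes <- lengths(groups)
  n <- sum(sizes)
  jt <- jt_statistic(groups)
  pooled <- unlist(groups)
  ties <- table(pooled)
  mu <- (n^2 - sum(sizes^2)) / 4
  t1 <- n * (n - 1) * (2 * n + 5) -
    sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
    sum(ties * (ties - 1) * (2 * ties + 5))
  t2 <- sum(sizes * (sizes - 1) * (sizes - 2)) *
    sum(ties * (ties - 1) * (ties - 2))
  t3 <- sum(sizes * (sizes - 1)) * sum(ties * (ties - 1))
  v <- t1 / 72 + t2 / (36 * n * (n - 1) * (n - 2)) +
    t3 / (8 * n * (n - 1))
  z <- if (v > 0) (jt - mu) / sqrt(v) else 0
  if (alternative == "decreasing") z <- -z
  if (is.null(exact)) exact <- n <= 12
  p <- if (exact)
    jt_exact_p(pooled, sizes, jt, increasing = alternative == "increasing")
  else
    stats::pnorm(z, lower.tail = FALSE)
  structure(list(jt_statistic = jt, z = z, p_one_sided = p,
                 method = if (exact) "exact" else "normal"),
            class = "TrendResult")
}

#' @export
print.TrendResult <- function(x, ...) {
  cat(sprintf("Jonckheere-Terpstra: JT = %g, z = %.3f, one-sided p = %.4g (%s)\n",
              x$jt_statistic, x$z, x$p_one_sided, x$method))
  invisible(x)
}

#' Permutation test for a group difference in means
#'
#' The observed statistic is `mean(values[label == 1]) -
#' mean(values[label == 0])`; the null is built by shuffling labels
#' with a seeded RNG. The empirical two-sided p-value uses the add-one
#' estimator, so `p >= 1 / (n_resamples + 1)`; `z` standardizes the
#' observed statistic against the permutation null.
#'
#' @param values numeric vector.
#' @param labels binary (0/1 or logical) vector, same length.
#' @param n_resamples number of label shuffles (default 10000).
#' @param seed RNG seed.
#' @return list of class `PermResult`: `observed_diff`, `z`,
#'   `p_two_sided`, `n_resamples`, `seed`.
#' @export
permutation_assoc <- function(values, labels, n_resamples = 10000,
                              seed = 1) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(values) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 1 || n0 < 1) stop("both label classes must be non-empty")
  obs <- mean(values[labels == 1L]) - mean(values[labels == 0L])
  n <- length(values)
  total <- sum(values)
  nulls <- with_seed(seed, vapply(seq_len(n_resamples), function(b) {
    idx <- sample.int(n, n1)
    s1 <- sum(values[idx])
    s1 / n1 - (total - s1) / n0
  }, numeric(1)))
  sd_null <- stats::sd(nulls)
  if (!is.finite(sd_null) || sd_null == 0) {
    warning("degenerate permutation null (sd = 0); z set to 0")
    z <- 0
    p <- 1
  } else {
    z <- (obs - mean(nulls)) / sd_null
    p <- (1 + sum(abs(nulls) >= abs(obs) - 1e-12)) / (n_resamples + 1)
  }
  structure(list(observed_diff = obs, z = z, p_two_sided = p,
                 n_resamples = n_resamples, seed = seed),
            class = "PermResult")
}

#' @export
print.PermResult <- function(x, ...) {
  cat(sprintf("permutation test: diff = %.4g, Z = %.3f, p = %.4g (%d resamples)\n",
              x$observed_diff, x$z, x$p_two_sided, x$n_resamples))
  invisible(x)
}
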