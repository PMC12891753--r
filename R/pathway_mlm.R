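# Footprint-style pathway activity scoring: per sample, an ordinary
# least-squares fit of the expression vector on the pathway weight
# matrix; the activity is the t-statistic of each pathway coefficient.

#' Read a long-format pathway weight table
#'
#' TSV with header columns `gene`, `pathway`, `weight`. The shipped toy
#' fixture (`system.file("extdata", "toy_pathway_weights_synthetic.tsv",
#' package = "edyloy")`) is synthetic; real analyses should supply a
#' published footprint weight matrix.
#'
#' @param path file path.
#' @param top optional: keep only the `top` genes of largest absolute
#'   weight per pathway (default all).
#' @return genes-by-pathways numeric weight matrix.
#' @export
read_pathway_weights <- function(path, top = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "pathway", "weight")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("weight table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(top)) {
    df <- do.call(rbind, lapply(split(df, df$pathway), function(d)
      d[order(-abs(d$weight)), ][seq_len(min(top, nrow(d))), ]))
  }
  genes <- sort(unique(df$gene))
  pws <- sort(unique(df$pathway))
  w <- matrix(0, length(genes), length(pws),
              dimnames = list(genes, pws))
  w[cbind(match(df$gene, genes), match(df$pathway, pws))] <- df$weight
  if (any(colSums(w != 0) == 0))
    stop("pathway with all-zero weights")
  w
}

#' Pathway activity by multivariate linear model
#'
#' For each sample j, fits `y_j ~ intercept + W` by ordinary least
#' squares over the genes shared between the expression matrix and the
#' weight matrix; the activity score of a pathway is the t-statistic of
#' its coefficient. Positive scores indicate activation. Input should
#' be a normalized, log-transformed matrix.
#'
#' @param expr genes-by-samples matrix.
#' @param weights genes-by-pathways weight matrix
#'   (see [read_pathway_weights()]).
#' @return samples-by-pathways matrix of t-values.
#' @export
mlm_activity <- function(expr, weights) {
  shared <- intersect(rownames(expr), rownames(weights))
  k <- ncol(weights)
  if (length(shared) < k + 2)
    stop("need at least ", k + 2, " shared genes; have ", length(shared))
  X <- cbind(`(intercept)` = 1, weights[shared, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear pathway(s): ",
         paste(drop_cols, collapse = ", "))
  }
  Y <- as.matrix(expr[shared, , drop = FALSE])
  coefs <- qr.coef(qx, Y)                      # (k+1) x samples
  res <- Y - X %*% coefs
  df_res <- length(shared) - ncol(X)
  sigma2 <- colSums(res^2) / df_res
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)))
  se <- sqrt(outer(xtx_inv_diag, sigma2))      # (k+1) x samples
  tvals <- coefs / se
  tvals[!is.finite(tvals)] <- 0
  t(tvals[-1L, , drop = FALSE])                # drop intercept
}

#' Compare a pathway's activity between EDY and non-EDY cells
#'
#' Wilcoxon rank-sum test on the activity scores of one pathway,
#' reporting the direction of the median difference (positive = higher
#' in the EDY class).
#'
#' @param activities samples-by-pathways matrix from [mlm_activity()].
#' @param edy_labels logical/binary vector, one per sample/cell.
#' @param pathway pathway (column) name.
#' @return list with `p`, `direction` (+1/0/-1) and `median_diff`.
#' @export
compare_activity_by_group <- function(activities, edy_labels, pathway) {
  if (!pathway %in% colnames(activities))
    stop("unknown pathway: ", pathway)
  lab <- as.logical(edy_labels)
  a <- activities[, pathway]
  x <- a[lab]; y <- a[!lab]
  if (!length(x) || !length(y))
    stop("both label classes must be non-empty")
  md <- stats::median(x) - stats::median(y)
  list(p = wilcoxon_rank_sum(x, y),
       direction = sign(md),
       median_diff = md)
}
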