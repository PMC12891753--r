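# Threshold calibration from reference samples and bulk EDY calling.

#' Define an EDY threshold rule
#'
#' Three rules cover the cohort-specific calibrations: the minimum
#' score among control-treated samples (`min_of_controls`), the maximum
#' score among female reference samples after removing an explicit
#' exclusion list (`max_of_reference`), or a fixed value (`fixed`).
#'
#' @param kind rule kind.
#' @param fixed_value threshold for `kind = "fixed"`.
#' @param exclude_reference_ids sample ids removed from the reference
#'   set before taking the maximum (`kind = "max_of_reference"`).
#' @return list of class `ThresholdRule`.
#' @export
threshold_rule <- function(kind = c("min_of_controls", "max_of_reference",
                                    "fixed"),
                           fixed_value = NULL,
                           exclude_reference_ids = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed" && (is.null(fixed_value) || !is.finite(fixed_value)))
    stop("fixed rule requires a finite fixed_value")
  structure(list(kind = kind, fixed_value = fixed_value,
                 exclude_reference_ids = exclude_reference_ids),
            class = "ThresholdRule")
}

#' Calibrate the EDY threshold from reference samples
#'
#' @param scores data.frame with `sample_id` and `score` (from
#'   [gsva_scores()]).
#' @param metadata data.frame with `sample_id` and `role` (one of
#'   `"case"`, `"control"`, `"reference"`).
#' @param rule a [threshold_rule()].
#' @return scalar threshold.
#' @export
calibrate_threshold <- function(scores, metadata, rule) {
  stopifnot(inherits(rule, "ThresholdRule"))
  if (rule$kind == "fixed") return(rule$fixed_value)
  role <- metadata$role[match(scores$sample_id, metadata$sample_id)]
  if (rule$kind == "min_of_controls") {
    s <- scores$score[role %in% "control"]
    if (!length(s)) stop("no control samples to calibrate from")
    return(min(s))
  }
  keep <- role %in% "reference"
  if (!is.null(rule$exclude_reference_ids)) {
    unknown <- setdiff(rule$exclude_reference_ids,
                       scores$sample_id[keep])
    if (length(unknown))
      stop("exclusions name non-reference samples: ",
           paste(unknown, collapse = ", "))
    keep <- keep & !(scores$sample_id %in% rule$exclude_reference_ids)
  }
  s <- scores$score[keep]
  if (!length(s)) stop("no reference samples to calibrate from")
  max(s)
}

#' Flag candidate reference outliers
#'
#' Convenience helper listing reference samples whose score exceeds
#' Q3 + 1.5 IQR of the reference scores. Intended for analyst review
#' when choosing `exclude_reference_ids`; never applied automatically.
#'
#' @inheritParams calibrate_threshold
#' @return character vector of sample ids (possibly empty).
#' @export
flag_reference_outliers <- function(scores, metadata) {
  role <- metadata$role[match(scores$sample_id, metadata$sample_id)]
  ref <- scores[role %in% "reference", , drop = FALSE]
  if (!nrow(ref)) return(character(0))
  q <- stats::quantile(ref$score, c(0.25, 0.75), names = FALSE)
  ref$sample_id[ref$score > q[2] + 1.5 * (q[2] - q[1])]
}

#' Call EDY status from scores
#'
#' A sample is EDY iff its score is strictly below the threshold; a
#' score exactly at the threshold is non-EDY.
#'
#' @param scores data.frame with `sample_id` and `score`.
#' @param threshold finite scalar.
#' @return data.frame `sample_id`, `score`, `threshold`, `edy`.
#' @export
call_edy <- function(scores, threshold) {
  stopifnot(is.finite(threshold))
  data.frame(sample_id = scores$sample_id,
             score = scores$score,
             threshold = threshold,
             edy = scores$score < threshold,
             stringsAsFactors = FALSE)
}

#' Cross-tabulate EDY status against two groups
#'
#' @param calls output of [call_edy()].
#' @param metadata data.frame with `sample_id` and a grouping column.
#' @param group_a,group_b the two group levels to tabulate.
#' @param group_col name of the grouping column (default `"group"`).
#' @return 2x2 integer matrix, rows `EDY`/`non-EDY`, columns the two
#'   groups.
#' @export
edy_by_group_table <- function(calls, metadata, group_a, group_b,
                               group_col = "group") {
  grp <- metadata[[group_col]][match(calls$sample_id, metadata$sample_id)]
  tab <- vapply(c(group_a, group_b), function(g) {
    in_g <- grp %in% g
    if (!any(in_g)) stop("group has no samples: ", g)
    c(sum(calls$edy & in_g), sum(!calls$edy & in_g))
  }, integer(2))
  dimnames(tab) <- list(c("EDY", "non-EDY"), c(group_a, group_b))
  tab
}

#' Summarize EDY calls against a binary progression outcome
#'
#' Builds the exposure-by-outcome 2x2 table (rows EDY/non-EDY, columns
#' progressor/non-progressor), runs [fisher_exact_2x2()], and reports
#' the progression proportion in each stratum.
#'
#' @param calls output of [call_edy()].
#' @param metadata data.frame with `sample_id` and `outcome`
#'   (`"progressor"` / `"non_progressor"`).
#' @return list with `table`, `contingency` ([fisher_exact_2x2()]
#'   result), `prop_progress_edy`, `prop_progress_nonedy` (percent).
#' @export
summarize_edy_outcome <- function(calls, metadata) {
  if (!"outcome" %in% names(metadata))
    stop("metadata is missing column(s): outcome")
  out <- metadata$outcome[match(calls$sample_id, metadata$sample_id)]
  keep <- out %in% c("progressor", "non_progressor")
  calls <- calls[keep, , drop = FALSE]
  out <- out[keep]
  prog <- out == "progressor"
  tab <- matrix(c(sum(calls$edy & prog), sum(calls$edy & !prog),
                  sum(!calls$edy & prog), sum(!calls$edy & !prog)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("EDY", "non-EDY"),
                                c("progressor", "non_progressor")))
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(table = tab,
       contingency = fisher_exact_2x2(tab),
       prop_progress_edy = pct(tab[1, 1], sum(tab[1, ])),
       prop_progress_nonedy = pct(tab[2, 1], sum(tab[2, ])))
}
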