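# Y-chromosome signal from segmented copy number, cellularity/ploidy
# adjustment, and LOY calling.
#
# Model: segment values are absolute copy-number estimates with the
# autosomal diploid state = 2, so a normal male Y sits at 1. A bulk
# sample with tumor-cell fraction (cellularity) rho mixes tumor cells
# carrying c_t Y copies with normal male cells carrying one:
#   raw = (1 - rho) * 1 + rho * c_t.
# Solving for c_t and expressing the dosage relative to tumor ploidy
# psi (factor 2/psi, so a genome-doubled tumor retaining 2 Y copies
# scores 1) gives the adjusted Y signal.

#' Read a SEG-like segment table
#'
#' TSV with header columns `sample_id`, `chrom`, `start`, `end`,
#' `value` (1-based inclusive coordinates; `value` on the absolute
#' copy-number scale).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_segments <- function(path) {
  seg <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "value")
  missing <- setdiff(need, names(seg))
  if (length(missing))
    stop("segment table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(seg$start > seg$end))
    stop("segment with start > end")
  seg
}

#' Read a per-sample purity/ploidy table
#'
#' TSV with columns `sample_id`, `cellularity`, `ploidy`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_purity_ploidy <- function(path) {
  pp <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "cellularity", "ploidy"), names(pp))
  if (length(missing))
    stop("purity/ploidy table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(pp$cellularity <= 0 | pp$cellularity > 1))
    stop("cellularity must lie in (0, 1]")
  if (any(pp$ploidy <= 0)) stop("ploidy must be positive")
  pp
}

#' Raw Y-chromosome signal
#'
#' Length-weighted mean copy number over the Y-chromosome segments of
#' one sample; segments with missing values are dropped first.
#'
#' @param segments data.frame as from [read_segments()].
#' @param sample_id sample to evaluate.
#' @return list with `raw` and `n_segments_used`.
#' @export
y_signal_raw <- function(segments, sample_id) {
  seg <- segments[segments$sample_id == sample_id &
                  normalize_chrom(segments$chrom) == "Y" &
                  is.finite(segments$value), , drop = FALSE]
  if (!nrow(seg))
    stop("no usable Y segments for sample ", sample_id)
  len <- seg$end - seg$start + 1
  list(raw = sum(len * seg$value) / sum(len),
       n_segments_used = nrow(seg))
}

#' Cellularity- and ploidy-adjusted Y signal
#'
#' Inverts the normal/tumor mixture (`c_t = (raw - (1 - rho)) / rho`)
#' and rescales by `2 / psi`. A negative tumor-cell estimate (noise
#' below the admixture floor) is clipped to 0 with a warning.
#'
#' @param raw raw Y signal (absolute copy-number scale, normal male = 1).
#' @param cellularity tumor-cell fraction rho in (0, 1].
#' @param ploidy tumor-cell ploidy psi > 0.
#' @return adjusted Y signal (normal male = 1, complete loss = 0).
#' @export
adjust_y_signal <- function(raw, cellularity, ploidy) {
  if (any(cellularity <= 0) || any(cellularity > 1))
    stop("cellularity must lie in (0, 1]")
  if (any(ploidy <= 0)) stop("ploidy must be positive")
  c_t <- (raw - (1 - cellularity)) / cellularity
  if (any(c_t < -1e-8))
    warning("negative tumor Y copy estimate clipped to 0")
  c_t <- pmax(c_t, 0)
  c_t * (2 / ploidy)
}

#' Convert read-depth ratios to absolute copy number
#'
#' For inputs on the depth-ratio scale (genome average = 1) rather than
#' absolute copy number, multiply by the average genome copy number of
#' the mixture, `rho * psi + 2 * (1 - rho)`.
#'
#' @param value ratio-scale values.
#' @inheritParams adjust_y_signal
#' @return absolute copy-number values.
#' @export
ratio_to_cn <- function(value, cellularity, ploidy) {
  value * (cellularity * ploidy + 2 * (1 - cellularity))
}

#' Call LOY from the adjusted Y signal
#'
#' @param adjusted adjusted Y signal(s).
#' @param threshold strict cutoff in (0, 1]; default 0.5 (loss in the
#'   majority of tumor cells).
#' @return logical vector, `TRUE` = LOY.
#' @export
call_loy <- function(adjusted, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  adjusted < threshold
}
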