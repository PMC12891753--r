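# Single-cell QC, Y-panel selection by expression prevalence, zero-UMI
# EDY classification, binned-control module scores, per-sample EDY
# fractions and group-wise expression frequency.

#' Single-cell QC configuration
#'
#' Defaults follow common droplet-data practice: keep cells expressing
#' more than 200 and fewer than 8000 genes with under 10% mitochondrial
#' UMIs, then keep genes detected in more than 0.1% of the remaining
#' cells.
#'
#' @param min_genes,max_genes strict bounds on genes detected per cell.
#' @param max_mito_fraction strict upper bound on the mitochondrial UMI
#'   fraction.
#' @param min_cell_fraction_per_gene strict lower bound on the fraction
#'   of cells a gene must be detected in.
#' @return list of class `CellQcConfig`.
#' @export
cell_qc_config <- function(min_genes = 200, max_genes = 8000,
                           max_mito_fraction = 0.10,
                           min_cell_fraction_per_gene = 0.001) {
  stopifnot(min_genes > 0, min_genes < max_genes,
            max_mito_fraction > 0, max_mito_fraction < 1,
            min_cell_fraction_per_gene > 0,
            min_cell_fraction_per_gene < 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction,
                 min_cell_fraction_per_gene = min_cell_fraction_per_gene),
            class = "CellQcConfig")
}

#' Quality-control filter for a UMI count matrix
#'
#' Cells must express strictly more than `min_genes` and strictly fewer
#' than `max_genes` genes and carry strictly less than
#' `max_mito_fraction` mitochondrial UMIs; genes must then be detected
#' in strictly more than `min_cell_fraction_per_gene` of the surviving
#' cells. Mitochondrial genes are recognized by the "MT-"/"mt-" symbol
#' prefix or an explicit annotation (`chromosome == "MT"`).
#'
#' @param counts genes-by-cells raw UMI matrix (dense or dgCMatrix).
#' @param gene_annotations optional data.frame with `symbol` and
#'   `chromosome` to identify mitochondrial genes.
#' @param cfg [cell_qc_config()].
#' @return list with `counts` (filtered) and `report` (cells/genes
#'   removed at each step).
#' @export
qc_filter <- function(counts, gene_annotations = NULL,
                      cfg = cell_qc_config()) {
  genes <- rownames(counts)
  mito <- grepl("^(MT-|mt-)", genes)
  if (!is.null(gene_annotations)) {
    mito_sym <- gene_annotations$symbol[
      normalize_chrom(gene_annotations$chromosome) %in% c("MT", "M")]
    mito <- mito | genes %in% mito_sym
  }
  n_genes_per_cell <- Matrix::colSums(counts > 0)
  tot <- Matrix::colSums(counts)
  mito_frac <- ifelse(tot > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)
  keep_cells <- n_genes_per_cell > cfg$min_genes &
    n_genes_per_cell < cfg$max_genes &
    mito_frac < cfg$max_mito_fraction
  if (!any(keep_cells)) stop("no cells pass QC")
  filtered <- counts[, keep_cells, drop = FALSE]
  detected_frac <- Matrix::rowSums(filtered > 0) / ncol(filtered)
  keep_genes <- detected_frac > cfg$min_cell_fraction_per_gene
  report <- list(
    cells_in = ncol(counts),
    cells_removed_gene_count = sum(!(n_genes_per_cell > cfg$min_genes &
                                       n_genes_per_cell < cfg$max_genes)),
    cells_removed_mito = sum((n_genes_per_cell > cfg$min_genes &
                                n_genes_per_cell < cfg$max_genes) &
                               !(mito_frac < cfg$max_mito_fraction)),
    cells_kept = sum(keep_cells),
    genes_in = nrow(counts),
    genes_removed = sum(!keep_genes),
    genes_kept = sum(keep_genes))
  list(counts = filtered[keep_genes, , drop = FALSE], report = report)
}

#' Log-normalize a UMI count matrix
#'
#' Per cell: `x -> log(1 + scale * x / total_cell_counts)`.
#'
#' @param counts genes-by-cells raw UMI matrix.
#' @param scale library-size scale factor (default 1e4).
#' @return matrix of the same shape.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop("cell with zero total counts")
  m <- as.matrix(counts)
  log1p(scale * sweep(m, 2L, tot, "/"))
}

#' Y-panel selection configuration for single-cell data
#'
#' @param min_avg_norm_expr strict lower bound on mean normalized
#'   expression (default 0.05).
#' @param min_expressing_cell_fraction strict lower bound on the
#'   fraction of cells with a nonzero raw count (default 0.05).
#' @param combine `"or"` (default; either criterion admits a gene) or
#'   `"and"`.
#' @return list of class `YPanelSelectConfig`.
#' @export
y_panel_select_config <- function(min_avg_norm_expr = 0.05,
                                  min_expressing_cell_fraction = 0.05,
                                  combine = c("or", "and")) {
  stopifnot(min_avg_norm_expr >= 0, min_expressing_cell_fraction >= 0)
  structure(list(min_avg_norm_expr = min_avg_norm_expr,
                 min_expressing_cell_fraction = min_expressing_cell_fraction,
                 combine = match.arg(combine)),
            class = "YPanelSelectConfig")
}

#' Select expressed Y genes from male single-cell data
#'
#' A Y-chromosome gene enters the panel when its mean normalized
#' expression exceeds `min_avg_norm_expr` or (by default) it is
#' detected in more than `min_expressing_cell_fraction` of cells. Run
#' on male cells only; detection sensitivity is dataset-specific, so an
#' explicit `dataset_specific` panel via [build_y_panel()] can override
#' the data-driven choice.
#'
#' @param norm_matrix log-normalized matrix (male cells).
#' @param raw_counts matching raw UMI matrix.
#' @param y_genes character vector of Y-chromosome gene symbols, or an
#'   annotation data.frame with `symbol`/`chromosome`.
#' @param cfg [y_panel_select_config()].
#' @param species passed through to the panel object.
#' @return `YGenePanel` with `source = "dataset_specific"`.
#' @export
select_y_genes_sc <- function(norm_matrix, raw_counts, y_genes,
                              cfg = y_panel_select_config(),
                              species = "human") {
  if (is.data.frame(y_genes))
    y_genes <- y_genes$symbol[normalize_chrom(y_genes$chromosome) == "Y"]
  y_genes <- intersect(y_genes, rownames(norm_matrix))
  if (!length(y_genes))
    stop("no Y genes in the matrix; supply a dataset_specific panel")
  avg <- rowMeans(norm_matrix[y_genes, , drop = FALSE])
  frac <- Matrix::rowSums(raw_counts[y_genes, , drop = FALSE] > 0) /
    ncol(raw_counts)
  pass_avg <- avg > cfg$min_avg_norm_expr
  pass_frac <- frac > cfg$min_expressing_cell_fraction
  keep <- if (cfg$combine == "or") pass_avg | pass_frac else
    pass_avg & pass_frac
  if (!any(keep))
    stop("no Y genes pass the expression filters; ",
         "supply a dataset_specific panel")
  build_y_panel(species = species, mode = "dataset_specific",
                genes = y_genes[keep])
}

#' Zero-UMI EDY classification of cells
#'
#' A cell is EDY iff every panel gene has zero raw UMIs in that cell.
#' Normalized values are never consulted.
#'
#' @param raw_counts genes-by-cells raw UMI matrix.
#' @param panel `YGenePanel` or character vector.
#' @return data.frame `cell_id`, `edy`, plus attribute `"panel_used"`.
#' @export
call_edy_cells <- function(raw_counts, panel) {
  genes <- match_panel(panel, rownames(raw_counts))
  if (!length(genes))
    stop("no panel genes present in the count matrix")
  panel_sum <- Matrix::colSums(raw_counts[genes, , drop = FALSE])
  res <- data.frame(cell_id = colnames(raw_counts) %||%
                      as.character(seq_along(panel_sum)),
                    edy = panel_sum == 0,
                    stringsAsFactors = FALSE)
  attr(res, "panel_used") <- genes
  res
}

#' Per-sample EDY cell fractions with ordered group labels
#'
#' @param calls output of [call_edy_cells()].
#' @param metadata data.frame with `cell_id`, `sample_id`, `group`
#'   (ordered factor or character) and optionally `sex`.
#' @return data.frame `sample_id`, `group`, `n_cells`, `n_edy`,
#'   `fraction`, ordered by group then sample.
#' @export
edy_fraction_per_sample <- function(calls, metadata) {
  md <- metadata[match(calls$cell_id, metadata$cell_id), , drop = FALSE]
  if ("sex" %in% names(md) && any(md$sex %in% "female"))
    warning("female cells present; EDY fractions are only meaningful ",
            "for male cells")
  agg <- stats::aggregate(calls$edy, by = list(sample_id = md$sample_id),
                          FUN = function(e) c(n = length(e), edy = sum(e)))
  res <- data.frame(sample_id = agg$sample_id,
                    n_cells = agg$x[, "n"],
                    n_edy = agg$x[, "edy"],
                    stringsAsFactors = FALSE)
  res$fraction <- res$n_edy / res$n_cells
  grp <- md$group[match(res$sample_id, md$sample_id)]
  if (is.factor(metadata$group))
    grp <- factor(grp, levels = levels(metadata$group), ordered = TRUE)
  res$group <- grp
  res[order(res$group, res$sample_id),
      c("sample_id", "group", "n_cells", "n_edy", "fraction")]
}

#' Module-score configuration
#'
#' @param n_bins number of equal-frequency bins on average expression.
#' @param n_control_per_gene control genes drawn (with replacement)
#'   from each set gene's bin.
#' @param seed RNG seed for the control draws.
#' @return list of class `ModuleScoreConfig`.
#' @export
module_score_config <- function(n_bins = 24, n_control_per_gene = 100,
                                seed = 1) {
  stopifnot(n_bins >= 2, n_control_per_gene >= 1)
  structure(list(n_bins = n_bins, n_control_per_gene = n_control_per_gene,
                 seed = seed),
            class = "ModuleScoreConfig")
}

#' Binned-control gene-set module score per cell
#'
#' All genes are binned into `n_bins` equal-frequency bins by their
#' average expression across cells; for every gene in the set,
#' `n_control_per_gene` control genes are drawn with replacement from
#' that gene's bin (set genes themselves are excluded from the control
#' pool unless the bin holds nothing else). The score is the mean
#' expression of the set minus the mean expression of the control
#' draw, per cell, so a score near 0 means the set behaves like
#' expression-matched background.
#'
#' @param norm_matrix genes-by-cells log-normalized matrix.
#' @param gene_set character vector of gene symbols.
#' @param cfg [module_score_config()].
#' @return numeric vector, one score per cell.
#' @export
module_score <- function(norm_matrix, gene_set,
                         cfg = module_score_config()) {
  if (cfg$n_bins > nrow(norm_matrix))
    stop("n_bins exceeds the number of genes")
  set_genes <- intersect(gene_set, rownames(norm_matrix))
  if (!length(set_genes))
    stop("gene set has no genes in the matrix")
  avg <- rowMeans(norm_matrix)
  # equal-frequency bins on average expression (ties broken by order)
  bin <- ceiling(rank(avg, ties.method = "first") *
                   cfg$n_bins / length(avg))
  set_idx <- match(set_genes, rownames(norm_matrix))
  ctrl_idx <- with_seed(cfg$seed, {
    unlist(lapply(set_idx, function(gi) {
      pool <- setdiff(which(bin == bin[[gi]]), set_idx)
      if (!length(pool)) pool <- which(bin == bin[[gi]])
      pool[sample.int(length(pool), cfg$n_control_per_gene,
                      replace = TRUE)]
    }))
  })
  set_mean <- colMeans(norm_matrix[set_genes, , drop = FALSE])
  ctrl_mean <- colMeans(norm_matrix[ctrl_idx, , drop = FALSE])
  unname(set_mean - ctrl_mean)
}

#' Per-group expression frequency of one gene
#'
#' Fraction of cells with a nonzero raw count, per group.
#'
#' @param raw_counts genes-by-cells raw UMI matrix.
#' @param gene gene symbol.
#' @param grouping vector of group labels, one per cell.
#' @return data.frame `group`, `n_cells`, `n_expressing`, `frequency`.
#' @export
expression_frequency <- function(raw_counts, gene, grouping) {
  if (!gene %in% rownames(raw_counts))
    stop("gene not in matrix: ", gene)
  stopifnot(length(grouping) == ncol(raw_counts))
  expressed <- as.numeric(raw_counts[gene, ]) > 0
  groups <- unique(grouping)
  res <- do.call(rbind, lapply(groups, function(g) {
    in_g <- grouping == g
    data.frame(group = g, n_cells = sum(in_g),
               n_expressing = sum(expressed & in_g),
               stringsAsFactors = FALSE)
  }))
  res$frequency <- res$n_expressing / res$n_cells
  res
}
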