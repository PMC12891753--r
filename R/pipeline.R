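# End-to-end orchestration: bulk scores -> threshold -> calls ->
# contingency statistics; single-cell QC -> EDY -> trend; segments ->
# adjusted signal -> LOY -> outcome association. Configs are plain
# lists or YAML files; every run can write its outputs plus a manifest
# sufficient to reproduce them.

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  config
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, config, extra = list()) {
  manifest <- c(list(
    package = "edyloy",
    version = as.character(utils::packageVersion("edyloy")),
    config_md5 = config_fingerprint(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

panel_from_config <- function(pc, annotations = NULL) {
  if (is.null(pc)) pc <- list(mode = "fixed_human_12", species = "human")
  build_y_panel(annotations = annotations,
                species = pc$species %||% "human",
                mode = pc$mode %||% "fixed_human_12",
                genes = pc$genes)
}

rule_from_config <- function(rc) {
  if (is.null(rc)) rc <- list(kind = "max_of_reference")
  threshold_rule(kind = rc$kind %||% "max_of_reference",
                 fixed_value = rc$fixed_value,
                 exclude_reference_ids = rc$exclude_reference_ids)
}

#' Run the bulk EDY pipeline
#'
#' Expression matrix -> Y-panel scores -> calibrated threshold -> EDY
#' calls -> outcome contingency statistics. The config (list or YAML
#' path) understands: `expression` (path or matrix), `metadata` (path
#' or data.frame with `sample_id`, `role`, and `outcome` for the
#' association step), `gene_map` (optional path), `panel` (list:
#' `mode`, `species`, `genes`), `rule` (list: `kind`, `fixed_value`,
#' `exclude_reference_ids`), `gsva` (list: `kernel`, `tau`,
#' `score_mode`) and `out_dir` (optional; when set, writes
#' `calls.tsv`, `contingency.json`, `manifest.json`).
#'
#' @param config list or YAML file path.
#' @return list: `scores`, `threshold`, `calls`, `summary`
#'   (see [summarize_edy_outcome()]; `NULL` without outcome data),
#'   `manifest` (when `out_dir` is set).
#' @export
run_bulk_pipeline <- function(config) {
  config <- load_config(config)
  mat <- resolve_input(config$expression, read_expression)
  if (is.null(mat)) stop("config$expression is required")
  metadata <- resolve_input(config$metadata,
                            function(p) read_metadata(p, c("sample_id",
                                                           "role")))
  if (is.null(metadata)) stop("config$metadata is required")
  annotations <- if (!is.null(config$gene_map))
    resolve_input(config$gene_map, read_gene_map)
  panel <- panel_from_config(config$panel, annotations)
  gc <- config$gsva %||% list()
  scores <- gsva_scores(mat, panel,
                        gsva_config(kernel = gc$kernel %||% "auto",
                                    tau = gc$tau %||% 1,
                                    score_mode = gc$score_mode %||%
                                      "max_diff"))
  threshold <- calibrate_threshold(scores, metadata,
                                   rule_from_config(config$rule))
  calls <- call_edy(scores, threshold)
  summary <- if ("outcome" %in% names(metadata))
    summarize_edy_outcome(calls, metadata) else NULL
  result <- list(scores = scores, threshold = threshold, calls = calls,
                 summary = summary)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    grp <- metadata[match(calls$sample_id, metadata$sample_id), ]
    out_calls <- cbind(calls,
                       group = grp$group %||% NA,
                       outcome = grp$outcome %||% NA)
    utils::write.table(out_calls,
                       file.path(config$out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(summary))
      jsonlite::write_json(
        list(table = summary$table,
             p_two_sided = summary$contingency$p_two_sided,
             p_one_sided = summary$contingency$p_one_sided,
             or_sample = summary$contingency$or_sample,
             ci_woolf = summary$contingency$ci_woolf,
             ci_conditional_exact =
               summary$contingency$ci_conditional_exact,
             prop_progress_edy = summary$prop_progress_edy,
             prop_progress_nonedy = summary$prop_progress_nonedy),
        file.path(config$out_dir, "contingency.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "string")
    result$manifest <- write_manifest(config$out_dir, config,
                                      list(threshold = threshold,
                                           n_edy = sum(calls$edy)))
  }
  result
}

#' Run the single-cell EDY pipeline
#'
#' UMI counts -> QC -> log-normalization -> Y-panel selection ->
#' zero-UMI EDY calls -> per-sample fractions -> ordered-group trend
#' test, plus optional module scores for user-supplied gene sets.
#' Config fields: `counts` (path, MTX directory or matrix),
#' `cell_metadata` (path or data.frame with `cell_id`, `sample_id`,
#' `group`, optionally `sex`), `qc` (list of [cell_qc_config()]
#' arguments or `FALSE` to skip), `panel` (list: `mode = "auto"` with
#' `y_genes`, or `mode = "list"` with `genes`), `module_sets` (named
#' list of gene vectors), `seed`, `out_dir`.
#'
#' @param config list or YAML file path.
#' @return list: `qc_report`, `calls`, `fractions`, `trend`
#'   ([jonckheere_terpstra()] result; `NULL` with < 2 groups),
#'   `module_scores`, `panel`.
#' @export
run_sc_pipeline <- function(config) {
  config <- load_config(config)
  counts <- resolve_input(config$counts, read_expression)
  if (is.null(counts)) stop("config$counts is required")
  metadata <- resolve_input(config$cell_metadata,
                            function(p) read_metadata(p, c("cell_id",
                                                           "sample_id",
                                                           "group")))
  if (is.null(metadata)) stop("config$cell_metadata is required")
  qc_report <- NULL
  if (!identical(config$qc, FALSE)) {
    qc <- qc_filter(counts, cfg = do.call(cell_qc_config,
                                          config$qc %||% list()))
    counts <- qc$counts
    qc_report <- qc$report
  }
  norm <- normalize_log(counts)
  pc <- config$panel %||% list(mode = "auto")
  panel <- if (identical(pc$mode, "list"))
    build_y_panel(species = pc$species %||% "human",
                  mode = "dataset_specific", genes = pc$genes)
  else
    select_y_genes_sc(norm, counts,
                      pc$y_genes %||% HUMAN_Y12,
                      species = pc$species %||% "human")
  calls <- call_edy_cells(counts, panel)
  fractions <- edy_fraction_per_sample(calls, metadata)
  groups_present <- unique(as.character(fractions$group))
  trend <- if (length(groups_present) >= 2) {
    ordered_groups <- split(fractions$fraction, fractions$group,
                            drop = TRUE)
    jonckheere_terpstra(ordered_groups, alternative = "increasing")
  } else NULL
  module_scores <- NULL
  if (!is.null(config$module_sets)) {
    msc <- module_score_config(seed = config$seed %||% 1)
    module_scores <- lapply(config$module_sets, function(gs)
      module_score(norm, gs, msc))
  }
  result <- list(qc_report = qc_report, calls = calls,
                 fractions = fractions, trend = trend,
                 module_scores = module_scores, panel = panel)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(fractions,
                       file.path(config$out_dir, "edy_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(calls, file.path(config$out_dir, "cell_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$manifest <- write_manifest(
      config$out_dir, config,
      list(panel = panel$genes,
           jt_p = if (!is.null(trend)) trend$p_one_sided else NA))
  }
  result
}

#' Run the copy-number LOY pipeline
#'
#' Segment table -> per-sample raw and adjusted Y signal -> LOY calls
#' -> Fisher association with the progression outcome. Config fields:
#' `segments` (path or data.frame), `purity_ploidy` (path or
#' data.frame), `metadata` (path or data.frame with `sample_id`,
#' `outcome`; optional), `loy_threshold` (default 0.5), `ratio_scale`
#' (`TRUE` when segment values are depth ratios rather than absolute
#' copy number), `out_dir`.
#'
#' @param config list or YAML file path.
#' @return list: `y_signal` (data.frame `sample_id`, `raw`, `adjusted`,
#'   `n_segments_used`, `loy`), `summary` (outcome association or
#'   `NULL`), `failed` (named character of per-sample errors).
#' @export
run_cna_pipeline <- function(config) {
  config <- load_config(config)
  segments <- resolve_input(config$segments, read_segments)
  pp <- resolve_input(config$purity_ploidy, read_purity_ploidy)
  if (is.null(segments) || is.null(pp))
    stop("config$segments and config$purity_ploidy are required")
  threshold <- config$loy_threshold %||% 0.5
  failed <- character(0)
  rows <- lapply(pp$sample_id, function(sid) {
    tryCatch({
      seg <- segments
      if (isTRUE(config$ratio_scale)) {
        i <- match(sid, pp$sample_id)
        seg$value <- ratio_to_cn(seg$value, pp$cellularity[[i]],
                                 pp$ploidy[[i]])
      }
      ys <- y_signal_raw(seg, sid)
      i <- match(sid, pp$sample_id)
      adj <- adjust_y_signal(ys$raw, pp$cellularity[[i]], pp$ploidy[[i]])
      data.frame(sample_id = sid, raw = ys$raw, adjusted = adj,
                 n_segments_used = ys$n_segments_used,
                 loy = call_loy(adj, threshold),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      failed[[sid]] <<- conditionMessage(e)
      NULL
    })
  })
  y_signal <- do.call(rbind, rows)
  if (is.null(y_signal))
    stop("no sample yielded a Y signal; first error: ", failed[[1L]])
  metadata <- resolve_input(config$metadata,
                            function(p) read_metadata(p, c("sample_id",
                                                           "outcome")))
  summary <- NULL
  if (!is.null(metadata) && "outcome" %in% names(metadata)) {
    loy_calls <- data.frame(sample_id = y_signal$sample_id,
                            score = y_signal$adjusted,
                            threshold = threshold,
                            edy = y_signal$loy,
                            stringsAsFactors = FALSE)
    summary <- summarize_edy_outcome(loy_calls, metadata)
  }
  result <- list(y_signal = y_signal, summary = summary, failed = failed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(y_signal,
                       file.path(config$out_dir, "y_signal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$manifest <- write_manifest(config$out_dir, config,
                                      list(loy_threshold = threshold,
                                           n_loy = sum(y_signal$loy)))
  }
  result
}
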