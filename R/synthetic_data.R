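# Seeded generators for bulk expression, single-cell UMI, segmented
# copy-number and binary-outcome data with the statistical structure
# the detection methods assume, plus the planted truth labels needed
# to test recovery.

#' Bulk expression simulation configuration
#'
#' Males carry a Y panel expressed at `male_y_level`; an `edy_fraction`
#' of them is EDY, with Y-panel expression multiplied by `depletion`
#' (0 = complete silencing). Females express the Y panel at
#' `female_y_level` times the male level. Non-Y genes are iid lognormal
#' and shared across sexes.
#'
#' @param n_male,n_female sample counts.
#' @param n_genes,n_y_genes total and Y-panel gene counts.
#' @param edy_fraction fraction of males planted as EDY.
#' @param depletion multiplier on Y-panel expression in EDY males,
#'   in \[0, 1).
#' @param female_y_level Y-panel multiplier for females (default 0.01).
#' @param male_y_level mean Y-panel expression level in non-EDY males.
#' @param noise lognormal sigma of expression noise.
#' @param seed RNG seed.
#' @return list of class `BulkSimConfig`.
#' @export
bulk_sim_config <- function(n_male = 20, n_female = 10, n_genes = 200,
                            n_y_genes = 12, edy_fraction = 0.2,
                            depletion = 0, female_y_level = 0.01,
                            male_y_level = 100, noise = 0.25, seed = 1) {
  stopifnot(n_y_genes < n_genes, edy_fraction >= 0, edy_fraction <= 1,
            depletion >= 0, depletion < 1, noise >= 0)
  structure(as.list(environment()), class = "BulkSimConfig")
}

#' Generate a bulk expression cohort with planted EDY
#'
#' @param cfg [bulk_sim_config()].
#' @return list: `matrix` (log2(1+x), layer `"log_normalized"`),
#'   `metadata` (`sample_id`, `sex`, `role`, `group`), `truth`
#'   (`sample_id`, `edy`), `y_panel` (gene symbols).
#' @export
gen_bulk <- function(cfg = bulk_sim_config()) {
  stopifnot(inherits(cfg, "BulkSimConfig"))
  with_seed(cfg$seed, {
    y_genes <- if (cfg$n_y_genes <= length(HUMAN_Y12))
      HUMAN_Y12[seq_len(cfg$n_y_genes)] else
        c(HUMAN_Y12, paste0("YG", seq_len(cfg$n_y_genes - length(HUMAN_Y12))))
    other <- paste0("G", seq_len(cfg$n_genes - cfg$n_y_genes))
    genes <- c(y_genes, other)
    samples <- c(sprintf("M%d", seq_len(cfg$n_male)),
                 sprintf("F%d", seq_len(cfg$n_female)))
    sex <- rep(c("male", "female"), c(cfg$n_male, cfg$n_female))
    n_edy <- round(cfg$edy_fraction * cfg$n_male)
    edy <- c(sample(rep(c(TRUE, FALSE),
                        c(n_edy, cfg$n_male - n_edy))),
             rep(FALSE, cfg$n_female))
    base_mean <- c(rep(cfg$male_y_level, cfg$n_y_genes),
                   stats::rlnorm(length(other), log(20), 1))
    mult <- matrix(1, cfg$n_genes, length(samples))
    mult[seq_len(cfg$n_y_genes), sex == "female"] <- cfg$female_y_level
    mult[seq_len(cfg$n_y_genes), edy] <- cfg$depletion
    raw <- mult * base_mean *
      exp(matrix(stats::rnorm(cfg$n_genes * length(samples),
                              0, cfg$noise),
                 cfg$n_genes, length(samples)))
    mat <- log2(1 + raw)
    dimnames(mat) <- list(genes, samples)
    attr(mat, "layer") <- "log_normalized"
    list(matrix = mat,
         metadata = data.frame(
           sample_id = samples, sex = sex,
           role = ifelse(sex == "female", "reference", "case"),
           group = ifelse(sex == "female", "reference", "OPMD"),
           stringsAsFactors = FALSE),
         truth = data.frame(sample_id = samples, edy = edy,
                            stringsAsFactors = FALSE),
         y_panel = y_genes)
  })
}

#' Single-cell simulation configuration
#'
#' Negative-binomial UMI counts per gene, an ordered tissue-group
#' design, and an EDY cell fraction per group planted as exact zeros on
#' the Y panel (the classification rule is exact-zero). Default
#' fractions mirror a normal < premalignant < cancer gradient.
#'
#' @param groups ordered group names.
#' @param n_samples_per_group samples per group.
#' @param cells_per_sample cells per sample.
#' @param edy_fraction per-group EDY cell probability.
#' @param n_genes background gene count (Y panel and mito genes are
#'   added on top).
#' @param panel_genes Y-panel gene symbols.
#' @param panel_nb_mean NB mean of each panel gene in non-EDY cells.
#' @param nb_size NB dispersion (size) for all genes.
#' @param mito_nb_mean NB mean of each of the 3 mitochondrial genes.
#' @param signature_genes optional genes up-shifted in EDY cells.
#' @param signature_fold NB-mean multiplier for `signature_genes` in
#'   EDY cells.
#' @param seed RNG seed.
#' @return list of class `ScSimConfig`.
#' @export
sc_sim_config <- function(groups = c("normal", "leukoplakia", "cancer"),
                          n_samples_per_group = 10,
                          cells_per_sample = 300,
                          edy_fraction = c(0.035, 0.149, 0.198),
                          n_genes = 50,
                          panel_genes = c("RPS4Y1", "TTTY15", "DDX3Y",
                                          "EIF1AY"),
                          panel_nb_mean = 2, nb_size = 2,
                          mito_nb_mean = 5,
                          signature_genes = NULL, signature_fold = 1,
                          seed = 1) {
  if (length(edy_fraction) == 1L)
    edy_fraction <- rep(edy_fraction, length(groups))
  stopifnot(length(edy_fraction) == length(groups),
            all(edy_fraction >= 0), all(edy_fraction <= 1),
            signature_fold > 0)
  structure(as.list(environment()), class = "ScSimConfig")
}

#' Generate a single-cell UMI cohort with planted EDY cells
#'
#' EDY cells get exactly zero counts on every panel gene; non-EDY cells
#' are rejection-sampled so that their panel UMI sum is at least 1,
#' guaranteeing that the zero-UMI rule recovers the planted labels
#' without error.
#'
#' @param cfg [sc_sim_config()].
#' @return list: `counts` (genes-by-cells integer matrix), `metadata`
#'   (`cell_id`, `sample_id`, `sex`, `group`, `cell_type`), `truth`
#'   (`cell_id`, `edy`), `panel`.
#' @export
gen_sc <- function(cfg = sc_sim_config()) {
  stopifnot(inherits(cfg, "ScSimConfig"))
  with_seed(cfg$seed, {
    bg_genes <- paste0("G", seq_len(cfg$n_genes))
    mito_genes <- paste0("MT-", c("ND1", "CO1", "ATP6"))
    genes <- c(cfg$panel_genes, bg_genes, mito_genes)
    bg_mean <- stats::rgamma(cfg$n_genes, shape = 2, scale = 1)
    n_cells_total <- length(cfg$groups) * cfg$n_samples_per_group *
      cfg$cells_per_sample
    counts <- matrix(0L, length(genes), n_cells_total,
                     dimnames = list(genes, NULL))
    edy_all <- logical(n_cells_total)
    cell_ids <- character(n_cells_total)
    offset <- 0L
    for (gi in seq_along(cfg$groups)) {
      for (si in seq_len(cfg$n_samples_per_group)) {
        idx <- offset + seq_len(cfg$cells_per_sample)
        sample_id <- sprintf("%s_S%02d", cfg$groups[[gi]], si)
        cell_ids[idx] <- sprintf("%s_C%04d", sample_id,
                                 seq_len(cfg$cells_per_sample))
        edy <- stats::runif(cfg$cells_per_sample) < cfg$edy_fraction[[gi]]
        edy_all[idx] <- edy
        nc <- cfg$cells_per_sample
        bg <- matrix(stats::rnbinom(cfg$n_genes * nc,
                                    mu = bg_mean, size = cfg$nb_size),
                     cfg$n_genes, nc)
        if (!is.null(cfg$signature_genes) && cfg$signature_fold != 1) {
          sig <- match(intersect(cfg$signature_genes, bg_genes), bg_genes)
          if (length(sig) && any(edy))
            bg[sig, edy] <- matrix(
              stats::rnbinom(length(sig) * sum(edy),
                             mu = bg_mean[sig] * cfg$signature_fold,
                             size = cfg$nb_size),
              length(sig), sum(edy))
        }
        pnl <- matrix(stats::rnbinom(length(cfg$panel_genes) * nc,
                                     mu = cfg$panel_nb_mean,
                                     size = cfg$nb_size),
                      length(cfg$panel_genes), nc)
        # non-EDY cells must have a nonzero panel sum
        redo <- !edy & colSums(pnl) == 0
        while (any(redo)) {
          pnl[, redo] <- matrix(
            stats::rnbinom(length(cfg$panel_genes) * sum(redo),
                           mu = cfg$panel_nb_mean, size = cfg$nb_size),
            length(cfg$panel_genes), sum(redo))
          redo <- !edy & colSums(pnl) == 0
        }
        pnl[, edy] <- 0L
        mito <- matrix(stats::rnbinom(length(mito_genes) * nc,
                                      mu = cfg$mito_nb_mean,
                                      size = cfg$nb_size),
                       length(mito_genes), nc)
        counts[, idx] <- rbind(pnl, bg, mito)
        offset <- offset + cfg$cells_per_sample
      }
    }
    colnames(counts) <- cell_ids
    storage.mode(counts) <- "integer"
    grp <- rep(cfg$groups,
               each = cfg$n_samples_per_group * cfg$cells_per_sample)
    smp <- sub("_C\\d+$", "", cell_ids)
    list(counts = counts,
         metadata = data.frame(
           cell_id = cell_ids, sample_id = smp, sex = "male",
           group = factor(grp, levels = cfg$groups, ordered = TRUE),
           cell_type = "epithelial", stringsAsFactors = FALSE),
         truth = data.frame(cell_id = cell_ids, edy = edy_all,
                            stringsAsFactors = FALSE),
         panel = cfg$panel_genes)
  })
}

#' Copy-number simulation configuration
#'
#' @param n_y_bins number of Y-chromosome bins/segments.
#' @param cellularity tumor-cell fraction rho in (0, 1].
#' @param ploidy tumor ploidy psi.
#' @param loy plant complete Y loss (`c_t = 0`) or retention
#'   (`c_t = 1`).
#' @param sigma per-bin Gaussian noise SD.
#' @param sample_id sample name used in the emitted tables.
#' @param seed RNG seed.
#' @return list of class `CnaSimConfig`.
#' @export
cna_sim_config <- function(n_y_bins = 50, cellularity = 0.7, ploidy = 2,
                           loy = TRUE, sigma = 0.1, sample_id = "S1",
                           seed = 1) {
  stopifnot(n_y_bins >= 1, cellularity > 0, cellularity <= 1, ploidy > 0,
            sigma >= 0)
  structure(as.list(environment()), class = "CnaSimConfig")
}

#' Generate segmented Y copy-number data with optional planted LOY
#'
#' Bin values are drawn around the normal/tumor mixture mean
#' `(1 - rho) + rho * c_t` on the absolute copy-number scale, with
#' `c_t = 0` under LOY and 1 otherwise.
#'
#' @param cfg [cna_sim_config()].
#' @return list: `segments` (SEG-like data.frame), `purity_ploidy`,
#'   `truth` (`c_t`, `loy`).
#' @export
gen_cna <- function(cfg = cna_sim_config()) {
  stopifnot(inherits(cfg, "CnaSimConfig"))
  with_seed(cfg$seed, {
    c_t <- if (cfg$loy) 0 else 1
    mu <- (1 - cfg$cellularity) + cfg$cellularity * c_t
    width <- 1e6
    start <- 2650000 + (seq_len(cfg$n_y_bins) - 1) * width
    segments <- data.frame(
      sample_id = cfg$sample_id, chrom = "Y",
      start = start, end = start + width - 1,
      value = stats::rnorm(cfg$n_y_bins, mu, cfg$sigma),
      stringsAsFactors = FALSE)
    list(segments = segments,
         purity_ploidy = data.frame(sample_id = cfg$sample_id,
                                    cellularity = cfg$cellularity,
                                    ploidy = cfg$ploidy,
                                    stringsAsFactors = FALSE),
         truth = list(c_t = c_t, loy = cfg$loy))
  })
}

#' Outcome simulation configuration
#'
#' @param baseline_progression_rate progression probability for
#'   non-EDY samples (default 0.381, a typical non-EDY progression
#'   rate in follow-up cohorts of premalignant lesions).
#' @param odds_ratio odds ratio of progression for EDY vs non-EDY.
#' @param seed RNG seed.
#' @return list of class `OutcomeSimConfig`.
#' @export
outcome_sim_config <- function(baseline_progression_rate = 0.381,
                               odds_ratio = 10, seed = 1) {
  stopifnot(baseline_progression_rate > 0,
            baseline_progression_rate < 1, odds_ratio > 0)
  structure(as.list(environment()), class = "OutcomeSimConfig")
}

#' Generate binary progression outcomes given EDY status
#'
#' `P(progress | non-EDY) = p0`; for EDY samples the odds are
#' multiplied by `odds_ratio`.
#'
#' @param edy_labels logical vector.
#' @param cfg [outcome_sim_config()].
#' @return character vector `"progressor"` / `"non_progressor"`.
#' @export
gen_outcomes <- function(edy_labels, cfg = outcome_sim_config()) {
  stopifnot(inherits(cfg, "OutcomeSimConfig"))
  p0 <- cfg$baseline_progression_rate
  odds1 <- cfg$odds_ratio * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  with_seed(cfg$seed, {
    p <- ifelse(as.logical(edy_labels), p1, p0)
    ifelse(stats::runif(length(p)) < p, "progressor", "non_progressor")
  })
}
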