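# helper: small matrix with named genes/cells
mk_counts <- function(values, genes, cells) {
  matrix(values, length(genes), length(cells),
         dimnames = list(genes, cells))
}

test_that("QC removes cells outside the gene-count and mito bounds", {
  cfg <- cell_qc_config(min_genes = 2, max_genes = 6,
                        max_mito_fraction = 0.10,
                        min_cell_fraction_per_gene = 0.01)
  genes <- c(paste0("G", 1:6), "MT-ND1")
  # C1: 2 genes (== min, removed); C2: 3 genes ok; C3: 12% mito
  counts <- mk_counts(0, genes, c("C1", "C2", "C3"))
  counts[c("G1", "G2"), "C1"] <- 1
  counts[c("G1", "G2", "G3"), "C2"] <- c(5, 5, 5)
  counts[c("G1", "G2", "G3"), "C3"] <- c(40, 25, 23)
  counts["MT-ND1", "C3"] <- 12
  res <- qc_filter(counts, cfg = cfg)
  expect_identical(colnames(res$counts), "C2")
  expect_equal(res$report$cells_removed_gene_count, 1)
  expect_equal(res$report$cells_removed_mito, 1)
})

test_that("QC removes exactly the planted failing cells and is idempotent", {
  sc <- gen_sc(sc_sim_config(n_samples_per_group = 2,
                             cells_per_sample = 100, seed = 4))
  counts <- sc$counts
  bad <- sample(colnames(counts), 10)
  counts[, bad] <- 0
  counts[1:2, bad] <- 1   # 2 genes detected -> below min_genes
  cfg <- cell_qc_config(min_genes = 5, max_genes = 10000,
                        max_mito_fraction = 0.9,
                        min_cell_fraction_per_gene = 0.0001)
  res <- qc_filter(counts, cfg = cfg)
  expect_setequal(setdiff(colnames(counts), colnames(res$counts)), bad)
  twice <- qc_filter(res$counts, cfg = cfg)
  expect_identical(twice$counts, res$counts)
})

test_that("log-normalization matches the closed form and is depth-invariant", {
  counts <- mk_counts(c(100, 0, 0), c("A", "B", "C"), "C1")
  norm <- normalize_log(counts)
  expect_equal(norm["A", 1], log(1 + 1e4))
  expect_equal(unname(norm[c("B", "C"), 1]), c(0, 0))
  set.seed(6)
  m <- mk_counts(rpois(30, 4) + 1, paste0("G", 1:6), paste0("C", 1:5))
  expect_equal(normalize_log(m), normalize_log(m * 2))
  tot <- colSums(m)
  direct <- log1p(1e4 * sweep(m, 2, tot, "/"))
  expect_equal(normalize_log(m), direct, tolerance = 1e-12)
  expect_error(normalize_log(mk_counts(0, "A", "C1")), "zero total")
})

test_that("Y-gene selection applies the prevalence/level filters", {
  set.seed(7)
  n_cells <- 400
  genes <- c("YA", "YB", "YC", paste0("G", 1:20))
  # realistic library depth (~10k UMIs/cell) so that a sporadic single
  # count maps to a small normalized value
  counts <- matrix(rpois(length(genes) * n_cells, 500), length(genes),
                   dimnames = list(genes, paste0("C", 1:n_cells)))
  # YA: expressed in ~6% of cells at low level; YB: ~1%; YC: high level
  counts["YA", ] <- rbinom(n_cells, 1, 0.06)
  counts["YB", ] <- rbinom(n_cells, 1, 0.01)
  counts["YC", ] <- rpois(n_cells, 30)
  norm <- normalize_log(counts)
  panel <- select_y_genes_sc(norm, counts, c("YA", "YB", "YC"))
  expect_true("YA" %in% panel$genes)    # prevalence criterion alone
  expect_false("YB" %in% panel$genes)
  expect_true("YC" %in% panel$genes)
  panel_and <- select_y_genes_sc(norm, counts, c("YA", "YB", "YC"),
                                 y_panel_select_config(combine = "and"))
  expect_false("YA" %in% panel_and$genes)
})

test_that("generator-selected Y panels recover the prevalent genes", {
  set.seed(19)
  prevalent <- paste0("YP", 1:4)
  rare <- paste0("YR", 1:3)
  genes <- c(prevalent, rare, paste0("G", 1:20))
  n <- 500
  counts <- matrix(rpois(length(genes) * n, 100), length(genes),
                   dimnames = list(genes, paste0("C", 1:n)))
  counts[prevalent, ] <- matrix(rpois(4 * n, 1), 4)
  counts[rare, ] <- matrix(rbinom(3 * n, 1, 0.005), 3)
  norm <- normalize_log(counts)
  panel <- select_y_genes_sc(norm, counts, c(prevalent, rare))
  expect_setequal(panel$genes, prevalent)
})

test_that("the zero-UMI rule classifies cells and ignores normalization", {
  panel <- c("RPS4Y1", "TTTY15", "DDX3Y", "EIF1AY")
  genes <- c(panel, "G1")
  counts <- mk_counts(0, genes, c("C1", "C2"))
  counts["DDX3Y", "C1"] <- 1
  counts["G1", ] <- 50
  calls <- call_edy_cells(counts, panel)
  expect_identical(calls$edy, c(FALSE, TRUE))
  # dropping absent panel genes warns; all-absent errors
  expect_warning(call_edy_cells(counts, c(panel, "USP9Y")), "USP9Y")
  expect_error(suppressWarnings(call_edy_cells(counts, "USP9Y")),
               "no panel genes")
})

test_that("planted EDY fractions are recovered within the binomial CI", {
  sc <- gen_sc(sc_sim_config(groups = "g", n_samples_per_group = 1,
                             cells_per_sample = 1000,
                             edy_fraction = 0.15, seed = 23))
  calls <- call_edy_cells(sc$counts, sc$panel)
  expect_identical(calls$edy, sc$truth$edy)
  ci <- binom.test(sum(calls$edy), nrow(calls), 0.15)$conf.int
  expect_true(ci[1] <= 0.15 && 0.15 <= ci[2])
})

test_that("per-sample fractions aggregate correctly and guard against females", {
  calls <- data.frame(cell_id = sprintf("c%02d", 1:20),
                      edy = rep(c(TRUE, FALSE), c(2, 18)))
  md <- data.frame(cell_id = calls$cell_id, sample_id = "S1",
                   group = "normal", sex = "male")
  fr <- edy_fraction_per_sample(calls, md)
  expect_equal(fr$fraction, 0.10)
  md$sex <- "female"
  expect_warning(edy_fraction_per_sample(calls, md), "female")
})

test_that("female cells with zero Y counts are all EDY-flagged", {
  sc <- gen_sc(sc_sim_config(groups = "g", n_samples_per_group = 2,
                             cells_per_sample = 50, edy_fraction = 0,
                             seed = 5))
  fem <- sc$counts
  fem[sc$panel, ] <- 0L   # female cells: no Y expression at all
  calls <- call_edy_cells(fem, sc$panel)
  expect_true(all(calls$edy))
})

test_that("module scores are centered for bin-matched sets and deterministic", {
  # all genes share one expression profile: every control equals the
  # set, so the score is exactly 0
  m <- matrix(rep(seq(0, 3, length.out = 8), each = 30), 30, 8,
              dimnames = list(paste0("G", 1:30), paste0("C", 1:8)))
  cfg <- module_score_config(n_bins = 5, n_control_per_gene = 20,
                             seed = 99)
  expect_equal(module_score(m, c("G3", "G11"), cfg), rep(0, 8))
  # determinism under a fixed seed
  set.seed(1)
  m2 <- matrix(rnorm(240), 30, 8,
               dimnames = dimnames(m))
  s1 <- module_score(m2, c("G1", "G2", "G3"), cfg)
  s2 <- module_score(m2, c("G1", "G2", "G3"), cfg)
  expect_identical(s1, s2)
  expect_error(module_score(m2, "G1", module_score_config(n_bins = 64)),
               "n_bins")
})

test_that("module scores shift by +c when set genes shift within their bin", {
  set.seed(12)
  m <- matrix(rnorm(200, 1), 25, 8,
              dimnames = list(paste0("G", 1:25), paste0("C", 1:8)))
  top <- c("G1", "G2")
  m[top, ] <- m[top, ] + 10          # already the top-expression bin
  cfg <- module_score_config(n_bins = 5, n_control_per_gene = 50,
                             seed = 7)
  base <- module_score(m, top, cfg)
  m_shift <- m
  m_shift[top, ] <- m_shift[top, ] + 2   # stays top-ranked: same bins
  expect_equal(module_score(m_shift, top, cfg), base + 2,
               tolerance = 1e-12)
})

test_that("signature genes up-shifted in EDY cells raise their module score", {
  sig <- paste0("G", 1:14)
  sc <- gen_sc(sc_sim_config(groups = "g", n_samples_per_group = 4,
                             cells_per_sample = 250,
                             edy_fraction = 0.5, n_genes = 60,
                             signature_genes = sig,
                             signature_fold = 3, seed = 77))
  keep <- colSums(sc$counts) > 0
  norm <- normalize_log(sc$counts[, keep])
  edy <- sc$truth$edy[keep]
  sco <- module_score(norm, sig, module_score_config(seed = 3))
  expect_lt(wilcoxon_rank_sum(sco[edy], sco[!edy], "greater"), 0.01)
})

test_that("expression frequency counts nonzero cells per group", {
  counts <- mk_counts(0, c("IL17RC", "G1"), sprintf("C%d", 1:12))
  counts["IL17RC", c("C1", "C2", "C8")] <- c(3, 1, 2)
  grp <- rep(c("EDY", "nonEDY"), c(7, 5))
  fr <- expression_frequency(counts, "IL17RC", grp)
  expect_equal(fr$frequency[fr$group == "EDY"], 2 / 7, tolerance = 1e-9)
  expect_equal(round(100 * fr$frequency[fr$group == "EDY"], 1), 28.6)
  expect_equal(fr$frequency[fr$group == "nonEDY"], 1 / 5)
  zero <- expression_frequency(counts, "G1", grp)
  expect_true(all(zero$frequency == 0))
  expect_error(expression_frequency(counts, "NOPE", grp), "NOPE")
})

test_that("planted expression prevalences are recovered within binomial CIs", {
  set.seed(31)
  n1 <- 400; n2 <- 400
  gene <- rbind(c(rbinom(n1, 1, 0.30), rbinom(n2, 1, 0.15)))
  counts <- matrix(gene, 1, dimnames = list("IL17RC", NULL))
  colnames(counts) <- sprintf("C%d", 1:(n1 + n2))
  grp <- rep(c("EDY", "nonEDY"), c(n1, n2))
  fr <- expression_frequency(counts, "IL17RC", grp)
  for (i in seq_len(2)) {
    p_true <- c(EDY = 0.30, nonEDY = 0.15)[[fr$group[i]]]
    ci <- binom.test(fr$n_expressing[i], fr$n_cells[i])$conf.int
    expect_true(ci[1] <= p_true && p_true <= ci[2])
  }
})
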