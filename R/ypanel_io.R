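# Reading expression matrices, gene annotations and metadata, and
# constructing the Y-chromosome gene panels all downstream scoring uses.

#' The fixed 12-gene human Y-chromosome panel
#'
#' Canonical protein-coding Y genes used for human bulk scoring.
#'
#' @format Character vector of 12 gene symbols.
#' @export
HUMAN_Y12 <- c("DDX3Y", "KDM5D", "ZFY", "UTY", "USP9Y", "EIF1AY",
               "RPS4Y1", "PRKY", "NLGN4Y", "TMSB4Y", "SRY", "TBL1Y")

#' Normalize chromosome names to a single dialect
#'
#' Strips any leading "chr" prefix so that "chrY" and "Y" compare equal.
#' Idempotent.
#'
#' @param x character vector of chromosome names.
#' @return character vector without "chr" prefixes.
#' @export
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read a genes-by-samples expression matrix
#'
#' Accepts a TSV/CSV file (genes in rows, first column = gene id, header
#' = sample ids) or a MatrixMarket triplet directory containing
#' `matrix.mtx`, a gene list (`genes.tsv` or `features.tsv`) and a
#' column list (`barcodes.tsv` or `samples.tsv`).
#'
#' @param path file or directory path.
#' @param layer_hint `"raw_counts"`, `"log_normalized"` or `"auto"`
#'   (default). Under `"auto"`, a matrix whose values are all integral
#'   (to 1e-6) is treated as raw counts.
#' @return numeric matrix with `rownames` = gene ids, `colnames` =
#'   sample ids, and attribute `"layer"` set.
#' @export
read_expression <- function(path,
                            layer_hint = c("auto", "raw_counts",
                                           "log_normalized")) {
  layer_hint <- match.arg(layer_hint)
  if (!file.exists(path))
    stop("expression input not found: ", path)
  if (dir.exists(path)) {
    mat <- read_mtx_triplet(path)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
    ids <- as.character(df[[1L]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      stop("duplicate gene ids in ", path, ": ",
           paste(dup, collapse = ", "))
    mat <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(mat))
      stop("non-numeric expression values in ", path)
    rownames(mat) <- ids
  }
  layer <- layer_hint
  if (layer == "auto") {
    layer <- if (all(abs(mat - round(mat)) < 1e-6) && all(mat >= 0))
      "raw_counts" else "log_normalized"
  }
  if (layer == "raw_counts") {
    if (any(mat < 0))
      stop("raw_counts layer contains negative values")
    if (any(abs(mat - round(mat)) > 1e-6))
      stop("raw_counts layer contains non-integer values")
  }
  attr(mat, "layer") <- layer
  mat
}

read_mtx_triplet <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx))
    stop("no matrix.mtx in ", dir)
  gene_file <- Filter(file.exists,
                      file.path(dir, c("genes.tsv", "features.tsv")))
  col_file <- Filter(file.exists,
                     file.path(dir, c("barcodes.tsv", "samples.tsv")))
  if (!length(gene_file) || !length(col_file))
    stop("MTX triplet directory ", dir,
         " must contain a gene list and a barcode/sample list")
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- utils::read.table(gene_file[[1L]], sep = "\t",
                             stringsAsFactors = FALSE)[[1L]]
  cols <- utils::read.table(col_file[[1L]], sep = "\t",
                            stringsAsFactors = FALSE)[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene ids in ", gene_file[[1L]], ": ",
         paste(dup, collapse = ", "))
  dimnames(m) <- list(genes, cols)
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for the TSV form; round-trips values
#' bit-identically.
#'
#' @param mat matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation map
#'
#' Accepts either a GTF file (gene features; requires the rtracklayer
#' package) or a headerless 2–4 column TSV with columns gene_id, symbol,
#' chromosome and optionally biotype. Chromosome names are normalized
#' ("chrY" becomes "Y"); a missing biotype defaults to `"unknown"`.
#'
#' @param path input file.
#' @return data.frame with columns `gene_id`, `symbol`, `chromosome`,
#'   `biotype`.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path))
    stop("gene map not found: ", path)
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF gene maps requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "gene"]
    sym <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
    bt <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else
      if (!is.null(gr$gene_type)) gr$gene_type else "unknown"
    ann <- data.frame(gene_id = gr$gene_id, symbol = sym,
                      chromosome = normalize_chrom(
                        as.character(methods::slot(gr, "seqnames"))),
                      biotype = bt, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "[\t ]+")
    nf <- lengths(fields)
    bad <- which(nf < 2L)
    if (length(bad))
      stop("expected ≥2 columns in gene map line ", bad[[1L]],
           " of ", path)
    ann <- data.frame(
      gene_id = vapply(fields, `[`, "", 1L),
      symbol = vapply(fields, `[`, "", 2L),
      chromosome = normalize_chrom(
        vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_, "")),
      biotype = vapply(fields, function(f)
        if (length(f) >= 4L) f[[4L]] else "unknown", ""),
      stringsAsFactors = FALSE)
    ann$chromosome[is.na(ann$chromosome)] <- "unknown"
  }
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup))
    stop("duplicate gene ids in gene map: ", paste(dup, collapse = ", "))
  ann
}

#' Read sample or cell metadata
#'
#' Thin TSV reader that checks for required columns.
#'
#' @param path TSV with header.
#' @param required columns that must be present.
#' @return data.frame.
#' @export
read_metadata <- function(path, required = "sample_id") {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  md
}

#' Construct a Y-chromosome gene panel
#'
#' Three modes mirror the three panels used across cohorts:
#' `fixed_human_12` returns the canonical 12-gene human panel
#' regardless of annotation input; `mouse_all_protein_coding` selects
#' every annotated protein-coding gene on chromosome Y; and
#' `dataset_specific` takes an explicit gene list (e.g. the 4-gene
#' panel RPS4Y1, TTTY15, DDX3Y, EIF1AY used for single-cell calling in
#' datasets with limited Y-gene detection).
#'
#' @param annotations data.frame as returned by [read_gene_map()]
#'   (required for `mouse_all_protein_coding`).
#' @param species `"human"` or `"mouse"`.
#' @param mode panel construction mode.
#' @param genes explicit gene list for `dataset_specific`.
#' @return object of class `YGenePanel`: a list with `species`, `genes`
#'   and `source`.
#' @export
build_y_panel <- function(annotations = NULL,
                          species = c("human", "mouse"),
                          mode = c("fixed_human_12",
                                   "mouse_all_protein_coding",
                                   "dataset_specific"),
                          genes = NULL) {
  species <- match.arg(species)
  mode <- match.arg(mode)
  panel <- switch(mode,
    fixed_human_12 = HUMAN_Y12,
    mouse_all_protein_coding = {
      if (is.null(annotations))
        stop("mouse_all_protein_coding requires gene annotations")
      with(annotations,
           symbol[normalize_chrom(chromosome) == "Y" &
                  biotype == "protein_coding"])
    },
    dataset_specific = {
      if (is.null(genes) || !length(genes))
        stop("dataset_specific mode requires an explicit gene list")
      as.character(genes)
    })
  panel <- panel[!duplicated(panel)]
  if (!length(panel))
    stop("no Y-panel genes found")
  structure(list(species = species, genes = panel, source = mode),
            class = "YGenePanel")
}

#' @export
print.YGenePanel <- function(x, ...) {
  cat("Y gene panel (", x$species, ", ", x$source, "): ",
      length(x$genes), " genes\n  ",
      paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Resolve a panel argument (YGenePanel or character vector) against the
# rownames of a matrix; warns about and drops unmatched panel genes.
match_panel <- function(panel, gene_ids) {
  genes <- if (inherits(panel, "YGenePanel")) panel$genes else
    as.character(panel)
  present <- genes %in% gene_ids
  if (!all(present))
    warning("panel genes absent from matrix, dropped: ",
            paste(genes[!present], collapse = ", "))
  genes[present]
}
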