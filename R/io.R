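# Cohort file input/output. All tables are plain TSV; peaks are BED
# (0-based half-open, via rtracklayer); coordinates in TSVs are 1-based
# inclusive.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_matrix_tsv <- function(mat, path, id_col) {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path, id_col) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- df[[id_col]]
  m
}

#' Write a synthetic cohort to a directory of standard files
#'
#' Emits the cohort as the analysis pipeline's input formats: copy-number
#' segments TSV, a combined probe-manifest + beta-value matrix TSV, a MAF-like
#' mutation TSV, a log2 expression matrix TSV, clinical TSV, gene-model TSV,
#' truth-label TSV, and a BED of open-chromatin peaks.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param directory output directory (created if missing).
#' @return invisibly, a manifest data.frame (`file`, `rows`).
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop(sprintf("cannot create output directory '%s'", directory))
  p <- function(f) file.path(directory, f)

  write_tsv(cohort$segments, p("segments.tsv"))
  meth <- data.frame(cohort$methylation$probes, cohort$methylation$beta,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(meth, p("methylation.tsv"))
  write_tsv(cohort$mutations, p("mutations.tsv"))
  write_matrix_tsv(cohort$expression, p("expression.tsv"), "gene")
  write_tsv(cohort$clinical, p("clinical.tsv"))
  write_tsv(cohort$genes, p("genes.tsv"))
  write_tsv(cohort$truth, p("truth.tsv"))
  gr <- GenomicRanges::GRanges(
    cohort$peaks$chromosome,
    IRanges::IRanges(cohort$peaks$start + 1L, cohort$peaks$end),
    name = cohort$peaks$name)
  rtracklayer::export(gr, p("peaks.bed"), format = "BED")

  manifest <- data.frame(
    file = c("segments.tsv", "methylation.tsv", "mutations.tsv",
             "expression.tsv", "clinical.tsv", "genes.tsv", "truth.tsv",
             "peaks.bed"),
    rows = c(nrow(cohort$segments), nrow(cohort$methylation$probes),
             nrow(cohort$mutations), nrow(cohort$expression),
             nrow(cohort$clinical), nrow(cohort$genes), nrow(cohort$truth),
             nrow(cohort$peaks)),
    stringsAsFactors = FALSE)
  write_tsv(manifest, p("manifest.tsv"))
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory directory containing the cohort files.
#' @return a `synthetic_cohort`-shaped list (without `config`).
#' @export
read_cohort <- function(directory) {
  p <- function(f) {
    fp <- file.path(directory, f)
    if (!file.exists(fp)) stop(sprintf("missing cohort file '%s'", fp))
    fp
  }
  meth <- read.delim(p("methylation.tsv"), check.names = FALSE,
                     stringsAsFactors = FALSE)
  probes <- meth[, c("probe", "chromosome", "position")]
  beta <- as.matrix(meth[, setdiff(names(meth),
                                   c("probe", "chromosome", "position")),
                         drop = FALSE])
  rownames(beta) <- probes$probe
  gr <- rtracklayer::import(p("peaks.bed"), format = "BED")
  peaks <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    stringsAsFactors = FALSE)
  structure(list(
    segments = read.delim(p("segments.tsv"), stringsAsFactors = FALSE),
    methylation = list(probes = probes, beta = beta),
    mutations = read.delim(p("mutations.tsv"), stringsAsFactors = FALSE),
    expression = read_matrix_tsv(p("expression.tsv"), "gene"),
    clinical = read.delim(p("clinical.tsv"), stringsAsFactors = FALSE),
    genes = read.delim(p("genes.tsv"), stringsAsFactors = FALSE),
    peaks = peaks,
    truth = read.delim(p("truth.tsv"), stringsAsFactors = FALSE),
    config = NULL), class = "synthetic_cohort")
}
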