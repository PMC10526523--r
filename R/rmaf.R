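# RNA-mutated allele frequency (RMAF): the fraction of RNA reads at a
# somatic-mutation site carrying the mutant allele. Near 1 the mutant allele
# is fully expressed (hemizygous or silenced wild type), near 0 the mutant
# is silenced, intermediate values indicate bi-allelic expression / XCI
# escape.

#' Drop Silent mutations
#'
#' Removes records whose annotation class is exactly `"Silent"`, preserving
#' the order of the rest.
#'
#' @param mutations data.frame with a `classification` column.
#' @return filtered data.frame.
#' @export
filter_silent <- function(mutations) {
  stopifnot("classification" %in% names(mutations))
  mutations[mutations$classification != "Silent", , drop = FALSE]
}

#' Compute RMAF from RNA allele counts
#'
#' `alt / (alt + ref)`, undefined (`NA`) below the coverage floor. Below
#' roughly 8 reads the 0.25 / 0.75 class boundaries cannot usefully separate
#' bi-allelic from mono-allelic expression, hence the default floor.
#'
#' @param alt_count,ref_count non-negative RNA read counts (vectorised).
#' @param min_coverage minimum `alt + ref` for a defined RMAF.
#' @return numeric vector in `[0, 1]` with `NA` where coverage is too low.
#' @export
compute_rmaf <- function(alt_count, ref_count, min_coverage = 8) {
  if (anyNA(alt_count) || anyNA(ref_count) ||
      any(alt_count < 0) || any(ref_count < 0))
    stop("allele counts must be non-negative")
  total <- alt_count + ref_count
  ifelse(total >= min_coverage, alt_count / total, NA_real_)
}

#' Classify mutation expression from RMAF
#'
#' `expressed` if RMAF >= 0.75; `non.expressed` if RMAF <= 0.25; `escape`
#' (bi-allelic expression) otherwise. Both boundary values belong to the
#' outer classes.
#'
#' @param rmaf numeric vector of defined RMAF values.
#' @return character vector of classes.
#' @export
classify_expression <- function(rmaf) {
  if (anyNA(rmaf)) stop("undefined RMAF; filter low-coverage records first")
  if (any(rmaf < 0 | rmaf > 1)) stop("RMAF must lie in [0, 1]")
  ifelse(rmaf >= 0.75, "expressed",
         ifelse(rmaf <= 0.25, "non.expressed", "escape"))
}

#' Annotate a mutation table with RMAF and expression class
#'
#' Convenience wrapper: drops Silent records, computes RMAF, classifies the
#' covered records, and leaves low-coverage records unclassified (`NA`) with
#' a warning.
#'
#' @param mutations MAF-like data.frame with `ref_count` and `alt_count`.
#' @param min_coverage see [compute_rmaf()].
#' @param drop_silent whether to remove Silent records first.
#' @return the table with `rmaf` and `expression_class` columns added.
#' @export
annotate_rmaf <- function(mutations, min_coverage = 8, drop_silent = TRUE) {
  if (drop_silent) mutations <- filter_silent(mutations)
  mutations$rmaf <- compute_rmaf(mutations$alt_count, mutations$ref_count,
                                 min_coverage)
  mutations$expression_class <- NA_character_
  ok <- !is.na(mutations$rmaf)
  mutations$expression_class[ok] <- classify_expression(mutations$rmaf[ok])
  if (any(!ok))
    warning(sprintf("%d mutation(s) below %d reads left unclassified",
                    sum(!ok), min_coverage))
  mutations
}

#' Expression-class by group contingency table with chi-square test
#'
#' Cross-tabulates mutation expression classes against per-sample group
#' labels and tests independence with Pearson's chi-square (no continuity
#' correction).
#'
#' @param mutations annotated table with `sample` and `expression_class`
#'   (unclassified records are dropped).
#' @param group_labels named character vector, sample -> group; every
#'   mutation's sample must be present.
#' @param simulate_p use Monte-Carlo p-value when expected counts are small.
#' @return list: `table` (class x group counts), `statistic`, `p_value`.
#' @export
expression_class_table <- function(mutations, group_labels,
                                   simulate_p = FALSE) {
  mut <- mutations[!is.na(mutations$expression_class), , drop = FALSE]
  missing <- setdiff(unique(mut$sample), names(group_labels))
  if (length(missing))
    stop(sprintf("samples without a group label: %s",
                 paste(head(missing, 5), collapse = ", ")))
  tab <- table(class = mut$expression_class,
               group = group_labels[mut$sample])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table has a degenerate margin")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE,
                                    simulate.p.value = simulate_p))
  list(table = tab, statistic = unname(ct$statistic),
       p_value = unname(ct$p.value))
}

#' Per-sample RMAF for one gene
#'
#' Mean RMAF over a gene's covered mutations per sample (e.g. TP53, where
#' values near 1 indicate loss of heterozygosity of the wild-type allele).
#' Samples without a covered mutation in the gene are absent from the
#' result.
#'
#' @param mutations annotated table with `gene`, `sample`, `rmaf`.
#' @param gene gene symbol.
#' @return named per-sample numeric vector.
#' @export
sample_level_rmaf <- function(mutations, gene) {
  if (!gene %in% mutations$gene)
    stop(sprintf("gene '%s' absent from mutation table", gene))
  mut <- mutations[mutations$gene == gene & !is.na(mutations$rmaf), ,
                   drop = FALSE]
  vapply(split(mut$rmaf, mut$sample), mean, numeric(1))
}
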