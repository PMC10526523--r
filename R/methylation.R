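# Promoter methylation: probe-to-gene assignment by TSS proximity,
# gene-level beta aggregation, per-sample X methylation, and the
# high/low/unaltered methylation clustering.

#' Assign methylation probes to gene promoters by TSS proximity
#'
#' A gene receives the probes lying within `near_bp` of its transcription
#' start site; if none exist there, the probes within `far_bp`; otherwise the
#' gene gets no methylation estimate. Distance is strand-agnostic
#' `|position - TSS|` (the TSS200 / TSS1500 convention of 450K annotation).
#' A probe may serve several genes if it falls in several windows.
#'
#' @param probes data.frame with columns `probe`, `chromosome`, `position`.
#' @param gene_models data.frame with columns `gene`, `chromosome`, `tss`.
#' @param near_bp,far_bp window half-widths in bp.
#' @return named list mapping gene -> character vector of probe ids; genes
#'   with no probe in either window are absent.
#' @export
assign_probes_to_genes <- function(probes, gene_models,
                                   near_bp = 200, far_bp = 1500) {
  stopifnot(all(c("probe", "chromosome", "position") %in% names(probes)),
            all(c("gene", "chromosome", "tss") %in% names(gene_models)))
  out <- list()
  for (i in seq_len(nrow(gene_models))) {
    on_chr <- probes$chromosome == gene_models$chromosome[i]
    d <- abs(probes$position - gene_models$tss[i])
    near <- on_chr & d <= near_bp
    hit <- if (any(near)) near else on_chr & d <= far_bp
    if (any(hit)) out[[gene_models$gene[i]]] <- probes$probe[hit]
  }
  out
}

#' Aggregate probe beta-values to gene promoter beta-values
#'
#' Gene-level beta is the mean of the assigned probes' non-missing
#' beta-values per sample; missing (`NA`) where every assigned probe is
#' missing. Missing values are propagated, never imputed.
#'
#' @param beta probe x sample matrix of beta-values in `[0, 1]` (NA allowed).
#' @param mapping gene -> probe-id list from [assign_probes_to_genes()].
#' @return gene x sample matrix with a row per mapped gene.
#' @export
gene_promoter_beta <- function(beta, mapping) {
  if (!length(mapping))
    return(matrix(numeric(0), 0, ncol(beta),
                  dimnames = list(character(0), colnames(beta))))
  missing_probes <- setdiff(unique(unlist(mapping)), rownames(beta))
  if (length(missing_probes))
    stop(sprintf("probes in mapping absent from beta matrix: %s",
                 paste(head(missing_probes, 5), collapse = ", ")))
  ok <- !is.na(beta)
  if (any(beta[ok] < 0 | beta[ok] > 1))
    stop("beta-values must lie in [0, 1]")
  out <- t(vapply(mapping, function(p) {
    colMeans(beta[p, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(beta))))
  out[is.nan(out)] <- NA_real_
  colnames(out) <- colnames(beta)
  out
}

#' Per-sample mean X-chromosome promoter methylation
#'
#' Unweighted mean of gene promoter beta-values over chromosome-X genes with
#' data; `NA` for a sample missing every X gene.
#'
#' @param gene_beta gene x sample matrix from [gene_promoter_beta()].
#' @param gene_models gene model table (`gene`, `chromosome`).
#' @param x_chrom chromosome name identifying X.
#' @return named per-sample numeric vector.
#' @export
mean_x_promoter_methylation <- function(gene_beta, gene_models,
                                        x_chrom = "chrX") {
  xg <- gene_models$gene[gene_models$chromosome == x_chrom]
  m <- gene_beta[rownames(gene_beta) %in% xg, , drop = FALSE]
  if (!nrow(m))
    stop("no chromosome-X genes with methylation data")
  res <- colMeans(m, na.rm = TRUE)
  res[is.nan(res)] <- NA_real_
  res
}

#' Cluster samples into high / low / unaltered X methylation groups
#'
#' Ward clustering on the Gower dissimilarity of the gene x sample beta
#' matrix (samples as objects), cut at `k`. Clusters are labelled by ranking
#' their centroid mean beta: highest centroid -> `high`, lowest -> `low`,
#' all others -> `unaltered`. With `k = 1` every sample is `unaltered`. If
#' the matrix carries no variation (all Gower columns zero-range) the
#' clustering is degenerate: every sample is labelled `unaltered` and the
#' result carries attribute `degenerate = TRUE`.
#'
#' @param gene_beta gene x sample matrix, typically restricted to X genes.
#' @param k number of clusters.
#' @return named character vector of labels (`high`/`low`/`unaltered`), with
#'   attribute `centroids` (mean beta per cluster).
#' @export
cluster_methylation_groups <- function(gene_beta, k = 3) {
  n <- ncol(gene_beta)
  if (k > n) stop(sprintf("k = %d exceeds the %d samples", k, n))
  samples <- colnames(gene_beta)
  if (k == 1) {
    lab <- setNames(rep("unaltered", n), samples)
    attr(lab, "centroids") <- c(unaltered = mean(gene_beta, na.rm = TRUE))
    return(lab)
  }
  d <- tryCatch(gower_dissimilarity(t(gene_beta)), error = function(e) NULL)
  if (is.null(d)) {
    lab <- setNames(rep("unaltered", n), samples)
    attr(lab, "degenerate") <- TRUE
    warning("no variation across samples; single unaltered methylation group")
    return(lab)
  }
  cl <- ward_cluster(d, k)
  cent <- vapply(split(seq_len(n), factor(cl, levels = seq_len(k))),
                 function(ix) mean(gene_beta[, ix], na.rm = TRUE), numeric(1))
  ord <- order(cent)                      # ascending centroid beta
  lab_by_cl <- rep("unaltered", k)
  lab_by_cl[ord[1]] <- "low"
  lab_by_cl[ord[k]] <- "high"
  lab <- setNames(lab_by_cl[cl], samples)
  attr(lab, "centroids") <- setNames(cent, lab_by_cl)
  lab
}
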