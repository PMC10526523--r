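# Covariate-adjusted differential expression with empirical-Bayes variance
# moderation, FDR/logFC signature selection, per-sample signature scoring,
# and gene-set enrichment.

#' Fit per-gene linear models of expression on a group contrast
#'
#' Ordinary least squares of log2 expression on
#' `[intercept, group, subtype dummies]`. The subtype covariate absorbs the
#' uneven molecular-subtype composition of the contrast groups; it is
#' treatment-coded with the most frequent subtype as reference. The group
#' coefficient is the log2 fold change of group versus reference.
#'
#' @param expression gene x sample log2 matrix.
#' @param group logical or two-level factor over samples (columns); `TRUE` /
#'   second level is the contrast group.
#' @param covariates optional per-sample subtype labels (character/factor).
#' @return data.frame per gene: `gene`, `logFC`, `stdev_unscaled` (unscaled
#'   standard deviation of the group coefficient), `sigma2` (residual
#'   variance), `df` (residual degrees of freedom).
#' @export
fit_gene_models <- function(expression, group, covariates = NULL) {
  n <- ncol(expression)
  if (length(group) != n) stop("group length must match sample count")
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  if (min(table(g)) < 2) stop("need at least 2 samples per group")
  dat <- data.frame(.group = g)
  if (!is.null(covariates)) {
    cv <- factor(covariates)
    cv <- stats::relevel(cv, ref = names(which.max(table(cv))))
    dat$.subtype <- cv
  }
  X <- model.matrix(if (is.null(covariates)) ~.group else ~.group + .subtype,
                    dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank-deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  fit <- lm.fit(X, t(expression))
  coefs <- t(fit$coefficients)
  df <- n - ncol(X)
  if (df < 1) stop("no residual degrees of freedom")
  res <- t(fit$residuals)
  sigma2 <- rowSums(res^2) / df
  xtxi <- chol2inv(qr.R(qrX))
  gcol <- grep("^\\.groupTRUE$|^\\.group", colnames(X))[1]
  data.frame(gene = rownames(expression),
             logFC = unname(coefs[, gcol]),
             stdev_unscaled = sqrt(xtxi[gcol, gcol]),
             sigma2 = unname(sigma2), df = df,
             stringsAsFactors = FALSE)
}

# Newton solver for trigamma(y) = x, vectorised.
trigamma_inverse <- function(x) {
  y <- ifelse(x > 1e7, 1 / sqrt(x), 0.5 + 1 / x)
  small <- !is.na(x) & x < 1e-6
  y[small] <- 1 / x[small]
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(-dif / y, na.rm = TRUE) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-gene residual variances
#'
#' Fits a scaled inverse-chi-square prior (`prior_df` d0, `prior_var` s0^2)
#' to the gene-wise residual variances by the method of moments on log
#' variances, using the digamma/trigamma identities of the log-chi-square
#' distribution, and shrinks each variance towards the prior:
#' `post = (d0 * s0^2 + df * s^2) / (d0 + df)`. With `d0 = 0` the posterior
#' equals the observed variance (ordinary t); with `d0 = Inf` every
#' posterior equals `s0^2`.
#'
#' @param sigma2 positive per-gene residual variances (>= 10 genes).
#' @param df residual degrees of freedom (scalar or per gene).
#' @return list: `prior_df`, `prior_var`, `post_var`, `total_df`
#'   (`df + prior_df`, the degrees of freedom of the moderated t).
#' @export
moderate_variances <- function(sigma2, df) {
  if (length(sigma2) < 10) stop("need at least 10 genes to fit the prior")
  if (anyNA(sigma2) || any(sigma2 <= 0))
    stop("residual variances must be positive")
  df <- rep_len(df, length(sigma2))
  z <- log(sigma2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s02 + df * sigma2) / (d0 + df)
  } else {
    # no excess dispersion beyond sampling noise: infinite prior df
    d0 <- Inf
    s02 <- mean(sigma2)
    post <- rep(s02, length(sigma2))
  }
  list(prior_df = d0, prior_var = s02, post_var = post, total_df = df + d0)
}

#' Moderated-t differential expression table
#'
#' Combines [fit_gene_models()] and [moderate_variances()]: moderated t is
#' the group coefficient over its posterior standard error, with
#' `df + prior_df` degrees of freedom; p-values are two-sided and adjusted
#' by Benjamini-Hochberg.
#'
#' @param expression,group,covariates as in [fit_gene_models()].
#' @param moderate set `FALSE` for ordinary t-statistics.
#' @return data.frame: `gene`, `logFC`, `t`, `p`, `fdr`, `residual_df`,
#'   `prior_df`, `prior_var`.
#' @export
de_analysis <- function(expression, group, covariates = NULL,
                        moderate = TRUE) {
  fit <- fit_gene_models(expression, group, covariates)
  if (moderate) {
    mod <- moderate_variances(fit$sigma2, fit$df)
    tstat <- fit$logFC / (fit$stdev_unscaled * sqrt(mod$post_var))
    tdf <- mod$total_df
    prior_df <- mod$prior_df; prior_var <- mod$prior_var
  } else {
    tstat <- fit$logFC / (fit$stdev_unscaled * sqrt(fit$sigma2))
    tdf <- fit$df
    prior_df <- 0; prior_var <- NA_real_
  }
  p <- if (all(is.infinite(tdf))) 2 * stats::pnorm(-abs(tstat))
       else 2 * pt(-abs(tstat), df = tdf)
  data.frame(gene = fit$gene, logFC = fit$logFC, t = tstat, p = p,
             fdr = bh_fdr(p), residual_df = fit$df,
             prior_df = prior_df, prior_var = prior_var,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Select a directed gene signature from a differential-expression table
#'
#' Genes passing `fdr <= fdr_max` with a strictly negative (`down`) or
#' strictly positive (`up`) logFC; weight is the sign of logFC.
#'
#' @param de_results data.frame from [de_analysis()].
#' @param direction `"down"` or `"up"`.
#' @param fdr_max FDR threshold.
#' @param name signature name.
#' @return a `signature` list: `name`, `genes` data.frame (`gene`, `weight`),
#'   `provenance`. Empty selection gives a warning and an empty signature.
#' @export
select_signature <- function(de_results, direction = c("down", "up"),
                             fdr_max = 0.05, name = NULL) {
  direction <- match.arg(direction)
  keep <- de_results$fdr <= fdr_max &
    (if (direction == "down") de_results$logFC < 0 else de_results$logFC > 0)
  sel <- de_results[keep, , drop = FALSE]
  if (!nrow(sel)) warning("no genes pass the signature filters")
  structure(list(
    name = name %||% paste0("signature_", direction),
    genes = data.frame(gene = sel$gene, weight = sign(sel$logFC)),
    provenance = list(direction = direction, fdr_max = fdr_max,
                      n_tested = nrow(de_results))),
    class = "signature")
}

#' Per-sample signature score
#'
#' Each signature gene's expression row is robustly rescaled to `[-1, 1]`
#' via its `quantiles` (default 2.5% / 97.5%) with clipping; the score is
#' the weight-normalised sum `sum(w_i * x_i) / sum(|w_i|)`. Signature genes
#' absent from the matrix are dropped with a warning.
#'
#' @param expression gene x sample log2 matrix.
#' @param signature a `signature` from [select_signature()], or a
#'   data.frame with `gene` and `weight`.
#' @param quantiles lower/upper rescaling quantiles.
#' @return named per-sample numeric score vector.
#' @export
sig_score <- function(expression, signature, quantiles = c(0.025, 0.975)) {
  genes <- if (inherits(signature, "signature")) signature$genes else signature
  present <- genes$gene %in% rownames(expression)
  if (any(!present))
    warning(sprintf("%d signature gene(s) absent from expression matrix",
                    sum(!present)))
  genes <- genes[present, , drop = FALSE]
  if (!nrow(genes)) stop("no usable signature genes in expression matrix")
  x <- expression[genes$gene, , drop = FALSE]
  scaled <- t(apply(x, 1, function(v) {
    q <- quantile(v, quantiles, na.rm = TRUE, names = FALSE)
    if (q[2] <= q[1]) return(rep(0, length(v)))
    2 * (pmin(pmax(v, q[1]), q[2]) - q[1]) / (q[2] - q[1]) - 1
  }))
  setNames(colSums(scaled * genes$weight) / sum(abs(genes$weight)),
           colnames(expression))
}

#' Upper-tail hypergeometric enrichment of a gene set in a region
#'
#' Probability of observing at least the actual overlap between the
#' signature and the region gene set when drawing `|signature|` genes
#' without replacement from the universe.
#'
#' @param signature_genes,region_genes,universe character vectors;
#'   both sets must be subsets of `universe`.
#' @return list: `overlap`, `p_value`.
#' @export
hypergeometric_enrichment <- function(signature_genes, region_genes,
                                      universe) {
  signature_genes <- unique(signature_genes)
  region_genes <- unique(region_genes)
  universe <- unique(universe)
  if (!all(region_genes %in% universe))
    stop("region genes must be a subset of the universe")
  if (!all(signature_genes %in% universe))
    stop("signature genes must be a subset of the universe")
  k <- length(intersect(signature_genes, region_genes))
  p <- phyper(k - 1, length(region_genes),
              length(universe) - length(region_genes),
              length(signature_genes), lower.tail = FALSE)
  list(overlap = k, p_value = p)
}

#' Overlap between two signatures
#'
#' @param sig_a_genes,sig_b_genes character vectors of gene symbols.
#' @return list: `shared` genes, `pct_of_a`, `pct_of_b` (nearest integer
#'   percent of each signature the intersection represents; `NA` for an
#'   empty signature).
#' @export
signature_overlap <- function(sig_a_genes, sig_b_genes) {
  a <- unique(sig_a_genes); b <- unique(sig_b_genes)
  shared <- intersect(a, b)
  list(shared = shared,
       pct_of_a = if (length(a)) round(100 * length(shared) / length(a)) else NA_real_,
       pct_of_b = if (length(b)) round(100 * length(shared) / length(b)) else NA_real_)
}

#' Promoter methylation inside versus outside open chromatin
#'
#' Flags each signature gene as inside open chromatin iff its TSS +/-
#' `window_bp` intersects any ATAC peak, then compares mean promoter
#' methylation between the inside and outside gene sets with Welch's
#' two-sample t-test.
#'
#' @param gene_beta gene x sample promoter beta matrix (selected tumours).
#' @param signature_genes genes to test (must have rows in `gene_beta` and
#'   entries in `gene_models`).
#' @param gene_models table with `gene`, `chromosome`, `tss`.
#' @param peaks data.frame (`chromosome`, `start`, `end`), BED-style 0-based
#'   half-open coordinates.
#' @param window_bp promoter window half-width.
#' @return list: `inside` logical by gene, `statistic`, `p_value`,
#'   `mean_inside`, `mean_outside`.
#' @export
open_chromatin_contrast <- function(gene_beta, signature_genes, gene_models,
                                    peaks, window_bp = 1000) {
  gm <- gene_models[match(signature_genes, gene_models$gene), , drop = FALSE]
  if (anyNA(gm$gene)) stop("signature genes missing from gene models")
  keep <- gm$gene %in% rownames(gene_beta)
  gm <- gm[keep, , drop = FALSE]
  if (!nrow(gm)) stop("no signature genes with methylation data")
  tss_gr <- GenomicRanges::GRanges(
    gm$chromosome,
    IRanges::IRanges(pmax(1, gm$tss - window_bp), gm$tss + window_bp))
  peak_gr <- GenomicRanges::GRanges(
    peaks$chromosome, IRanges::IRanges(peaks$start + 1L, peaks$end))
  inside <- IRanges::overlapsAny(tss_gr, peak_gr)
  names(inside) <- gm$gene
  if (sum(inside) < 2 || sum(!inside) < 2)
    stop("need at least two genes inside and two outside open chromatin")
  mb <- rowMeans(gene_beta[gm$gene, , drop = FALSE], na.rm = TRUE)
  tt <- t.test(mb[inside], mb[!inside])
  list(inside = inside, statistic = unname(tt$statistic),
       p_value = tt$p.value, mean_inside = mean(mb[inside]),
       mean_outside = mean(mb[!inside]))
}
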