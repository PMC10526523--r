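# Allele-specific copy number on chrX: binning of segments, Gower/Ward
# clustering, and the nested Xi-deletion -> Xa-amplification ->
# methylation-group assignment cascade.

#' Define equal-width chrX bins
#'
#' @param n_bins number of bins.
#' @param bin_size_bp width of each bin; coordinates are 1-based inclusive.
#' @return data.frame (`bin`, `start`, `end`) tiling `[1, n_bins * bin_size_bp]`.
#' @export
make_bins <- function(n_bins, bin_size_bp) {
  data.frame(bin = seq_len(n_bins),
             start = (seq_len(n_bins) - 1) * bin_size_bp + 1,
             end = seq_len(n_bins) * bin_size_bp)
}

#' Project copy-number segments onto fixed bins
#'
#' For each sample and bin, computes the length-weighted mean copy number of
#' the chosen allele over the segments overlapping the bin. Bins with no
#' segment coverage are imputed with the sample's modal covered-bin value and
#' flagged in the `imputed` attribute; this avoids spurious dissimilarity
#' from missing telomeric segments.
#'
#' @param segments data.frame (`sample`, `chromosome`, `start`, `end`,
#'   `major_cn`, `minor_cn`), 1-based inclusive, chrX only.
#' @param bins from [make_bins()].
#' @param allele `"minor"` (Xi proxy) or `"major"` (Xa proxy).
#' @return sample x bin numeric matrix with logical attribute `imputed`.
#' @export
bin_segments <- function(segments, bins, allele = c("minor", "major")) {
  allele <- match.arg(allele)
  cn_col <- paste0(allele, "_cn")
  stopifnot(all(c("sample", "start", "end", cn_col) %in% names(segments)))
  if (nrow(segments) && any(segments$start > segments$end))
    stop("segments with start > end")
  samples <- unique(segments$sample)
  m <- matrix(NA_real_, length(samples), nrow(bins),
              dimnames = list(samples, NULL))
  imputed <- matrix(FALSE, length(samples), nrow(bins),
                    dimnames = list(samples, NULL))
  bin_ir <- IRanges::IRanges(bins$start, bins$end)
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    seg_ir <- IRanges::IRanges(seg$start, seg$end)
    cov <- IRanges::coverage(seg_ir)
    if (any(S4Vectors::runValue(cov) > 1)) {
      ovl <- IRanges::findOverlaps(seg_ir, drop.self = TRUE, drop.redundant = TRUE)
      bad <- unique(c(S4Vectors::queryHits(ovl), S4Vectors::subjectHits(ovl)))
      stop(sprintf("overlapping segments for sample %s (rows %s)",
                   s, paste(sort(bad), collapse = ", ")))
    }
    hits <- IRanges::findOverlaps(bin_ir, seg_ir)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); h <- S4Vectors::subjectHits(hits)
      w <- IRanges::width(IRanges::pintersect(bin_ir[q], seg_ir[h]))
      num <- tapply(w * seg[[cn_col]][h], q, sum)
      den <- tapply(w, q, sum)
      m[s, as.integer(names(num))] <- num / den
    }
    miss <- is.na(m[s, ])
    if (any(miss)) {
      m[s, miss] <- modal_value(m[s, !miss])
      imputed[s, miss] <- TRUE
    }
  }
  attr(m, "imputed") <- imputed
  m
}

#' Gower dissimilarity for a numeric matrix
#'
#' Range-normalised mean absolute difference: for samples i, j, the mean
#' over columns of `|x_ic - x_jc| / range(column c)`, skipping zero-range
#' columns. Symmetric with zero diagonal, bounded by `[0, 1]`.
#'
#' @param x sample x variable numeric matrix (rows are objects).
#' @return a `dist` object.
#' @export
gower_dissimilarity <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  rng <- apply(x, 2, function(v) diff(range(v)))
  keep <- rng > 0
  if (!any(keep)) stop("all columns have zero range")
  xs <- sweep(x[, keep, drop = FALSE], 2, rng[keep], `/`)
  dist(xs, method = "manhattan") / sum(keep)
}

#' Ward hierarchical clustering of a dissimilarity matrix, cut at k
#'
#' Agglomerative clustering with the Ward criterion (squared-dissimilarity
#' update; `stats::hclust(method = "ward.D2")`), tree cut to `k` groups.
#'
#' @param dissimilarity a `dist` or symmetric matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer cluster labels named by sample.
#' @export
ward_cluster <- function(dissimilarity, k) {
  if (is.matrix(dissimilarity)) {
    if (!isSymmetric(unname(dissimilarity)))
      stop("dissimilarity matrix must be symmetric")
    dissimilarity <- as.dist(dissimilarity)
  }
  n <- attr(dissimilarity, "Size")
  if (k < 1 || k > n) stop(sprintf("k must be in [1, %d]", n))
  if (k == n) {
    lab <- seq_len(n)
    names(lab) <- attr(dissimilarity, "Labels") %||% as.character(lab)
    return(lab)
  }
  cutree(hclust(dissimilarity, method = "ward.D2"), k = k)
}

# Two-way clustering plus labelling by an aberration statistic: the cluster
# whose mean fraction of bins beyond `threshold` (direction-dependent) is
# larger gets `aberrant_label`; ties label the larger cluster unaltered.
.cluster_aberration <- function(mat, aberrant_label, unaltered_label,
                                frac_fun, k = 2) {
  samples <- rownames(mat)
  if (nrow(mat) < 2) stop("need at least 2 samples to cluster")
  d <- tryCatch(gower_dissimilarity(mat), error = function(e) NULL)
  if (is.null(d)) {
    warning("no copy-number variation; single unaltered group")
    return(setNames(rep(unaltered_label, nrow(mat)), samples))
  }
  cl <- ward_cluster(d, k)
  frac <- vapply(split(seq_len(nrow(mat)), factor(cl, levels = seq_len(k))),
                 function(ix) mean(frac_fun(mat[ix, , drop = FALSE])),
                 numeric(1))
  sizes <- tabulate(cl, k)
  ab <- which.max(frac)
  if (sum(frac == max(frac)) > 1) {
    # tie on the labelling statistic: the larger cluster is unaltered
    tied <- which(frac == max(frac))
    ab <- tied[which.min(sizes[tied])]
  }
  setNames(ifelse(cl == ab, aberrant_label, unaltered_label), samples)
}

#' Assign Xi-deletion groups from the minor-allele bin matrix
#'
#' Ward clustering (k = 2) on the Gower dissimilarity of the minor-allele
#' copy-number matrix; the cluster with the larger mean fraction of bins at
#' copy number < 0.5 is labelled `Xi-large-deletion`, the other
#' `Xi-unaltered`. The minor allele proxies the inactive X: its loss leaves
#' a hemizygous active X.
#'
#' @param minor_matrix sample x bin matrix from
#'   `bin_segments(..., allele = "minor")`.
#' @param k number of clusters.
#' @return named character labels.
#' @export
assign_xi_groups <- function(minor_matrix, k = 2) {
  .cluster_aberration(minor_matrix, "Xi-large-deletion", "Xi-unaltered",
                      function(m) rowMeans(m < 0.5), k)
}

#' Assign Xa-amplification groups from the major-allele bin matrix
#'
#' As [assign_xi_groups()], on Xi-unaltered samples only: the cluster with
#' the larger mean fraction of bins at copy number > 1.5 is labelled
#' `Xa-large-amplification`.
#'
#' @param major_matrix sample x bin matrix restricted to Xi-unaltered
#'   samples.
#' @param k number of clusters.
#' @return named character labels (empty for an empty input).
#' @export
assign_xa_groups <- function(major_matrix, k = 2) {
  if (!nrow(major_matrix)) return(setNames(character(0), character(0)))
  .cluster_aberration(major_matrix, "Xa-large-amplification", "Xa-unaltered",
                      function(m) rowMeans(m > 1.5), k)
}

#' Run the three-tier aberration-assignment cascade
#'
#' Tier 1 clusters all samples by minor-allele (Xi) copy number; tier 2
#' clusters the Xi-unaltered samples by major-allele (Xa) copy number;
#' tier 3 clusters the Xa-unaltered samples with methylation data into
#' high / low / unaltered X promoter methylation groups. Samples unaltered
#' at every tier are flagged `selected_unaltered` — the reference group for
#' the differential-expression contrasts.
#'
#' @param segments chrX segment table (see [bin_segments()]).
#' @param gene_beta gene x sample promoter beta matrix restricted to X genes
#'   (may omit samples; those get methylation group `not-applicable`).
#' @param bins from [make_bins()].
#' @param k_cn,k_meth cluster counts for the copy-number and methylation
#'   tiers.
#' @return data.frame (`sample`, `xi_group`, `xa_group`, `methylation_group`,
#'   `selected_unaltered`).
#' @export
run_cascade <- function(segments, gene_beta, bins, k_cn = 2, k_meth = 3) {
  samples <- unique(segments$sample)
  if (!length(samples)) stop("no samples in segment table")
  minor <- bin_segments(segments, bins, "minor")
  xi <- assign_xi_groups(minor, k_cn)
  xi_unalt <- names(xi)[xi == "Xi-unaltered"]

  xa <- setNames(rep("not-applicable", length(samples)), samples)
  if (length(xi_unalt) >= 2) {
    major <- bin_segments(segments[segments$sample %in% xi_unalt, , drop = FALSE],
                          bins, "major")
    xa[rownames(major)] <- assign_xa_groups(major, k_cn)
  } else if (length(xi_unalt)) {
    xa[xi_unalt] <- "Xa-unaltered"
  }

  meth <- setNames(rep("not-applicable", length(samples)), samples)
  xa_unalt <- names(xa)[xa == "Xa-unaltered"]
  with_meth <- intersect(xa_unalt, colnames(gene_beta))
  if (length(with_meth) >= k_meth) {
    mg <- cluster_methylation_groups(gene_beta[, with_meth, drop = FALSE],
                                     k = k_meth)
    meth[names(mg)] <- mg
  } else if (length(with_meth)) {
    meth[with_meth] <- "unaltered"
  }

  data.frame(sample = samples,
             xi_group = unname(xi[samples]),
             xa_group = unname(xa[samples]),
             methylation_group = unname(meth[samples]),
             selected_unaltered = unname(
               xi[samples] == "Xi-unaltered" &
               xa[samples] == "Xa-unaltered" &
               meth[samples] == "unaltered"),
             stringsAsFactors = FALSE)
}
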