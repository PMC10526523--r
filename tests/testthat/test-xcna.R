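seg_row <- function(sample, start, end, major, minor)
  data.frame(sample = sample, chromosome = "chrX", start = start, end = end,
             major_cn = major, minor_cn = minor)

test_that("segment binning: full coverage, length weighting, imputation", {
  bins <- make_bins(4, 100)
  # one segment covering all bins with minor 0
  m <- bin_segments(seg_row("a", 1, 400, 1, 0), bins, "minor")
  expect_equal(unname(m["a", ]), rep(0, 4))
  # two segments with cn 0 and 1, each covering half of bin 1
  segs <- rbind(seg_row("a", 1, 50, 1, 0), seg_row("a", 51, 400, 1, 1))
  m <- bin_segments(segs, bins, "minor")
  expect_equal(unname(m["a", 1]), 0.5)
  expect_equal(unname(m["a", 2:4]), rep(1, 3))
  # uncovered bin takes the modal value and is flagged
  m <- bin_segments(seg_row("a", 1, 300, 2, 1), bins, "major")
  expect_equal(unname(m["a", 4]), 2)
  expect_true(attr(m, "imputed")["a", 4])
  expect_false(any(attr(m, "imputed")["a", 1:3]))
  # overlapping segments are rejected with offenders listed
  expect_error(bin_segments(rbind(seg_row("a", 1, 100, 1, 1),
                                  seg_row("a", 50, 200, 1, 1)),
                            bins, "minor"), "overlapping")
})

test_that("binning matches the interval-arithmetic oracle", {
  bins <- make_bins(5, 1000)
  set.seed(8)
  segs <- do.call(rbind, lapply(c("s1", "s2", "s3"), function(s) {
    cuts <- sort(sample(2:4999, 3))
    starts <- c(1, cuts + 1)
    ends <- c(cuts, 5000)
    data.frame(sample = s, chromosome = "chrX", start = starts, end = ends,
               major_cn = sample(1:3, 4, TRUE), minor_cn = sample(0:1, 4, TRUE))
  }))
  for (al in c("minor", "major")) {
    m <- bin_segments(segs, bins, al)
    o <- bin_oracle(segs, bins, paste0(al, "_cn"))
    expect_equal(unclass(m)[, ], o[rownames(m), ], ignore_attr = TRUE)
  }
})

test_that("binning conserves copy-number mass on fully covered chromosomes", {
  bins <- make_bins(10, 500)
  set.seed(9)
  cuts <- sort(sample(2:4999, 6))
  segs <- data.frame(sample = "s", chromosome = "chrX",
                     start = c(1, cuts + 1), end = c(cuts, 5000),
                     major_cn = sample(1:3, 7, TRUE),
                     minor_cn = sample(0:1, 7, TRUE))
  m <- bin_segments(segs, bins, "minor")
  seg_mass <- sum((segs$end - segs$start + 1) * segs$minor_cn) / 5000
  expect_equal(mean(m["s", ]), seg_mass, tolerance = 1e-9)
})

test_that("Gower dissimilarity matches its definition", {
  x <- rbind(a = c(0, 5), b = c(0, 5), c = c(10, 0))
  d <- as.matrix(gower_dissimilarity(x))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)   # both columns at full range
  set.seed(10)
  y <- matrix(rnorm(12), 4, 3)
  expect_equal(as.matrix(gower_dissimilarity(y)), gower_oracle(y),
               ignore_attr = TRUE)
  # symmetry, zero diagonal, [0, 1] bounds
  dm <- as.matrix(gower_dissimilarity(y))
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 4))
  expect_true(all(dm >= 0 & dm <= 1))
  # zero-range columns are skipped; all-constant input errors
  y2 <- cbind(y, 7)
  expect_equal(as.matrix(gower_dissimilarity(y2)),
               gower_oracle(y2), ignore_attr = TRUE)
  expect_error(gower_dissimilarity(matrix(3, 4, 2)), "zero range")
})

test_that("Ward clustering separates planted clouds and handles edges", {
  set.seed(12)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 10), 20))
  rownames(x) <- sprintf("s%02d", 1:40)
  cl <- ward_cluster(gower_dissimilarity(x), 2)
  expect_equal(ari(cl, rep(1:2, each = 20)), 1)
  expect_equal(length(unique(ward_cluster(gower_dissimilarity(x), 40))), 40)
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ward_cluster(bad, 2), "symmetric")
  expect_error(ward_cluster(gower_dissimilarity(x), 41), "k must be")
})

test_that("Xi groups: label by deleted-bin fraction, degenerate collapses", {
  m <- rbind(matrix(0, 5, 8), matrix(1, 6, 8))
  rownames(m) <- sprintf("s%02d", 1:11)
  lab <- assign_xi_groups(m)
  expect_true(all(lab[1:5] == "Xi-large-deletion"))
  expect_true(all(lab[6:11] == "Xi-unaltered"))
  expect_warning(lab1 <- assign_xi_groups(matrix(1, 4, 3,
    dimnames = list(paste0("s", 1:4), NULL))), "variation")
  expect_true(all(lab1 == "Xi-unaltered"))
})

test_that("Xa groups: label by amplified-bin fraction, empty input ok", {
  m <- rbind(matrix(3, 4, 8), matrix(1, 7, 8))
  rownames(m) <- sprintf("s%02d", 1:11)
  lab <- assign_xa_groups(m)
  expect_true(all(lab[1:4] == "Xa-large-amplification"))
  expect_true(all(lab[5:11] == "Xa-unaltered"))
  expect_equal(length(assign_xa_groups(matrix(numeric(0), 0, 5))), 0)
})

test_that("the cascade recovers planted groups and nests its tiers", {
  co <- generate_cohort(sim_config(n_samples = 200, seed = 5))
  gm_x <- co$genes[co$genes$chromosome == "chrX", ]
  mapping <- assign_probes_to_genes(co$methylation$probes, gm_x)
  gb <- gene_promoter_beta(co$methylation$beta, mapping)
  bins <- make_bins(100, 1500000)
  asg <- run_cascade(co$segments, gb, bins)
  tr <- co$truth[match(asg$sample, co$truth$sample), ]
  expect_gte(ari(asg$xi_group, tr$xi_truth), 0.9)
  t2 <- asg$xa_group != "not-applicable"
  expect_gte(ari(asg$xa_group[t2], tr$xa_truth[t2]), 0.9)
  t3 <- asg$methylation_group != "not-applicable"
  expect_gte(ari(asg$methylation_group[t3], tr$meth_truth[t3]), 0.9)
  # nesting: tier 2 runs exactly on the Xi-unaltered samples,
  # tier 3 on the Xa-unaltered samples (all have methylation here)
  expect_equal(sum(t2), sum(asg$xi_group == "Xi-unaltered"))
  expect_equal(sum(t3), sum(asg$xa_group == "Xa-unaltered"))
  # selected-unaltered means unaltered at every tier
  sel <- asg$selected_unaltered
  expect_true(all(asg$xi_group[sel] == "Xi-unaltered"))
  expect_true(all(asg$xa_group[sel] == "Xa-unaltered"))
  expect_true(all(asg$methylation_group[sel] == "unaltered"))
  # each sample gets exactly one label per applicable tier
  expect_equal(anyDuplicated(asg$sample), 0)
})

test_that("samples without methylation get a not-applicable tier-3 label", {
  co <- generate_cohort(sim_config(n_samples = 60, seed = 77))
  gm_x <- co$genes[co$genes$chromosome == "chrX", ]
  gb <- gene_promoter_beta(co$methylation$beta,
                           assign_probes_to_genes(co$methylation$probes, gm_x))
  drop <- colnames(gb)[1:10]
  gb2 <- gb[, setdiff(colnames(gb), drop), drop = FALSE]
  bins <- make_bins(100, 1500000)
  asg <- run_cascade(co$segments, gb2, bins)
  dropped <- asg[asg$sample %in% drop, ]
  expect_true(all(dropped$methylation_group == "not-applicable"))
  expect_true(all(dropped$xi_group %in%
                  c("Xi-large-deletion", "Xi-unaltered")))
  expect_true(!any(dropped$selected_unaltered))
})

test_that("an all-unaltered cohort is fully selected", {
  segs <- do.call(rbind, lapply(sprintf("s%02d", 1:6), function(s)
    seg_row(s, 1, 1000, 1, 1)))
  gb <- matrix(0.45, 4, 6,
               dimnames = list(paste0("g", 1:4), sprintf("s%02d", 1:6)))
  bins <- make_bins(10, 100)
  asg <- suppressWarnings(run_cascade(segs, gb, bins))
  expect_true(all(asg$selected_unaltered))
})
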