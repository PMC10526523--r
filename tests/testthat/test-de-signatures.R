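expr_mat <- function(v, samples) {
  m <- matrix(v, nrow = 1, dimnames = list("g1", samples))
  m
}

test_that("per-gene OLS recovers the group difference and flags confounds", {
  e <- rbind(g1 = c(5, 5, 5, 7, 7, 7), g2 = c(1, 2, 3, 1, 2, 3))
  colnames(e) <- paste0("s", 1:6)
  grp <- rep(c(FALSE, TRUE), each = 3)
  fit <- fit_gene_models(e, grp)
  expect_equal(fit$logFC[fit$gene == "g1"], 2)
  expect_equal(fit$logFC[fit$gene == "g2"], 0)
  expect_equal(fit$df[1], 4)
  # group indicator identical to a subtype dummy -> rank-deficient
  expect_error(fit_gene_models(e, grp, covariates = ifelse(grp, "a", "b")),
               "rank-deficient")
  expect_error(fit_gene_models(e, rep(TRUE, 6)), "two levels")
})

test_that("planted log-fold changes are recovered with covariates", {
  set.seed(14)
  n <- 50; genes <- 200
  grp <- rep(c(FALSE, TRUE), each = n)
  subtype <- sample(c("A", "B", "C"), 2 * n, TRUE, c(0.5, 0.3, 0.2))
  base <- rnorm(genes, 8, 1)
  e <- matrix(rnorm(genes * 2 * n, 0, 0.5), genes) + base
  # subtype B shifts everything, group shifts by 1
  e <- e + rep(0.5 * (subtype == "B"), each = genes)
  e <- e + rep(1.0 * grp, each = genes)
  dimnames(e) <- list(sprintf("g%03d", 1:genes), sprintf("s%03d", 1:(2 * n)))
  fit <- fit_gene_models(e, grp, subtype)
  expect_lt(abs(mean(fit$logFC) - 1.0), 0.1)
})

test_that("variance moderation: exact degenerate limits", {
  # all variances equal: no shrinkage target other than the common value
  mod <- moderate_variances(rep(2, 50), df = 10)
  expect_equal(mod$prior_df, Inf)
  expect_equal(mod$prior_var, 2)
  expect_equal(mod$post_var, rep(2, 50))
  # formula limits: d0 = 0 leaves variances unchanged; d0 -> Inf gives s0^2
  s2 <- c(0.5, 1, 2); df <- 10
  expect_equal((0 * 1 + df * s2) / (0 + df), s2)
  mod2 <- moderate_variances(exp(rnorm(100)), df = 10)
  if (is.finite(mod2$prior_df)) {
    big <- (1e12 * mod2$prior_var + df * s2) / (1e12 + df)
    expect_equal(big, rep(mod2$prior_var, 3), tolerance = 1e-6)
  }
  expect_error(moderate_variances(c(rep(1, 20), -1), 10), "positive")
  expect_error(moderate_variances(rep(1, 5), 10), "at least 10")
})

test_that("a known inverse-chi-square prior is recovered", {
  set.seed(15)
  d0 <- 4; s02 <- 1; df <- 16; genes <- 2000
  true_var <- d0 * s02 / rchisq(genes, d0)
  s2 <- true_var * rchisq(genes, df) / df
  mod <- moderate_variances(s2, df)
  expect_lt(abs(mod$prior_df - d0) / d0, 0.25)
  expect_lt(abs(mod$prior_var - s02) / s02, 0.10)
})

test_that("moderation agrees with the reference empirical-Bayes fit", {
  set.seed(16)
  s2 <- (2 / rchisq(500, 5)) * rchisq(500, 12) / 12
  mod <- moderate_variances(s2, 12)
  ref <- limma::fitFDist(s2, df1 = 12)
  expect_equal(mod$prior_var, ref$scale, tolerance = 1e-6)
  expect_equal(mod$prior_df, ref$df2, tolerance = 1e-6)
  # full moderated t pipeline against limma::eBayes on a simulated matrix
  n <- 16; genes <- 300
  grp <- rep(c(0, 1), each = n / 2)
  e <- matrix(rnorm(genes * n, 0, rep(sqrt(s2[1:genes]), n)), genes, n)
  e[1:30, grp == 1] <- e[1:30, grp == 1] + 1
  dimnames(e) <- list(sprintf("g%03d", 1:genes), sprintf("s%02d", 1:n))
  de <- de_analysis(e, grp == 1)
  lfit <- limma::eBayes(limma::lmFit(e, cbind(1, grp)))
  expect_equal(de$logFC, unname(lfit$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(de$t, unname(lfit$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p, unname(lfit$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment matches the hand step-up and stays calibrated", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(18)
  for (i in 1:20) {
    p <- runif(50)
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  # null calibration: fraction of replicates with any discovery ~ 0.05
  set.seed(19)
  hits <- mean(replicate(200, any(bh_fdr(runif(1000)) <= 0.05)))
  expect_lt(abs(hits - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("signature selection honours FDR and strict sign constraints", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   logFC = c(-1, 1, -2, 0),
                   fdr = c(0.04, 0.04, 0.2, 0.01))
  down <- select_signature(de, "down")
  expect_equal(down$genes$gene, "a")
  expect_equal(down$genes$weight, -1)
  up <- select_signature(de, "up")
  expect_equal(up$genes$gene, "b")
  # logFC = 0 excluded under either direction; directions are disjoint
  expect_false("d" %in% c(down$genes$gene, up$genes$gene))
  expect_equal(length(intersect(down$genes$gene, up$genes$gene)), 0)
  expect_warning(select_signature(de, "down", fdr_max = 1e-6), "no genes")
})

test_that("signature scores: bounds, antisymmetry, and a hand fixture", {
  set.seed(20)
  e <- matrix(rnorm(300), 3, 100,
              dimnames = list(c("a", "b", "c"), sprintf("s%03d", 1:100)))
  sig <- data.frame(gene = c("a", "b", "c"), weight = c(1, 1, 1))
  sc <- sig_score(e, sig)
  expect_true(all(sc >= -1 & sc <= 1))
  # a sample at or above every gene's upper quantile scores exactly 1
  e2 <- cbind(e, top = apply(e, 1, max) + 1)
  expect_equal(unname(sig_score(e2, sig)["top"]), 1)
  # negating the weights negates the scores
  sig_neg <- transform(sig, weight = -weight)
  expect_equal(sig_score(e, sig_neg), -sc)
  # gene order never matters; absent genes are dropped with a warning
  expect_equal(sig_score(e, sig[c(3, 1, 2), ]), sc)
  expect_warning(sc2 <- sig_score(e, rbind(sig,
    data.frame(gene = "zz", weight = 1))), "absent")
  expect_equal(sc2, sc)
  # hand-computed 3-gene fixture
  ef <- matrix(c(0, 5, 10,
                 10, 5, 0,
                 2, 2, 2), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  sigf <- data.frame(gene = c("a", "b"), weight = c(1, -1))
  q <- function(v) quantile(v, c(0.025, 0.975), names = FALSE)
  resc <- function(v) 2 * (pmin(pmax(v, q(v)[1]), q(v)[2]) - q(v)[1]) /
    diff(q(v)) - 1
  hand <- (resc(ef["a", ]) - resc(ef["b", ])) / 2
  expect_equal(sig_score(ef, sigf), hand)
  expect_error(suppressWarnings(
    sig_score(ef, data.frame(gene = "zz", weight = 1))), "usable")
})

test_that("hypergeometric enrichment matches the closed form", {
  u <- sprintf("g%02d", 1:10)
  out <- hypergeometric_enrichment(u[1:4], u[1:5], u)
  expect_equal(out$overlap, 4)
  expect_equal(out$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(out$p_value, hyper_oracle(4, 5, 10, 4), tolerance = 1e-12)
  # zero overlap and signature = universe both give p = 1
  expect_equal(hypergeometric_enrichment(u[6:9], u[1:5], u)$p_value,
               hyper_oracle(0, 5, 10, 4))
  expect_equal(hypergeometric_enrichment(u[6:9], u[1:5], u)$p_value, 1)
  expect_equal(hypergeometric_enrichment(u, u[1:5], u)$p_value, 1)
  expect_error(hypergeometric_enrichment(c("zz"), u[1:5], u), "subset")
  # random fixtures against the combinatorial oracle
  set.seed(24)
  for (i in 1:10) {
    reg <- sample(u, sample(2:8, 1))
    sig <- sample(u, sample(2:8, 1))
    out <- hypergeometric_enrichment(sig, reg, u)
    expect_equal(out$p_value,
                 hyper_oracle(out$overlap, length(reg), 10, length(sig)),
                 tolerance = 1e-12)
  }
})

test_that("signature overlap percentages round to the nearest integer", {
  out <- signature_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(out$shared, c("b", "c"))
  expect_equal(out$pct_of_a, 67)
  expect_equal(out$pct_of_b, 67)
  expect_equal(signature_overlap(c("a"), c("b"))$pct_of_a, 0)
  big <- signature_overlap(sprintf("x%02d", 1:63),
                           c(sprintf("x%02d", 1:27), sprintf("y%02d", 1:53)))
  expect_equal(length(big$shared), 27)
  expect_equal(big$pct_of_a, 43)
  expect_equal(big$pct_of_b, 34)
})

test_that("open-chromatin contrast flags genes and is calibrated", {
  gm <- data.frame(gene = sprintf("g%02d", 1:40), chromosome = "chrX",
                   tss = seq(10000, by = 100000, length.out = 40))
  # peak exactly covering one TSS with window 0 -> only that gene inside
  peaks1 <- data.frame(chromosome = "chrX", start = gm$tss[1] - 1,
                       end = gm$tss[1])
  gb0 <- matrix(runif(80), 40, 2, dimnames = list(gm$gene, c("s1", "s2")))
  expect_error(open_chromatin_contrast(gb0, gm$gene, gm, peaks1,
                                       window_bp = 0), "at least two")
  peaks2 <- rbind(peaks1, data.frame(chromosome = "chrX",
                                     start = gm$tss[2] - 1, end = gm$tss[2]))
  out0 <- open_chromatin_contrast(gb0, gm$gene, gm, peaks2, window_bp = 0)
  expect_equal(unname(which(out0$inside)), c(1, 2))
  # null calibration: identical beta distributions give uniform p
  set.seed(25)
  peaks <- data.frame(chromosome = "chrX", start = gm$tss[1:20] - 500,
                      end = gm$tss[1:20] + 500)
  ps <- replicate(200, {
    gb <- matrix(rbeta(40 * 4, 5, 5), 40, 4, dimnames = list(gm$gene, NULL))
    open_chromatin_contrast(gb, gm$gene, gm, peaks)$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  expect_gt(mean(ps), 0.35)
  # power: planted lower beta inside open chromatin
  set.seed(26)
  gb <- matrix(c(rnorm(20 * 4, 0.3, 0.05), rnorm(20 * 4, 0.5, 0.05)),
               40, 4, byrow = TRUE, dimnames = list(gm$gene, NULL))
  out <- open_chromatin_contrast(gb, gm$gene, gm, peaks)
  expect_lt(out$p_value, 0.01)
  expect_lt(out$mean_inside, out$mean_outside)
})
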