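#' Simulation configuration for a synthetic breast-tumour cohort
#'
#' Builds and validates the parameter set driving [generate_cohort()]. The
#' defaults plant the cohort structure the downstream analysis assumes: four
#' molecular subtypes with TP53 mutation rates increasing with aggressiveness,
#' large inactive-X (Xi) deletions and active-X (Xa) amplifications enriched in
#' TP53-mutant tumours, and high/low/unaltered X promoter-methylation groups
#' among copy-number-quiet tumours.
#'
#' @param n_samples number of tumour samples.
#' @param subtype_probs named probabilities of the molecular subtypes;
#'   must sum to 1.
#' @param p_tp53_mut_by_subtype named per-subtype probability of a somatic
#'   TP53 mutation.
#' @param p_xi_del_by_tp53 named vector `c(mut=, wt=)`: probability of a large
#'   Xi deletion given TP53 status.
#' @param p_xa_amp_by_tp53 named vector `c(mut=, wt=)`: probability of a large
#'   Xa amplification given TP53 status, among Xi-unaltered tumours.
#' @param p_meth_high,p_meth_low probabilities of the high / low X promoter
#'   methylation groups among tumours unaltered at both copy-number tiers.
#' @param n_bins number of abstract chrX bins.
#' @param bin_size_bp width of each bin in bp (1-based inclusive coordinates).
#' @param n_genes_x,n_genes_auto number of X-linked and autosomal genes.
#' @param n_mutations_per_sample Poisson mean of X-linked somatic mutations
#'   per sample.
#' @param rmaf_depth_mean mean RNA read depth at a mutation site.
#' @param signature_beta log-hazard per unit of the planted aggressiveness
#'   score in the survival model.
#' @param censor_rate probability that a sample's follow-up is censored.
#' @param seed integer seed; fully determines the cohort.
#' @param par_bins number of bins forming PAR1 (first bins) and PAR2 (last
#'   bins), the pseudoautosomal regions whose genes consistently escape XCI.
#' @param n_escape_nonpar number of non-PAR XCI-escapee genes.
#' @param beta_concentration Beta-distribution concentration for promoter
#'   beta-values (larger = tighter around the group mean).
#' @param dosage_scale multiplier on the log2 expressed-copy dosage effect
#'   (see Details).
#' @param expr_sd residual log2-expression standard deviation.
#' @param baseline_hazard exponential baseline hazard (per year).
#' @param survival_dist `"exponential"` or `"weibull"` baseline.
#' @param weibull_shape shape used when `survival_dist = "weibull"`.
#' @param focal_noise_rate per-bin probability of a focal one-bin copy-number
#'   blip in otherwise unaltered samples.
#' @param p_drop_terminal_bin probability that a sample's terminal bin has no
#'   segment coverage (emulating missing telomeric segments).
#' @param p_silent probability that a simulated mutation is annotated Silent.
#'
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 300,
                       subtype_probs = c(LumA = 0.54, LumB = 0.20,
                                         Basal = 0.18, Her2 = 0.08),
                       p_tp53_mut_by_subtype = c(LumA = 0.15, LumB = 0.30,
                                                 Basal = 0.80, Her2 = 0.50),
                       p_xi_del_by_tp53 = c(mut = 0.51, wt = 0.18),
                       p_xa_amp_by_tp53 = c(mut = 0.68, wt = 0.41),
                       p_meth_high = 0.19,
                       p_meth_low = 0.09,
                       n_bins = 100,
                       bin_size_bp = 1500000L,
                       n_genes_x = 100,
                       n_genes_auto = 40,
                       n_mutations_per_sample = 3,
                       rmaf_depth_mean = 30,
                       signature_beta = log(3),
                       censor_rate = 0.3,
                       seed = 1L,
                       par_bins = 2L,
                       n_escape_nonpar = 6L,
                       beta_concentration = 60,
                       dosage_scale = 1.0,
                       expr_sd = 0.5,
                       baseline_hazard = log(2) / 12,
                       survival_dist = c("exponential", "weibull"),
                       weibull_shape = 1.2,
                       focal_noise_rate = 0.02,
                       p_drop_terminal_bin = 0.1,
                       p_silent = 0.15) {
  cfg <- list(
    n_samples = n_samples, subtype_probs = subtype_probs,
    p_tp53_mut_by_subtype = p_tp53_mut_by_subtype,
    p_xi_del_by_tp53 = p_xi_del_by_tp53,
    p_xa_amp_by_tp53 = p_xa_amp_by_tp53,
    p_meth_high = p_meth_high, p_meth_low = p_meth_low,
    n_bins = n_bins, bin_size_bp = bin_size_bp,
    n_genes_x = n_genes_x, n_genes_auto = n_genes_auto,
    n_mutations_per_sample = n_mutations_per_sample,
    rmaf_depth_mean = rmaf_depth_mean,
    signature_beta = signature_beta, censor_rate = censor_rate,
    seed = seed, par_bins = par_bins, n_escape_nonpar = n_escape_nonpar,
    beta_concentration = beta_concentration,
    dosage_scale = dosage_scale,
    expr_sd = expr_sd, baseline_hazard = baseline_hazard,
    survival_dist = match.arg(survival_dist),
    weibull_shape = weibull_shape,
    focal_noise_rate = focal_noise_rate,
    p_drop_terminal_bin = p_drop_terminal_bin,
    p_silent = p_silent)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_samples) || length(cfg$n_samples) != 1 ||
      cfg$n_samples < 0 || cfg$n_samples != round(cfg$n_samples))
    stop_config("n_samples", "must be a single non-negative integer")
  if (is.null(names(cfg$subtype_probs)) || anyNA(cfg$subtype_probs) ||
      abs(sum(cfg$subtype_probs) - 1) > 1e-9)
    stop_config("subtype_probs", "must be named and sum to 1")
  check_prob(cfg$subtype_probs, "subtype_probs")
  if (!all(names(cfg$subtype_probs) %in% names(cfg$p_tp53_mut_by_subtype)))
    stop_config("p_tp53_mut_by_subtype", "must name every subtype")
  check_prob(cfg$p_tp53_mut_by_subtype, "p_tp53_mut_by_subtype")
  for (f in c("p_xi_del_by_tp53", "p_xa_amp_by_tp53")) {
    if (!all(c("mut", "wt") %in% names(cfg[[f]])))
      stop_config(f, "must have entries named 'mut' and 'wt'")
    check_prob(cfg[[f]], f)
  }
  check_prob(cfg$p_meth_high, "p_meth_high")
  check_prob(cfg$p_meth_low, "p_meth_low")
  if (cfg$p_meth_high + cfg$p_meth_low > 1)
    stop_config("p_meth_high", "p_meth_high + p_meth_low must not exceed 1")
  for (f in c("n_bins", "bin_size_bp", "n_genes_x", "n_genes_auto"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop_config(f, "must be a positive integer")
  if (cfg$n_mutations_per_sample < 0)
    stop_config("n_mutations_per_sample", "must be non-negative")
  if (cfg$rmaf_depth_mean <= 0)
    stop_config("rmaf_depth_mean", "must be positive")
  check_prob(cfg$censor_rate, "censor_rate")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    stop_config("seed", "must be a single integer")
  if (2L * cfg$par_bins >= cfg$n_bins)
    stop_config("par_bins", "PAR1 + PAR2 must leave non-PAR bins")
  invisible(cfg)
}

# Group-mean promoter beta for an X gene given sample state.
# XCI-subject genes sit near 0.45 (one methylated allele of two), shifted to
# 0.80 in hypermethylated tumours, 0.15 in hypomethylated tumours, 0.25 when
# the methylated Xi copy is deleted. Escapee promoters sit near 0.10 when in
# open chromatin, 0.25 otherwise, rising to 0.45 when hypermethylation
# silences the Xi copy.
.beta_mean <- function(escapee, open, xi_del, meth_group) {
  if (escapee) {
    if (meth_group == "high") return(0.45)
    return(if (open) 0.08 else 0.25)
  }
  if (xi_del) return(0.25)
  switch(meth_group, high = 0.80, low = 0.15, 0.45)
}

#' Generate a synthetic multi-omics cohort
#'
#' Draws a cohort with planted ground truth: allele-specific copy-number
#' segments over abstract chrX bins, a promoter-methylation probe matrix,
#' X-linked somatic mutations with RNA allele counts, a log2 expression
#' matrix, and clinical survival records. The planted per-sample group labels
#' (Xi-large-deletion / Xa-large-amplification / methylation high-low) and
#' per-mutation true expression fractions are retained in `$truth` so that
#' recovery by the analysis cascade can be measured.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_cohort` list with elements `segments`, `methylation`
#'   (`probes` data.frame + `beta` matrix), `mutations`, `expression`,
#'   `clinical`, `genes`, `peaks`, `truth`, and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  chr_len <- cfg$n_bins * cfg$bin_size_bp

  ## ---- gene models -------------------------------------------------------
  gx <- sprintf("XG%03d", seq_len(cfg$n_genes_x))
  tss_x <- round((seq_len(cfg$n_genes_x) - 0.5) * chr_len / cfg$n_genes_x)
  gene_bin <- pmin(cfg$n_bins, (tss_x - 1) %/% cfg$bin_size_bp + 1)
  par1 <- gene_bin <= cfg$par_bins
  par2 <- gene_bin > cfg$n_bins - cfg$par_bins
  nonpar_idx <- which(!par1 & !par2)
  escape_extra <- sort(sample(nonpar_idx, min(cfg$n_escape_nonpar, length(nonpar_idx))))
  escapee <- par1 | par2
  escapee[escape_extra] <- TRUE
  # XIST: the XCI master regulator, placed mid-chromosome, XCI-subject.
  xist_idx <- which(!escapee)[ceiling(sum(!escapee) / 2)]
  gx[xist_idx] <- "XIST"
  # constitutive escapees sit in open chromatin (low promoter methylation);
  # the rest escape variably from closed chromatin
  open_chrom <- escapee & runif(cfg$n_genes_x) < 0.6
  if (any(escapee) && !any(open_chrom)) open_chrom[which(escapee)[1]] <- TRUE
  if (all(open_chrom[escapee])) open_chrom[rev(which(escapee))[1]] <- FALSE
  xcu_idx <- sort(sample(nonpar_idx, min(12, length(nonpar_idx))))
  sting_idx <- sort(sample(seq_len(cfg$n_genes_x), min(15, cfg$n_genes_x)))
  ts_idx <- sort(sample(seq_len(cfg$n_genes_x), min(8, cfg$n_genes_x)))
  tags <- vapply(seq_len(cfg$n_genes_x), function(i) {
    t <- c(if (par1[i]) "PAR1", if (par2[i]) "PAR2",
           if (i %in% xcu_idx) "XCU", if (i %in% sting_idx) "p53-STING",
           if (i %in% ts_idx) "COSMIC-TS")
    paste(t, collapse = ",")
  }, character(1))
  genes_x <- data.frame(
    gene = gx, chromosome = "chrX", tss = tss_x,
    strand = sample(c("+", "-"), cfg$n_genes_x, replace = TRUE),
    region_tags = tags, escapee = escapee, open_chrom = open_chrom,
    bin = gene_bin, stringsAsFactors = FALSE)
  ga <- c("TP53", sprintf("AG%03d", seq_len(cfg$n_genes_auto - 1)))
  genes_auto <- data.frame(
    gene = ga, chromosome = c("chr17", rep("chr1", cfg$n_genes_auto - 1)),
    tss = c(7676592L, round(seq_len(cfg$n_genes_auto - 1) * 2e6)),
    strand = sample(c("+", "-"), cfg$n_genes_auto, replace = TRUE),
    region_tags = "", escapee = FALSE, open_chrom = FALSE,
    bin = NA_integer_, stringsAsFactors = FALSE)
  genes <- rbind(genes_x, genes_auto)
  rownames(genes) <- genes$gene

  ## ---- clinical truth ----------------------------------------------------
  subtype <- if (n) sample(names(cfg$subtype_probs), n, TRUE, cfg$subtype_probs) else character(0)
  tp53 <- ifelse(runif(n) < cfg$p_tp53_mut_by_subtype[subtype], "mut", "wt")
  xi_del <- runif(n) < cfg$p_xi_del_by_tp53[tp53]
  xa_amp <- !xi_del & runif(n) < cfg$p_xa_amp_by_tp53[tp53]
  meth_group <- rep("not-applicable", n)
  quiet <- !xi_del & !xa_amp
  u <- runif(n)
  meth_group[quiet] <- ifelse(u[quiet] < cfg$p_meth_high, "high",
                       ifelse(u[quiet] < cfg$p_meth_high + cfg$p_meth_low,
                              "low", "unaltered"))

  ## ---- copy-number bin vectors and segments ------------------------------
  minor_bins <- matrix(1, n, cfg$n_bins, dimnames = list(samples, NULL))
  major_bins <- matrix(1, n, cfg$n_bins, dimnames = list(samples, NULL))
  for (i in seq_len(n)) {
    # large events are terminal: the affected window is anchored at a
    # chromosome end (complete deletions/amplifications cover everything)
    terminal_window <- function() {
      f <- runif(1, 0.7, 1.0)
      w <- max(1L, round(f * cfg$n_bins))
      if (runif(1) < 0.5) seq_len(w) else (cfg$n_bins - w + 1L):cfg$n_bins
    }
    if (xi_del[i]) {
      minor_bins[i, terminal_window()] <- 0
    } else if (xa_amp[i]) {
      win <- terminal_window()
      major_bins[i, win] <- sample(2:3, length(win), replace = TRUE)
    } else {
      blips <- which(runif(cfg$n_bins) < cfg$focal_noise_rate)
      for (b in blips) {
        if (runif(1) < 0.5) minor_bins[i, b] <- 0 else major_bins[i, b] <- 2
      }
    }
  }

  seg_list <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- rep(TRUE, cfg$n_bins)
    if (cfg$n_bins > 2 && runif(1) < cfg$p_drop_terminal_bin)
      keep[if (runif(1) < 0.5) 1L else cfg$n_bins] <- FALSE
    key <- paste(major_bins[i, ], minor_bins[i, ], keep)
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    covered <- keep[starts]
    seg_list[[i]] <- data.frame(
      sample = samples[i], chromosome = "chrX",
      start = (starts[covered] - 1L) * cfg$bin_size_bp + 1L,
      end = ends[covered] * cfg$bin_size_bp,
      major_cn = major_bins[i, starts[covered]],
      minor_cn = minor_bins[i, starts[covered]],
      stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_list)
  if (is.null(segments))
    segments <- data.frame(sample = character(0), chromosome = character(0),
                           start = integer(0), end = integer(0),
                           major_cn = integer(0), minor_cn = integer(0))

  ## ---- methylation probes and beta matrix --------------------------------
  # Three probe layouts exercise the TSS-proximity rule: most genes have
  # near probes (<200 bp), some only far probes (200-1500 bp), a few none.
  nx <- cfg$n_genes_x
  layout <- rep("near", nx)
  if (nx >= 10) {
    layout[seq(5, nx, by = 10)] <- "far"
    layout[seq(10, nx, by = 20)] <- "none"
  }
  probe_rows <- list()
  for (i in seq_len(nx)) {
    off <- switch(layout[i], near = c(-150L, 40L, 120L), far = c(-900L, 700L),
                  none = integer(0))
    if (!length(off)) next
    probe_rows[[length(probe_rows) + 1L]] <- data.frame(
      probe = sprintf("cg%s_%d", genes_x$gene[i], seq_along(off)),
      chromosome = "chrX", position = genes_x$tss[i] + off,
      gene = genes_x$gene[i], stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, probe_rows)
  conc <- cfg$beta_concentration
  beta <- matrix(NA_real_, nrow(probes), n,
                 dimnames = list(probes$probe, samples))
  for (i in seq_len(n)) {
    mg <- meth_group[i]
    mu <- vapply(seq_len(nrow(probes)), function(p) {
      g <- probes$gene[p]
      .beta_mean(genes[g, "escapee"], genes[g, "open_chrom"], xi_del[i], mg)
    }, numeric(1))
    beta[, i] <- rbeta(nrow(probes), mu * conc, (1 - mu) * conc)
  }

  ## ---- expression --------------------------------------------------------
  all_genes <- genes$gene
  base <- rnorm(length(all_genes), 8, 1.5)
  names(base) <- all_genes
  base["XIST"] <- 10
  expr <- matrix(rnorm(length(all_genes) * n, 0, cfg$expr_sd),
                 length(all_genes), n,
                 dimnames = list(all_genes, samples)) + base
  # Expressed-copy dosage model: a gene's output tracks its number of
  # transcriptionally active copies. XCI-subject genes express the major
  # (Xa) copies only, so Xi deletion leaves them unchanged while Xa
  # amplification raises them; escapees also express the minor (Xi) copy,
  # so Xi deletion halves their dose. Hypermethylation silences the escapee
  # Xi copy; hypomethylation reactivates XCI-subject Xi copies.
  for (i in seq_len(n)) {
    bx <- genes_x$bin
    maj <- major_bins[i, bx]
    min_ <- minor_bins[i, bx]
    esc <- genes_x$escapee
    xi_active <- ifelse(esc, meth_group[i] != "high", meth_group[i] == "low")
    copies <- maj + ifelse(xi_active, min_, 0)
    baseline <- ifelse(esc, 2, 1)
    lfc <- cfg$dosage_scale * log2(pmax(copies, 0.5) / baseline)
    lfc[genes_x$gene == "XIST"] <- 0
    expr[genes_x$gene, i] <- expr[genes_x$gene, i] + lfc
    if (xi_del[i]) expr["XIST", i] <- expr["XIST", i] - 2
    if (tp53[i] == "mut") expr["XIST", i] <- expr["XIST", i] - 1
  }

  ## ---- somatic mutations with RNA allele counts --------------------------
  mut_rows <- list()
  for (i in seq_len(n)) {
    nm <- rpois(1, cfg$n_mutations_per_sample)
    if (nm > 0) {
      gi <- sample(seq_len(nx), nm, replace = TRUE)
      for (j in seq_len(nm)) {
        # Expressed (p=1) mutations are twice as frequent when Xi is deleted:
        # a hemizygous X leaves no silenced wild-type copy.
        probs <- if (xi_del[i]) c(0.5, 0.3, 0.2) else c(0.25, 0.3, 0.45)
        p_true <- sample(c(1, 0.5, 0), 1, prob = probs)
        depth <- rpois(1, cfg$rmaf_depth_mean)
        alt <- rbinom(1, depth, p_true)
        cls <- if (runif(1) < cfg$p_silent) "Silent"
               else sample(c("Missense_Mutation", "Nonsense_Mutation"), 1,
                           prob = c(0.85, 0.15))
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          sample = samples[i], gene = genes_x$gene[gi[j]],
          chromosome = "chrX", position = genes_x$tss[gi[j]] + 500L,
          classification = cls, ref_count = depth - alt, alt_count = alt,
          true_p = p_true, stringsAsFactors = FALSE)
      }
    }
    if (tp53[i] == "mut") {
      # TP53 LOH (RMAF near 1) accompanies large Xi deletions.
      p_true <- if (xi_del[i]) 1.0 else 0.5
      depth <- rpois(1, cfg$rmaf_depth_mean)
      alt <- rbinom(1, depth, p_true)
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        sample = samples[i], gene = "TP53", chromosome = "chr17",
        position = 7676592L, classification = "Missense_Mutation",
        ref_count = depth - alt, alt_count = alt, true_p = p_true,
        stringsAsFactors = FALSE)
    }
  }
  mutations <- do.call(rbind, mut_rows)
  if (is.null(mutations))
    mutations <- data.frame(sample = character(0), gene = character(0),
                            chromosome = character(0), position = integer(0),
                            classification = character(0),
                            ref_count = integer(0), alt_count = integer(0),
                            true_p = numeric(0))

  ## ---- survival ----------------------------------------------------------
  aggressiveness <- 1.0 * xi_del + 0.7 * xa_amp +
    0.4 * (meth_group == "high") + 0.4 * (meth_group == "low")
  hr <- exp(cfg$signature_beta * aggressiveness)
  time <- if (cfg$survival_dist == "weibull") {
    # inverse-CDF draw: S(t) = exp(-(h0*t)^shape * hr)
    u <- runif(n)
    (-log(u) / hr)^(1 / cfg$weibull_shape) / cfg$baseline_hazard
  } else {
    rexp(n, rate = cfg$baseline_hazard * hr)
  }
  event <- rep(1L, n)
  cens <- runif(n) < cfg$censor_rate
  time[cens] <- runif(sum(cens), 0, time[cens])
  event[cens] <- 0L
  clinical <- data.frame(sample = samples, subtype = subtype,
                         tp53_status = tp53, time = round(time, 4),
                         event = event, stringsAsFactors = FALSE)

  ## ---- ATAC peaks: open chromatin over constitutive-escapee promoters ----
  open_tss <- genes_x$tss[genes_x$open_chrom]
  extra <- sort(sample(setdiff(round(seq(1e6, chr_len - 1e6, length.out = 50)),
                               genes_x$tss), 8))
  peak_centers <- sort(c(open_tss, extra))
  peaks <- data.frame(chromosome = "chrX",
                      start = pmax(0L, peak_centers - 500L),  # BED 0-based
                      end = peak_centers + 500L,
                      name = sprintf("peak_%03d", seq_along(peak_centers)),
                      stringsAsFactors = FALSE)

  truth <- data.frame(
    sample = samples,
    xi_truth = ifelse(xi_del, "Xi-large-deletion", "Xi-unaltered"),
    xa_truth = ifelse(xi_del, "not-applicable",
                      ifelse(xa_amp, "Xa-large-amplification", "Xa-unaltered")),
    meth_truth = meth_group, aggressiveness = aggressiveness,
    stringsAsFactors = FALSE)

  structure(list(
    segments = segments,
    methylation = list(probes = probes[, c("probe", "chromosome", "position")],
                       beta = beta),
    mutations = mutations, expression = expr, clinical = clinical,
    genes = genes[, c("gene", "chromosome", "tss", "strand", "region_tags")],
    peaks = peaks, truth = truth, config = cfg), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d segments, %d probes, %d mutations, %d genes\n",
              nrow(x$clinical), nrow(x$segments), nrow(x$methylation$probes),
              nrow(x$mutations), nrow(x$genes)))
  invisible(x)
}
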