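# End-to-end orchestration: simulate a cohort to disk, run the full
# aberration analysis on a cohort directory, and render a markdown report.
# These functions back the thin command-line script shipped in inst/cli.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Simulate a synthetic cohort to disk
#'
#' @param config a [sim_config()] (or a list of its arguments).
#' @param out_dir output directory (created if missing).
#' @param seed optional override of `config$seed`.
#' @return invisibly, the file manifest from [write_cohort()].
#' @export
cmd_simulate <- function(config = sim_config(), out_dir, seed = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.null(seed)) { config$seed <- seed; validate_sim_config(config) }
  cohort <- stage("simulate", generate_cohort(config))
  manifest <- stage("write", write_cohort(cohort, out_dir))
  message(sprintf("wrote %d files to %s", nrow(manifest), out_dir))
  invisible(manifest)
}

#' Run the full X-aberration analysis on a cohort directory
#'
#' Executes the pipeline: promoter methylation aggregation, the
#' Xi-deletion / Xa-amplification / methylation clustering cascade, RMAF
#' classification, four differential-expression signatures
#' (Xi-deletion down, Xa-amplification up, high-methylation down,
#' low-methylation up) against the selected unaltered tumours, per-sample
#' signature scores, Kaplan-Meier / Cox survival evaluation, region
#' enrichment, signature overlap, and the open-chromatin methylation
#' contrast. When the cohort carries planted truth labels, per-tier
#' adjusted Rand indices are added to the run manifest.
#'
#' @param input_dir cohort directory from [cmd_simulate()] (or equivalent
#'   real-data exports in the same formats).
#' @param out_dir results directory.
#' @param bin_size_bp chrX bin width for copy-number projection.
#' @param fdr_max signature FDR threshold.
#' @param min_coverage RMAF coverage floor.
#' @param near_bp,far_bp probe-to-TSS windows.
#' @param horizon_years survival horizon.
#' @param k_cn,k_meth cluster counts for the copy-number and methylation
#'   tiers.
#' @return invisibly, the full results list.
#' @export
cmd_run <- function(input_dir, out_dir, bin_size_bp = 1500000, fdr_max = 0.05,
                    min_coverage = 8, near_bp = 200, far_bp = 1500,
                    horizon_years = 20, k_cn = 2, k_meth = 3) {
  cohort <- stage("read", read_cohort(input_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  clinical <- cohort$clinical
  genes <- cohort$genes
  x_genes <- genes$gene[genes$chromosome == "chrX"]

  ## promoter methylation
  res <- list()
  res$gene_beta <- stage("methylation", {
    mapping <- assign_probes_to_genes(
      cohort$methylation$probes, genes[genes$chromosome == "chrX", ],
      near_bp, far_bp)
    gene_promoter_beta(cohort$methylation$beta, mapping)
  })
  res$mean_x_beta <- stage("methylation",
    mean_x_promoter_methylation(res$gene_beta, genes))

  ## clustering cascade
  max_end <- max(cohort$segments$end)
  bins <- make_bins(ceiling(max_end / bin_size_bp), bin_size_bp)
  res$assignments <- stage("cascade",
    run_cascade(cohort$segments, res$gene_beta, bins, k_cn, k_meth))
  asg <- res$assignments
  xi <- setNames(asg$xi_group, asg$sample)

  ## RMAF classification
  res$mutations <- stage("rmaf",
    annotate_rmaf(cohort$mutations, min_coverage))
  res$expression_classes <- stage("rmaf", tryCatch(
    expression_class_table(
      res$mutations[res$mutations$chromosome == "chrX", ], xi),
    error = function(e) NULL))
  res$tp53_rmaf <- stage("rmaf", tryCatch(
    sample_level_rmaf(res$mutations, "TP53"), error = function(e) NULL))

  ## differential expression and signatures
  expr_x <- cohort$expression[rownames(cohort$expression) %in% x_genes, ,
                              drop = FALSE]
  subtype <- setNames(clinical$subtype, clinical$sample)
  sel <- asg$sample[asg$selected_unaltered]
  contrasts <- list(
    xi_deletion = list(grp = asg$sample[asg$xi_group == "Xi-large-deletion"],
                       direction = "down"),
    xa_amplification = list(
      grp = asg$sample[asg$xa_group == "Xa-large-amplification"],
      direction = "up"),
    high_methylation = list(
      grp = asg$sample[asg$methylation_group == "high"], direction = "down",
      ref = asg$sample[asg$methylation_group == "unaltered"]),
    low_methylation = list(
      grp = asg$sample[asg$methylation_group == "low"], direction = "up",
      ref = asg$sample[asg$methylation_group == "unaltered"]))

  res$de <- list(); res$signatures <- list(); res$survival <- list()
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    ref <- ct$ref %||% sel
    use <- c(ref, ct$grp)
    if (length(ct$grp) < 2 || length(ref) < 2) next
    de <- stage(paste0("de_", nm), de_analysis(
      expr_x[, use, drop = FALSE],
      use %in% ct$grp, subtype[use]))
    res$de[[nm]] <- de
    sig <- stage(paste0("signature_", nm), suppressWarnings(
      select_signature(de, ct$direction, fdr_max, name = nm)))
    res$signatures[[nm]] <- sig
    if (nrow(sig$genes)) {
      sc <- stage(paste0("score_", nm), sig_score(cohort$expression, sig))
      res$scores[[nm]] <- sc
      surv <- clinical[match(names(sc), clinical$sample), ]
      res$survival[[nm]] <- stage(paste0("survival_", nm), {
        cox <- cox_hr(surv$time, surv$event, sc, horizon_years)
        split <- median_split(sc)
        km <- km_logrank(surv$time, surv$event, split, horizon_years)
        list(cox = cox, logrank_statistic = km$statistic,
             logrank_p = km$p_value,
             group_sizes = as.list(table(split)))
      })
    }
  }

  ## region enrichment and signature overlap
  tag_set <- function(tag) {
    genes$gene[genes$chromosome == "chrX" &
               grepl(tag, genes$region_tags, fixed = TRUE)]
  }
  res$enrichment <- stage("enrichment", {
    out <- list()
    universe <- rownames(expr_x)
    for (nm in names(res$signatures)) {
      sg <- intersect(res$signatures[[nm]]$genes$gene, universe)
      if (!length(sg)) next
      for (tag in c("PAR1", "PAR2")) {
        rg <- intersect(tag_set(tag), universe)
        if (length(rg))
          out[[paste(nm, tag, sep = "_")]] <-
            hypergeometric_enrichment(sg, rg, universe)
      }
    }
    out
  })
  res$overlaps <- stage("overlap", {
    ov <- list()
    pair <- function(a, b) {
      if (!is.null(res$signatures[[a]]) && !is.null(res$signatures[[b]]))
        signature_overlap(res$signatures[[a]]$genes$gene,
                          res$signatures[[b]]$genes$gene)
    }
    ov$xi_deletion_vs_high_methylation <-
      pair("xi_deletion", "high_methylation")
    ov$xa_amplification_vs_low_methylation <-
      pair("xa_amplification", "low_methylation")
    ov
  })

  ## open chromatin contrast on selected tumours
  res$open_chromatin <- stage("open_chromatin", {
    out <- list()
    gb_sel <- res$gene_beta[, intersect(sel, colnames(res$gene_beta)),
                            drop = FALSE]
    for (nm in c("xi_deletion", "xa_amplification")) {
      sg <- res$signatures[[nm]]
      if (is.null(sg)) next
      g <- intersect(sg$genes$gene, rownames(gb_sel))
      out[[nm]] <- tryCatch(
        open_chromatin_contrast(gb_sel, g, genes, cohort$peaks),
        error = function(e) list(error = conditionMessage(e)))
    }
    out
  })

  ## cohort-level statistics
  res$stats <- stage("stats", {
    st <- list()
    safe_rank <- function(values, labels, kind) {
      labels <- droplevels(as.factor(labels))
      need <- if (kind == "wilcoxon") 2 else 2
      if (nlevels(labels) < need ||
          (kind == "wilcoxon" && nlevels(labels) != 2)) return(NULL)
      rank_tests(values, labels, kind)
    }
    cl <- clinical[match(asg$sample, clinical$sample), ]
    xi_del <- asg$xi_group == "Xi-large-deletion"
    st$xi_by_subtype <- crosstab_percent(
      tapply(xi_del, cl$subtype, sum), table(cl$subtype))
    st$xi_by_tp53 <- crosstab_percent(
      tapply(xi_del, cl$tp53_status, sum), table(cl$tp53_status))
    in2 <- asg$xa_group != "not-applicable"
    if (any(in2)) {
      xa_amp <- asg$xa_group[in2] == "Xa-large-amplification"
      st$xa_by_subtype <- crosstab_percent(
        tapply(xa_amp, cl$subtype[in2], sum), table(cl$subtype[in2]))
      st$xa_by_tp53 <- crosstab_percent(
        tapply(xa_amp, cl$tp53_status[in2], sum), table(cl$tp53_status[in2]))
    }
    mx <- res$mean_x_beta[asg$sample]
    st$meanx_by_subtype_kw <- safe_rank(mx, cl$subtype, "kruskal_wallis")
    st$meanx_by_tp53_wilcoxon <- safe_rank(mx, cl$tp53_status, "wilcoxon")
    st$meanx_by_xi_wilcoxon <- safe_rank(mx, asg$xi_group, "wilcoxon")
    if ("XIST" %in% rownames(cohort$expression)) {
      xist <- cohort$expression["XIST", asg$sample]
      st$xist_by_tp53_wilcoxon <- safe_rank(xist, cl$tp53_status, "wilcoxon")
      st$xist_by_xi_wilcoxon <- safe_rank(xist, asg$xi_group, "wilcoxon")
    }
    if (!is.null(res$tp53_rmaf)) {
      common <- intersect(names(res$tp53_rmaf), asg$sample)
      gl <- xi[common]
      if (length(unique(gl)) == 2)
        st$tp53_rmaf_by_xi_wilcoxon <-
          rank_tests(res$tp53_rmaf[common], gl, "wilcoxon")
    }
    t3 <- asg$methylation_group != "not-applicable"
    if (length(unique(asg$methylation_group[t3])) >= 2)
      st$meanx_by_meth_group_kw <- safe_rank(
        res$mean_x_beta[asg$sample[t3]], asg$methylation_group[t3],
        "kruskal_wallis")
    st
  })

  ## truth recovery, if available
  if (!is.null(cohort$truth) && nrow(cohort$truth)) {
    tr <- cohort$truth[match(asg$sample, cohort$truth$sample), ]
    res$ari <- list(
      xi = mclust::adjustedRandIndex(asg$xi_group, tr$xi_truth))
    t2 <- asg$xa_group != "not-applicable"
    if (any(t2))
      res$ari$xa <- mclust::adjustedRandIndex(asg$xa_group[t2],
                                              tr$xa_truth[t2])
    t3 <- asg$methylation_group != "not-applicable"
    if (any(t3))
      res$ari$methylation <- mclust::adjustedRandIndex(
        asg$methylation_group[t3], tr$meth_truth[t3])
  }

  ## persist results
  stage("write", {
    write_tsv(res$assignments, file.path(out_dir, "assignments.tsv"))
    write_matrix_tsv(res$gene_beta, file.path(out_dir, "gene_beta.tsv"),
                     "gene")
    write_tsv(res$mutations, file.path(out_dir, "mutations_rmaf.tsv"))
    for (nm in names(res$de))
      write_tsv(res$de[[nm]], file.path(out_dir, sprintf("de_%s.tsv", nm)))
    for (nm in names(res$signatures)) {
      s <- res$signatures[[nm]]
      jsonlite::write_json(
        list(name = s$name, genes = s$genes, provenance = s$provenance),
        file.path(out_dir, sprintf("signature_%s.json", nm)),
        auto_unbox = TRUE, digits = NA)
    }
    if (length(res$scores)) {
      sc <- do.call(cbind, res$scores)
      write_tsv(data.frame(sample = rownames(sc), sc, check.names = FALSE),
                file.path(out_dir, "scores.tsv"))
    }
    jsonlite::write_json(
      res$survival,
      file.path(out_dir, "survival.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    # named atomic vectors must become objects, not bare arrays, in JSON
    as_json_friendly <- function(x) {
      if (is.list(x)) lapply(x, as_json_friendly)
      else if (is.atomic(x) && !is.null(names(x))) as.list(x)
      else x
    }
    jsonlite::write_json(
      as_json_friendly(
        list(stats = res$stats, enrichment = res$enrichment,
             overlaps = res$overlaps,
             open_chromatin = lapply(res$open_chromatin, function(x) {
               x$inside <- NULL; x }))),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    manifest <- list(
      n_samples = nrow(clinical),
      tier1_n = nrow(asg),
      tier1_sizes = as.list(table(asg$xi_group)),
      tier2_n = sum(asg$xa_group != "not-applicable"),
      tier2_sizes = as.list(table(
        asg$xa_group[asg$xa_group != "not-applicable"])),
      tier3_n = sum(asg$methylation_group != "not-applicable"),
      tier3_sizes = as.list(table(
        asg$methylation_group[asg$methylation_group != "not-applicable"])),
      n_selected_unaltered = sum(asg$selected_unaltered),
      signature_sizes = lapply(res$signatures, function(s) nrow(s$genes)),
      ari = res$ari,
      parameters = list(bin_size_bp = bin_size_bp, fdr_max = fdr_max,
                        min_coverage = min_coverage, near_bp = near_bp,
                        far_bp = far_bp, horizon_years = horizon_years,
                        k_cn = k_cn, k_meth = k_meth))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  })
  invisible(res)
}

#' Render a markdown summary of a results directory
#'
#' @param results_dir directory written by [cmd_run()].
#' @param out_file output markdown path (default `report.md` inside
#'   `results_dir`).
#' @return invisibly, the lines written.
#' @export
cmd_report <- function(results_dir, out_file = file.path(results_dir,
                                                         "report.md")) {
  need <- c("run_manifest.json", "assignments.tsv", "stats.json",
            "survival.json")
  missing <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing))
    stop(sprintf("results directory incomplete; missing: %s",
                 paste(missing, collapse = ", ")))
  man <- jsonlite::read_json(file.path(results_dir, "run_manifest.json"))
  stats <- jsonlite::read_json(file.path(results_dir, "stats.json"))
  surv <- jsonlite::read_json(file.path(results_dir, "survival.json"))

  fmt_sizes <- function(x)
    paste(sprintf("%s = %s", names(x), unlist(x)), collapse = ", ")
  lines <- c(
    "# X-chromosome aberration analysis report", "",
    sprintf("Samples: %s", man$n_samples), "",
    "## Clustering cascade",
    sprintf("- Tier 1 (Xi, n = %s): %s", man$tier1_n,
            fmt_sizes(man$tier1_sizes)),
    sprintf("- Tier 2 (Xa, n = %s): %s", man$tier2_n,
            fmt_sizes(man$tier2_sizes)),
    sprintf("- Tier 3 (methylation, n = %s): %s", man$tier3_n,
            fmt_sizes(man$tier3_sizes)),
    sprintf("- Selected unaltered tumours: %s", man$n_selected_unaltered))
  if (!is.null(man$ari))
    lines <- c(lines, sprintf("- Truth recovery ARI: %s",
      paste(sprintf("%s = %.3f", names(man$ari), unlist(man$ari)),
            collapse = ", ")))
  lines <- c(lines, "", "## Cross-tabulations (percent aberrant)")
  for (nm in intersect(c("xi_by_subtype", "xi_by_tp53", "xa_by_subtype",
                         "xa_by_tp53"), names(stats$stats))) {
    ct <- stats$stats[[nm]]
    lines <- c(lines, sprintf("- %s: %s (chi-square p = %.3g)", nm,
                              fmt_sizes(ct$percent),
                              as.numeric(ct$p_value %||% NA)))
  }
  lines <- c(lines, "", "## Signatures")
  for (nm in names(man$signature_sizes))
    lines <- c(lines, sprintf("- %s: %s genes", nm,
                              man$signature_sizes[[nm]]))
  if (length(stats$overlaps)) {
    lines <- c(lines, "", "## Signature overlap")
    for (nm in names(stats$overlaps)) {
      ov <- stats$overlaps[[nm]]
      if (is.null(ov)) next
      lines <- c(lines, sprintf("- %s: %d shared (%s%% / %s%%)", nm,
                                length(ov$shared), ov$pct_of_a, ov$pct_of_b))
    }
  }
  if (length(surv)) {
    lines <- c(lines, "", "## Survival")
    for (nm in names(surv)) {
      s <- surv[[nm]]
      lines <- c(lines, sprintf(
        "- %s: HR(score) = %.2f [%.2f, %.2f], p = %.3g; HR(median split) = %.2f; log-rank p = %.3g",
        nm, s$cox$continuous$hr, s$cox$continuous$ci_lower,
        s$cox$continuous$ci_upper, s$cox$continuous$p_value,
        s$cox$median_split$hr, s$logrank_p))
    }
  }
  writeLines(lines, out_file)
  invisible(lines)
}
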