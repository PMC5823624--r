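# End-to-end orchestration: simulate (or load) -> CNA anchors/regions ->
# gene meta-analysis -> paradox classification + validation -> miRNA
# meta-analysis -> target overlap, pair correlations, CMC -> summary report.

#' Pipeline configuration
#'
#' Bundles the study-level settings: the synthetic-cohort configuration, the
#' significance levels of each stage (genes 0.01, miRNAs 0.05, pairs 0.05,
#' randomization validation 1e-4), the permutation/randomization sizes and the
#' master seed from which every stage seed is derived.
#'
#' @param sim a [simulation_config()]; the pipeline overrides its seed with a
#'   sub-seed derived from `seed` so that one master seed drives the run.
#' @param gene_alpha,mirna_alpha,pair_alpha,anchor_alpha stage significance
#'   levels.
#' @param thresholds an [analysis_thresholds()] (z 1.647, log2 CNA 0.2,
#'   validation 1e-4).
#' @param n_perm anchor permutations; `n_rand` validation randomizations;
#'   `n_null` random pairs for the empirical correlation null.
#' @param max_gap maximal inter-anchor gap inside one aberrant region, bases.
#' @param exclude_genes optional id list dropped before paradox
#'   classification (e.g. non-protein-coding genes).
#' @param out_dir optional directory for stage outputs.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            gene_alpha = 0.01, mirna_alpha = 0.05,
                            pair_alpha = 0.05, anchor_alpha = 0.05,
                            thresholds = analysis_thresholds(),
                            n_perm = 1e4, n_rand = 1e5, n_null = 1e4,
                            max_gap = 5e6, exclude_genes = NULL,
                            out_dir = NULL, seed = 1L) {
  for (a in c(gene_alpha, mirna_alpha, pair_alpha, anchor_alpha))
    stopifnot(a > 0, a < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim` and
#' `thresholds` keys take the arguments of [simulation_config()] and
#' [analysis_thresholds()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("sim", "thresholds"))]
  if (!is.null(y$sim)) args$sim <- do.call(simulation_config, y$sim)
  if (!is.null(y$thresholds))
    args$thresholds <- do.call(analysis_thresholds, y$thresholds)
  do.call(pipeline_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full paradoxical-gene discovery pipeline
#'
#' Executes all stages on a synthetic cohort generated from
#' `config$sim` (or on a pre-built cohort passed via `cohort`): anchor
#' integration and the permutation frequency test, gene and miRNA rank
#' meta-analyses, gene-to-region assignment with the association chi-square,
#' paradox classification, sample-wise frequencies and randomization
#' validation, target-overlap enrichment, CNA-controlled pair correlations
#' with empirical significance and explanatory classification, and per-gene
#' multiple-correlation percentiles.  The first expression cohort doubles as
#' the matched validation cohort (expression + per-gene CNA + miRNA
#' expression over the same samples).
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort (as from [simulate_cohort()]);
#'   by default one is simulated from `config$sim`.
#' @return object of class `paradoxcna_pipeline`: a list with the per-stage
#'   results (`anchors`, `regions`, `gene_meta`, `chi_square`, `records`,
#'   `mirna_meta`, `overlap`, `pairs`, `cmc`), the `summary` report, the
#'   `seeds` audit and (for simulated cohorts) the planted `truth`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  seeds <- .derive_seeds(config$seed,
                         c("simulation", "anchors", "validation", "pairs"))
  if (is.null(cohort)) {
    cohort <- .stage("simulate", {
      sim <- config$sim
      sim$seed <- seeds[["simulation"]]
      simulate_cohort(sim)
    })
  }

  anchors <- .stage("cna_integration", {
    at <- build_anchor_table(cohort$cna)
    anchor_frequency_test(at, n_perm = config$n_perm,
                          seed = seeds[["anchors"]],
                          alpha = config$anchor_alpha)
  })
  regions <- .stage("cna_integration",
                    merge_significant_anchors(anchors, config$max_gap))

  gene_meta <- .stage("gene_meta", {
    studies <- lapply(cohort$cohorts, function(co) rank_differential(co$expr))
    aggregate_ranked_lists(studies, alpha = config$gene_alpha,
                           universe = "per_list")
  })

  paradox <- .stage("paradox", {
    sig <- gene_meta[gene_meta$significant, ]
    if (!is.null(config$exclude_genes))
      sig <- sig[!sig$id %in% config$exclude_genes, ]
    de_dir <- stats::setNames(sig$direction, sig$id)
    region_map <- assign_genes_to_regions(cohort$genes, regions)
    chi <- association_chi_square(de_dir, region_map)
    records <- identify_paradoxical(de_dir, region_map)

    vc <- cohort$cohorts[[1]]
    z <- zscore_expression(vc$expr)
    par_rec <- records[records$is_paradoxical, ]
    par_rec <- sample_paradox_frequencies(z, vc$gene_cna, par_rec,
                                          config$thresholds)
    par_rec <- validate_paradox_genes(z, vc$gene_cna, par_rec,
                                      config$thresholds,
                                      n_rand = config$n_rand,
                                      seed = seeds[["validation"]])
    list(chi = chi, records = records, paradoxical = par_rec,
         de_direction = de_dir, region_map = region_map)
  })

  mirna_meta <- .stage("mirna_meta",
    aggregate_ranked_lists(cohort$mirna_rankings,
                           alpha = config$mirna_alpha, universe = "union"))

  assoc <- .stage("mirna_assoc", {
    vc <- cohort$cohorts[[1]]
    tum_expr <- .em_tumors(vc$expr)
    tum_mirna <- .em_tumors(vc$mirna)
    dereg <- mirna_meta[mirna_meta$significant, ]
    mirna_dir <- stats::setNames(dereg$direction, dereg$id)
    validated <- paradox$paradoxical$gene[paradox$paradoxical$validated]

    population <- sort(unique(unlist(lapply(cohort$cohorts, function(co)
      rownames(co$expr$values)))))
    targeted <- unique(cohort$network$gene[cohort$network$mirna %in% names(mirna_dir)])
    overlap <- target_overlap_test(validated, targeted, population)

    tested_m <- intersect(names(mirna_dir), rownames(tum_mirna))
    tested_g <- intersect(validated, rownames(tum_expr))
    pairs <- expand.grid(mirna = tested_m, gene = tested_g,
                         stringsAsFactors = FALSE)
    if (nrow(pairs)) {
      pairs <- empirical_pair_test(pairs, tum_expr, tum_mirna, vc$gene_cna,
                                   n_null = config$n_null,
                                   seed = seeds[["pairs"]],
                                   alpha = config$pair_alpha)
      gd <- stats::setNames(paradox$paradoxical$de_direction,
                            paradox$paradoxical$gene)
      pairs$explanatory <- classify_explanatory(
        mirna_dir[pairs$mirna], gd[pairs$gene],
        pairs$r_partial, pairs$significant)
    }

    C_all <- gene_cmc(tum_expr, tum_mirna[tested_m, , drop = FALSE])
    cmc <- cmc_percentile(C_all[intersect(validated, names(C_all))], C_all)
    list(overlap = overlap, pairs = pairs, cmc = cmc, C_all = C_all,
         deregulated_mirnas = mirna_dir)
  })

  result <- structure(list(
    config = config, seeds = seeds, cohort = cohort, truth = cohort$truth,
    anchors = anchors, regions = regions, gene_meta = gene_meta,
    chi_square = paradox$chi, records = paradox$records,
    paradoxical = paradox$paradoxical, region_map = paradox$region_map,
    mirna_meta = mirna_meta, overlap = assoc$overlap, pairs = assoc$pairs,
    cmc = assoc$cmc, C_all = assoc$C_all,
    deregulated_mirnas = assoc$deregulated_mirnas),
    class = "paradoxcna_pipeline")
  result$summary <- summarize_pipeline(result)
  if (!is.null(config$out_dir)) .write_pipeline(result, config$out_dir)
  result
}

#' Summary report of a pipeline run
#'
#' Per-stage counts and the headline statistics, with the seed audit.
#'
#' @param x a `paradoxcna_pipeline` object.
#' @return a list of class `paradoxcna_summary`.
#' @export
summarize_pipeline <- function(x) {
  an <- x$anchors$anchors
  rec <- x$records
  par <- x$paradoxical
  quad <- table(factor(ifelse(rec$de_direction > 0, "up", "down"),
                       c("up", "down")),
                factor(ifelse(rec$region_direction > 0, "gain", "loss"),
                       c("gain", "loss")))
  pr <- x$pairs
  structure(list(
    n_anchors = nrow(an),
    n_significant_anchors = sum(an$sig_gain | an$sig_loss),
    n_regions = nrow(x$regions),
    n_de_genes = sum(x$gene_meta$significant),
    n_de_up = sum(x$gene_meta$significant & x$gene_meta$direction > 0),
    n_de_down = sum(x$gene_meta$significant & x$gene_meta$direction < 0),
    n_de_in_region = nrow(rec),
    quadrants = quad,
    n_paradoxical = sum(rec$is_paradoxical),
    n_validated = sum(par$validated),
    chi2 = x$chi_square$chi2, chi2_p = x$chi_square$p,
    n_deregulated_mirnas = length(x$deregulated_mirnas),
    n_mirna_up = sum(x$deregulated_mirnas > 0),
    n_mirna_down = sum(x$deregulated_mirnas < 0),
    overlap = x$overlap,
    n_pairs = nrow(pr),
    n_significant_pairs = if (nrow(pr)) sum(pr$significant) else 0L,
    n_explanatory_pairs = if (nrow(pr)) sum(pr$explanatory) else 0L,
    pct_explanatory = if (nrow(pr) && sum(pr$significant) > 0)
      .pct(sum(pr$explanatory), sum(pr$significant)) else NA_real_,
    n_cmc_top = x$cmc$n_top,
    cmc_enrichment_p = x$cmc$enrichment_p,
    seeds = x$seeds), class = "paradoxcna_summary")
}

#' @export
print.paradoxcna_summary <- function(x, ...) {
  cat("paradoxcna pipeline summary\n")
  cat(sprintf("  anchors: %d (%d significant), aberrant regions: %d\n",
              x$n_anchors, x$n_significant_anchors, x$n_regions))
  cat(sprintf("  DE genes: %d (%d up, %d down); in aberrant regions: %d\n",
              x$n_de_genes, x$n_de_up, x$n_de_down, x$n_de_in_region))
  cat(sprintf("  association chi-square = %.1f (p = %.3g)\n", x$chi2, x$chi2_p))
  cat(sprintf("  paradoxical genes: %d, validated: %d\n",
              x$n_paradoxical, x$n_validated))
  cat(sprintf("  deregulated miRNAs: %d (%d up, %d down)\n",
              x$n_deregulated_mirnas, x$n_mirna_up, x$n_mirna_down))
  cat(sprintf("  target overlap: %d/%d targeted (p = %.3g)\n",
              x$overlap$overlap, x$overlap$n_hits, x$overlap$p))
  cat(sprintf("  miRNA:gene pairs: %d tested, %d significant, %d explanatory (%.1f%%)\n",
              x$n_pairs, x$n_significant_pairs, x$n_explanatory_pairs,
              ifelse(is.na(x$pct_explanatory), 0, x$pct_explanatory)))
  cat(sprintf("  genes in CMC top 5%%: %d (enrichment p = %.3g)\n",
              x$n_cmc_top, x$cmc_enrichment_p))
  cat(sprintf("  seeds: %s\n",
              paste(sprintf("%s=%d", names(x$seeds), x$seeds), collapse = ", ")))
  invisible(x)
}

#' @export
print.paradoxcna_pipeline <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

# write stage outputs as TSV/BED under out_dir
.write_pipeline <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  an <- x$anchors$anchors
  .write_tsv(data.frame(an[, c("chrom", "pos")],
                        gain_freq = .fmt_num(an$gain_freq),
                        loss_freq = .fmt_num(an$loss_freq),
                        p_gain = .fmt_num(an$p_gain),
                        p_loss = .fmt_num(an$p_loss)), p("anchors.tsv"))
  if (nrow(x$regions))
    write_bed(transform(x$regions,
                        id = sprintf("region%d", seq_len(nrow(x$regions)))),
              p("regions.bed"))
  .write_tsv(x$gene_meta, p("genes_meta.tsv"))
  .write_tsv(x$mirna_meta, p("mirna_meta.tsv"))
  .write_tsv(x$paradoxical, p("paradox.tsv"))
  if (nrow(x$pairs)) .write_tsv(x$pairs, p("pairs.tsv"))
  .write_tsv(data.frame(gene = names(x$C_all), C = .fmt_num(unname(x$C_all))),
             p("cmc.tsv"))
  s <- x$summary
  txt <- utils::capture.output(print(s))
  writeLines(txt, p("summary.txt"))
  invisible(dir)
}

#' Compare a pipeline run with the planted truth
#'
#' Recovery metrics for simulated cohorts: sensitivity and precision of the
#' validated paradoxical gene set against the planted one, sensitivity of the
#' deregulated-miRNA meta-analysis (direction must match), and the fraction
#' of planted regulator edges among the tested pairs that were classified
#' explanatory (with the same fraction over tested non-edge pairs).
#'
#' @param x a `paradoxcna_pipeline` with a simulated cohort.
#' @return list with `paradox_sensitivity`, `paradox_precision`,
#'   `mirna_sensitivity`, `edge_explanatory_rate`, `nonedge_explanatory_rate`
#'   and the underlying counts.
#' @export
evaluate_recovery <- function(x) {
  truth <- x$truth
  if (is.null(truth)) stop("no planted truth attached to this run")
  planted <- truth$paradox_gene_ids
  validated <- x$paradoxical$gene[x$paradoxical$validated]
  tp <- intersect(validated, planted)

  md <- x$deregulated_mirnas
  tm <- truth$deregulated_mirnas
  mirna_tp <- sum(names(tm) %in% names(md) & md[names(tm)] == tm, na.rm = TRUE)

  pr <- x$pairs
  edge_rate <- nonedge_rate <- NA_real_
  n_edge <- n_nonedge <- 0L
  if (nrow(pr)) {
    key <- paste(pr$mirna, pr$gene)
    planted_key <- paste(truth$regulator_edges$mirna, truth$regulator_edges$gene)
    is_edge <- key %in% planted_key
    n_edge <- sum(is_edge); n_nonedge <- sum(!is_edge)
    if (n_edge) edge_rate <- mean(pr$explanatory[is_edge])
    if (n_nonedge) nonedge_rate <- mean(pr$explanatory[!is_edge])
  }
  list(paradox_sensitivity = length(tp) / length(planted),
       paradox_precision = if (length(validated))
         length(tp) / length(validated) else NA_real_,
       n_planted = length(planted), n_validated = length(validated),
       n_true_positive = length(tp),
       mirna_sensitivity = mirna_tp / length(tm),
       edge_explanatory_rate = edge_rate,
       nonedge_explanatory_rate = nonedge_rate,
       n_edge_pairs = n_edge, n_nonedge_pairs = n_nonedge)
}

# percentage formatting used in reports: one decimal, as printed
.pct <- function(num, den) round(100 * num / den, 1)
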