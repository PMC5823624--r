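# Synthetic multi-cohort generator with planted ground truth.
#
# The generator emulates the study design the pipeline is built for: several
# aCGH-style CNA call sets on distinct, jittered probe grids; several
# tumor/normal expression cohorts sharing one gene universe (with per-cohort
# dropout); ranked up/down miRNA lists from independent "studies"; and a
# miRNA-target network.  Tumor gene expression follows a log-scale linear
# model: baseline + dosage (alpha per copy-call unit) + miRNA repression +
# noise.  For planted paradoxical genes the repression has a programmed
# (clonal) mean component that overshoots the dosage effect *in the samples
# carrying the aberration* -- the tumor maintains the gene's expression
# program in defiance of its copy number, which is the sample-wise
# co-occurrence signal the downstream randomization test measures -- plus a
# tracking component that follows the regulator miRNA's per-sample expression
# fluctuations, which is what the partial-correlation stage measures.  See
# .paradox_strength() and the methods vignette.

#' Configuration of the synthetic cohort generator
#'
#' Defaults define the reference study conditions used by the package's
#' end-to-end evaluations: 2,000 genes on 5 chromosomes, 40 miRNAs (12
#' deregulated), 3 CNA call datasets and 4 expression cohorts of 60 tumors /
#' 15 normals each, 10 aberrant regions at 40% carrier frequency, and 60
#' planted paradoxical genes.
#'
#' @param n_genes,n_mirnas feature universe sizes.
#' @param n_deregulated_mirnas number of planted deregulated miRNAs (split
#'   half up-, half downregulated).
#' @param n_cna_datasets,n_expr_datasets number of CNA call sets / expression
#'   cohorts.
#' @param samples_per_dataset tumors per dataset; `normals_per_dataset`
#'   normals per expression cohort.
#' @param n_chromosomes,chrom_length genome layout (one size per chromosome).
#' @param aberrant_region_count,region_length planted aberrant regions
#'   (directions alternate gain/loss).
#' @param aberration_frequency per-region per-tumor carrier probability.
#' @param background_rate rate of sporadic background calls outside planted
#'   regions.
#' @param dosage_effect expression log-units per copy-call unit (alpha).
#' @param mirna_repression global scale of miRNA repressive coupling (beta).
#' @param noise_sd,mirna_noise_sd expression noise, log-units.
#' @param mirna_shift tumor log-fold shift of deregulated miRNAs.
#' @param n_paradox_genes planted paradoxical genes (must fit inside aberrant
#'   regions).
#' @param regulator_range min/max planted regulator miRNAs per paradox gene.
#' @param decoy_targets_per_mirna background targets per miRNA in the network.
#' @param decoy_coupling repressive coupling of background (non-planted)
#'   target edges, before scaling by `mirna_repression`.
#' @param gene_dropout fraction of genes missing per expression cohort.
#' @param n_mirna_studies,detection_rate,fp_mean ranked miRNA study lists:
#'   number of studies, probability a planted miRNA is reported per study, and
#'   mean number of false-positive entries per study.
#' @param probe_length,probe_jitter mean CNA probe length and fractional
#'   jitter of probe boundaries (each dataset gets its own grid).
#' @param gene_length length of simulated gene loci.
#' @param cna_log_means,cna_noise_sd log2-ratio class means for calls
#'   \{-1, 0, +1\} and the noise around them (used for the matched per-gene
#'   CNA matrix and for ratio-mode probe data).
#' @param seed master seed; all generator randomness derives from it.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, n_mirnas = 40L,
                              n_deregulated_mirnas = 12L,
                              n_cna_datasets = 3L, n_expr_datasets = 4L,
                              samples_per_dataset = 60L,
                              normals_per_dataset = 15L,
                              n_chromosomes = 5L, chrom_length = 1e8,
                              aberrant_region_count = 10L,
                              region_length = 1e7,
                              aberration_frequency = 0.4,
                              background_rate = 0.01,
                              dosage_effect = 0.5, mirna_repression = 1.0,
                              noise_sd = 0.5, mirna_noise_sd = 0.5,
                              mirna_shift = 1.5,
                              n_paradox_genes = 60L,
                              regulator_range = c(1L, 2L),
                              decoy_targets_per_mirna = 25L,
                              decoy_coupling = 0.1,
                              gene_dropout = 0.05,
                              n_mirna_studies = 9L, detection_rate = 0.8,
                              fp_mean = 2,
                              probe_length = 2e6, probe_jitter = 0.25,
                              gene_length = 2e4,
                              cna_log_means = c(-0.5, 0, 0.58),
                              cna_noise_sd = 0.1,
                              seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_genes", "n_mirnas", "n_cna_datasets", "n_expr_datasets",
              "samples_per_dataset", "normals_per_dataset", "n_chromosomes",
              "aberrant_region_count", "n_paradox_genes", "n_mirna_studies")
  for (nm in counts)
    if (cfg[[nm]] < 0 || cfg[[nm]] != floor(cfg[[nm]]))
      stop(sprintf("`%s` must be a non-negative count", nm))
  for (nm in c("aberration_frequency", "background_rate", "gene_dropout",
               "detection_rate"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("`%s` must be a fraction in [0, 1]", nm))
  if (cfg$noise_sd <= 0) stop("`noise_sd` must be positive")
  if (cfg$n_deregulated_mirnas > cfg$n_mirnas)
    stop("more deregulated miRNAs than miRNAs")
  if (cfg$samples_per_dataset < 1) stop("need at least one tumor sample")
  # genome capacity: regions are laid out in disjoint per-chromosome blocks
  per_chrom <- ceiling(cfg$aberrant_region_count / max(cfg$n_chromosomes, 1L))
  if (cfg$aberrant_region_count > 0 &&
      cfg$region_length > 0.8 * cfg$chrom_length / per_chrom)
    stop("configuration error: aberrant regions exceed genome capacity")
  structure(cfg, class = "simulation_config")
}

# sub-seeds: one per generator stage, so stages can be re-run independently
# and still agree on the shared genome/regulatory layout
.sim_seeds <- function(config) {
  .derive_seeds(config$seed,
                c("layout", "mirna", "cna", "expr", "rankings"))
}

# effective repression of planted paradox genes, derived from the config.
# The planted miRNA-mediated repression has two components:
#   * a programmed (clonal) mean shift: r0 in tumors not carrying the
#     aberration, r1 in carrier samples.  r1 overshoots the dosage effect by
#     4 noise SDs, so carrier samples are deregulated *against* their copy
#     number -- the sample-wise co-occurrence signal the randomization test
#     measures.  r0 is raised if needed so the cohort-mean inversion is at
#     least 2 noise SDs.
#   * per-edge tracking of the regulator miRNA's expression fluctuations with
#     coupling SD `track` (gene log-units), the per-sample covariance the
#     partial-correlation stage measures.
.paradox_strength <- function(config) {
  beta <- config$mirna_repression
  s <- config$noise_sd
  f <- config$aberration_frequency
  boost <- 4 * s * beta
  r0 <- max(0.5 * s * beta, 2 * s - f * boost)
  r1 <- config$dosage_effect + r0 + boost
  list(r0 = r0, r1 = r1, track = 0.9 * s * beta)
}

# genome layout: aberrant regions in disjoint blocks, genes placed uniformly,
# paradox genes sampled from genes inside regions.  Run under the layout seed.
.sim_genome <- function(config) {
  .with_seed(.sim_seeds(config)[["layout"]], {
    nr <- config$aberrant_region_count
    regions <- NULL
    if (nr > 0) {
      chrom_of <- ((seq_len(nr) - 1L) %% config$n_chromosomes) + 1L
      starts <- numeric(nr)
      for (ch in unique(chrom_of)) {
        idx <- which(chrom_of == ch)
        block <- config$chrom_length / length(idx)
        lo <- (seq_along(idx) - 1) * block + 0.05 * block
        hi <- seq_along(idx) * block - 0.05 * block - config$region_length
        starts[idx] <- floor(lo + runif(length(idx)) * pmax(hi - lo, 1))
      }
      regions <- data.frame(
        chrom = paste0("chr", chrom_of),
        start = starts, end = starts + config$region_length,
        direction = rep_len(c(1L, -1L), nr),
        frequency = config$aberration_frequency,
        stringsAsFactors = FALSE)
    }
    chrom <- paste0("chr", sample.int(config$n_chromosomes, config$n_genes,
                                      replace = TRUE))
    start <- floor(runif(config$n_genes) *
                     (config$chrom_length - config$gene_length))
    genes <- data.frame(
      chrom = chrom, start = start, end = start + config$gene_length,
      id = sprintf("G%04d", seq_len(config$n_genes)),
      stringsAsFactors = FALSE)
    genes$region <- NA_integer_
    if (!is.null(regions)) {
      for (r in seq_len(nrow(regions))) {
        hit <- genes$chrom == regions$chrom[r] &
          genes$start < regions$end[r] & genes$end > regions$start[r]
        genes$region[hit] <- r
      }
    }
    genes$region_direction <- ifelse(is.na(genes$region), 0L,
                                     regions$direction[genes$region])
    in_region <- which(!is.na(genes$region))
    if (config$n_paradox_genes > length(in_region))
      stop("n_paradox_genes exceeds the number of genes inside aberrant regions")
    paradox <- sort(sample(in_region, config$n_paradox_genes))
    genes$is_paradox <- seq_len(nrow(genes)) %in% paradox
    genes$mu <- rnorm(config$n_genes, mean = 7, sd = 1.5)
    list(regions = regions, genes = genes)
  })
}

#' Generate the planted regulatory truth (deregulated miRNAs and target edges)
#'
#' Draws the deregulated miRNA set, the planted regulator edges that make the
#' paradox genes paradoxical (each paradox gene gets 1-2 regulators deregulated
#' in the direction of its region, i.e. opposite to its expression change), and
#' background target edges, together with the target-network table consumed by
#' the association stage.
#'
#' @param config a [simulation_config()].
#' @return list with `mirna_ids`, `mu` (baselines), `deregulated` (named
#'   direction vector), `edges` (data.frame mirna/gene/coef/boost/planted) and
#'   `network` (mirna/gene/score table).
#' @export
simulate_regulatory_truth <- function(config) {
  layout <- .sim_genome(config)
  genes <- layout$genes
  strength <- .paradox_strength(config)
  .with_seed(.sim_seeds(config)[["mirna"]], {
    ids <- sprintf("mir-%02d", seq_len(config$n_mirnas))
    mu <- stats::setNames(rnorm(config$n_mirnas, 5, 1), ids)
    nd <- config$n_deregulated_mirnas
    dereg_ids <- sample(ids, nd)
    dirs <- rep_len(c(1L, -1L), nd)
    deregulated <- stats::setNames(dirs, dereg_ids)

    edges <- list()
    paradox <- genes[genes$is_paradox, ]
    for (i in seq_len(nrow(paradox))) {
      want_dir <- paradox$region_direction[i]  # repressor deregulated with region
      pool <- dereg_ids[deregulated[dereg_ids] == want_dir]
      k <- sample(seq(config$regulator_range[1], config$regulator_range[2]), 1)
      k <- min(k, length(pool))
      regs <- sample(pool, k)
      # tracking slope: coupling SD of `track` gene log-units per edge
      slope <- if (config$mirna_noise_sd > 0)
        strength$track / config$mirna_noise_sd else 0
      edges[[length(edges) + 1L]] <- data.frame(
        mirna = regs, gene = paradox$id[i],
        coef = slope, planted = TRUE, stringsAsFactors = FALSE)
    }
    # background targets: deregulated miRNAs also hit genes outside aberrant
    # regions (weak repression); neutral miRNAs hit arbitrary non-paradox genes
    outside <- genes$id[genes$region_direction == 0L]
    nonpar <- genes$id[!genes$is_paradox]
    for (m in ids) {
      pool <- if (m %in% dereg_ids) outside else nonpar
      k <- min(config$decoy_targets_per_mirna, length(pool))
      if (k > 0)
        edges[[length(edges) + 1L]] <- data.frame(
          mirna = m, gene = sample(pool, k),
          coef = config$decoy_coupling * config$mirna_repression,
          planted = FALSE, stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, edges)
    edges <- edges[!duplicated(edges[, c("mirna", "gene")]), ]
    rownames(edges) <- NULL
    network <- data.frame(mirna = edges$mirna, gene = edges$gene,
                          score = round(runif(nrow(edges), 0.34, 1), 3),
                          stringsAsFactors = FALSE)
    list(mirna_ids = ids, mu = mu, deregulated = deregulated,
         edges = edges, network = network)
  })
}

#' Simulate multi-cohort CNA call datasets with planted aberrant regions
#'
#' Each dataset receives its own jittered probe grid (so downstream anchor
#' integration is non-trivial) and tumor samples carry each planted region's
#' aberration independently with probability `aberration_frequency`; outside
#' planted regions calls are neutral apart from sporadic background events.
#'
#' @param config a [simulation_config()].
#' @return list with `datasets` (list of [probe_call_dataset()]), `regions`
#'   (planted-region table) and `genes` (gene coordinate table).
#' @export
simulate_cna_datasets <- function(config) {
  layout <- .sim_genome(config)
  regions <- layout$regions
  .with_seed(.sim_seeds(config)[["cna"]], {
    datasets <- vector("list", config$n_cna_datasets)
    for (d in seq_len(config$n_cna_datasets)) {
      probes <- .jittered_grid(config)
      S <- config$samples_per_dataset
      calls <- matrix(0, nrow(probes), S,
                      dimnames = list(NULL, sprintf("cna%d_s%02d", d, 1:S)))
      if (!is.null(regions)) {
        carrier <- matrix(runif(nrow(regions) * S) < config$aberration_frequency,
                          nrow(regions), S)
        for (r in seq_len(nrow(regions))) {
          rows <- which(probes$chrom == regions$chrom[r] &
                          probes$start < regions$end[r] &
                          probes$end > regions$start[r])
          if (length(rows) && any(carrier[r, ]))
            calls[rows, carrier[r, ]] <- regions$direction[r]
        }
      }
      if (config$background_rate > 0) {
        bg <- which(calls == 0 &
                      matrix(runif(length(calls)) < config$background_rate,
                             nrow(calls)))
        calls[bg] <- sample(c(-1, 1), length(bg), replace = TRUE)
      }
      datasets[[d]] <- probe_call_dataset(probes, calls)
    }
    list(datasets = datasets, regions = regions, genes = layout$genes)
  })
}

# one dataset's probe grid: contiguous tiling with jittered boundaries
.jittered_grid <- function(config) {
  out <- list()
  for (ch in seq_len(config$n_chromosomes)) {
    np <- max(2L, round(config$chrom_length / config$probe_length))
    cuts <- seq(0, config$chrom_length, length.out = np + 1)
    jit <- runif(np - 1, -config$probe_jitter, config$probe_jitter) *
      config$probe_length
    cuts[2:np] <- round(cuts[2:np] + jit)
    out[[ch]] <- data.frame(chrom = paste0("chr", ch),
                            start = cuts[-(np + 1)], end = cuts[-1],
                            stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, out)
  grid$id <- sprintf("p%04d", seq_len(nrow(grid)))
  grid
}

#' Convert a call dataset to noisy log2 ratios
#'
#' Ratio-mode companion of the generator: replaces each discrete call with a
#' draw around its class mean, for exercising [call_from_log_ratios()].
#'
#' @param dataset a [probe_call_dataset()].
#' @param means log2 class means for calls \{-1, 0, +1\}.
#' @param sd noise SD around the class means.
#' @param seed RNG seed.
#' @return list with `probes` and numeric `values` matrix.
#' @export
simulate_log_ratios <- function(dataset, means = c(-0.5, 0, 0.58), sd = 0.1,
                                seed = 1L) {
  .with_seed(seed, {
    calls <- dataset$calls
    vals <- matrix(means[calls + 2] + rnorm(length(calls), 0, sd),
                   nrow(calls), dimnames = dimnames(calls))
    vals[is.na(calls)] <- NA_real_
    list(probes = dataset$probes, values = vals)
  })
}

#' Simulate tumor/normal expression cohorts with planted paradoxical genes
#'
#' Tumor expression follows the dosage + miRNA-repression model described in
#' the package vignette; planted paradoxical genes receive repression strong
#' enough to invert their dosage effect (net tumor-vs-normal shift of at least
#' 2 noise SDs in the opposite direction), concentrated in the samples that
#' carry the aberration.  Each cohort also gets a matched per-gene log2 CNA
#' matrix for its tumor samples and a miRNA expression matrix.
#'
#' @param config a [simulation_config()].
#' @param cna_truth result of [simulate_cna_datasets()] (same config).
#' @param mirna_truth result of [simulate_regulatory_truth()] (same config).
#' @return list with `cohorts` (each: `expr`, `mirna`, `gene_cna`, `calls`)
#'   and `truth` (planted ground truth, see [simulate_cohort()]).
#' @export
simulate_expression <- function(config, cna_truth, mirna_truth) {
  layout <- .sim_genome(config)
  if (!isTRUE(all.equal(cna_truth$regions, layout$regions)))
    stop("inconsistent CNA truth: regions do not match this config's genome")
  if (!all(mirna_truth$edges$gene %in% layout$genes$id))
    stop("inconsistent gene/miRNA universes between truths")
  genes <- layout$genes
  regions <- layout$regions
  edges <- mirna_truth$edges
  G <- nrow(genes)

  .with_seed(.sim_seeds(config)[["expr"]], {
    cohorts <- vector("list", config$n_expr_datasets)
    for (cidx in seq_len(config$n_expr_datasets)) {
      TT <- config$samples_per_dataset
      NN <- config$normals_per_dataset
      tum_ids <- sprintf("c%d_t%02d", cidx, seq_len(TT))
      nor_ids <- if (NN > 0) sprintf("c%d_n%02d", cidx, seq_len(NN))

      # per-tumor gene calls from region carrier status + background
      calls <- matrix(0, G, TT, dimnames = list(genes$id, tum_ids))
      if (!is.null(regions)) {
        carrier <- matrix(runif(nrow(regions) * TT) < config$aberration_frequency,
                          nrow(regions), TT)
        for (r in seq_len(nrow(regions))) {
          rows <- which(genes$region %in% r)
          if (length(rows) && any(carrier[r, ]))
            calls[rows, carrier[r, ]] <- regions$direction[r]
        }
      }
      if (config$background_rate > 0) {
        bg <- which(calls == 0 &
                      matrix(runif(length(calls)) < config$background_rate, G))
        calls[bg] <- sample(c(-1, 1), length(bg), replace = TRUE)
      }

      # miRNA expression: deregulated miRNAs shifted in tumors
      M <- length(mirna_truth$mirna_ids)
      mu_m <- mirna_truth$mu
      ym <- matrix(rnorm(M * (TT + NN), 0, config$mirna_noise_sd), M,
                   dimnames = list(mirna_truth$mirna_ids, c(tum_ids, nor_ids)))
      ym <- ym + mu_m
      dereg <- mirna_truth$deregulated
      ym[names(dereg), seq_len(TT)] <-
        ym[names(dereg), seq_len(TT)] + dereg * config$mirna_shift
      dY <- ym[, seq_len(TT), drop = FALSE] - mu_m  # tumor deviation from baseline
      dereg_shift <- matrix(0, M, TT, dimnames = dimnames(dY))
      dereg_shift[names(dereg), ] <- dereg * config$mirna_shift

      # gene expression
      x <- matrix(rnorm(G * (TT + NN), 0, config$noise_sd), G,
                  dimnames = list(genes$id, c(tum_ids, nor_ids)))
      x <- x + genes$mu
      x[, seq_len(TT)] <- x[, seq_len(TT)] + config$dosage_effect * calls
      # programmed repression of paradox genes: r0 off-aberration, r1 on it
      strength <- .paradox_strength(config)
      for (gi in which(genes$is_paradox)) {
        rd <- genes$region_direction[gi]
        m_s <- strength$r0 +
          (strength$r1 - strength$r0) * (calls[gi, ] == rd)
        x[gi, seq_len(TT)] <- x[gi, seq_len(TT)] - rd * m_s
      }
      # miRNA coupling: planted edges track their regulator's fluctuations;
      # background edges carry the full (mean + fluctuation) weak repression
      fluct <- dY - dereg_shift
      for (e in seq_len(nrow(edges))) {
        g <- edges$gene[e]
        m <- edges$mirna[e]
        src <- if (edges$planted[e]) fluct[m, ] else dY[m, ]
        x[g, seq_len(TT)] <- x[g, seq_len(TT)] - edges$coef[e] * src
      }

      # matched per-gene log2 CNA for the tumor samples
      gc <- matrix(config$cna_log_means[calls + 2] +
                     rnorm(G * TT, 0, config$cna_noise_sd),
                   G, dimnames = list(genes$id, tum_ids))

      keep <- rep(TRUE, G)
      if (config$gene_dropout > 0)
        keep[sample.int(G, round(config$gene_dropout * G))] <- FALSE
      cls <- stats::setNames(c(rep("tumor", TT), rep("normal", NN)),
                             c(tum_ids, nor_ids))
      cohorts[[cidx]] <- list(
        expr = expression_matrix(x[keep, , drop = FALSE], cls),
        mirna = expression_matrix(ym, cls),
        gene_cna = gc[keep, , drop = FALSE],
        calls = calls[keep, , drop = FALSE])
    }
    list(cohorts = cohorts, truth = .build_truth(genes, mirna_truth))
  })
}

# assemble the SyntheticTruth object (and its flat table form)
.build_truth <- function(genes, mirna_truth) {
  de <- integer(0)
  region_dir <- stats::setNames(genes$region_direction[genes$region_direction != 0],
                                genes$id[genes$region_direction != 0])
  # paradox genes: expression opposite to region; other region genes: dosage
  de <- stats::setNames(ifelse(genes$is_paradox, -genes$region_direction,
                               genes$region_direction), genes$id)
  # background targets of deregulated miRNAs: repression flips the miRNA sign
  edges <- mirna_truth$edges
  dereg <- mirna_truth$deregulated
  bg <- edges[!edges$planted & edges$mirna %in% names(dereg), ]
  if (nrow(bg)) {
    push <- tapply(-dereg[bg$mirna] * bg$coef, bg$gene, sum)
    sel <- names(push)[sign(push) != 0 & de[names(push)] == 0]
    de[sel] <- sign(push)[match(sel, names(push))]
  }
  paradox_ids <- genes$id[genes$is_paradox]
  stopifnot(all(de[paradox_ids] * region_dir[paradox_ids] == -1))
  table <- data.frame(gene = genes$id,
                      de_direction = unname(de[genes$id]),
                      region_direction = genes$region_direction,
                      is_paradox = genes$is_paradox,
                      stringsAsFactors = FALSE)
  list(paradox_gene_ids = paradox_ids,
       gene_region_direction = region_dir,
       de_direction = de[de != 0],
       deregulated_mirnas = dereg,
       regulator_edges = edges[edges$planted, c("mirna", "gene")],
       table = table)
}

#' Simulate ranked up/down miRNA lists from independent studies
#'
#' Each synthetic study reports a noisy truncated ranking: planted deregulated
#' miRNAs are detected with probability `detection_rate` (with the correct
#' direction), padded with a Poisson number of false-positive miRNAs at
#' unremarkable scores; lists are ranked by a prominence score.  Each planted
#' miRNA carries a latent prominence, drawn once and perturbed per study, so
#' that study rankings are correlated the way real studies of a shared effect
#' are.
#'
#' @param config a [simulation_config()].
#' @param mirna_truth result of [simulate_regulatory_truth()].
#' @return list of [ranked_study()] objects, one per study.
#' @export
simulate_mirna_study_rankings <- function(config, mirna_truth) {
  dereg <- mirna_truth$deregulated
  others <- setdiff(mirna_truth$mirna_ids, names(dereg))
  .with_seed(.sim_seeds(config)[["rankings"]], {
    prominence <- stats::setNames(rnorm(length(dereg), 2, 0.5), names(dereg))
    lapply(seq_len(config$n_mirna_studies), function(j) {
      hit <- runif(length(dereg)) < config$detection_rate
      ids <- names(dereg)[hit]
      dirs <- unname(dereg[hit])
      score <- abs(prominence[ids] + rnorm(sum(hit), 0, 0.4))
      nfp <- min(rpois(1, config$fp_mean), length(others))
      if (nfp > 0) {
        fp <- sample(others, nfp)
        ids <- c(ids, fp)
        dirs <- c(dirs, sample(c(-1L, 1L), nfp, replace = TRUE))
        score <- c(score, abs(rnorm(nfp, 0.5, 0.25)))
      }
      up <- ids[dirs == 1L][order(score[dirs == 1L], decreasing = TRUE)]
      down <- ids[dirs == -1L][order(score[dirs == -1L], decreasing = TRUE)]
      ranked_study(up = up, down = down)
    })
  })
}

#' Simulate a complete multi-cohort study with planted truth
#'
#' One-call wrapper that runs all generators under mutually consistent
#' sub-seeds: genome layout, regulatory truth, CNA call datasets, expression
#' cohorts (with matched per-gene CNA), miRNA study rankings and the target
#' network.
#'
#' @param config a [simulation_config()].
#' @return list with `config`, `genes`, `regions`, `cna` (datasets), `cohorts`,
#'   `mirna_rankings`, `network` and `truth`.  `truth` carries the planted
#'   paradox gene ids, direction maps, deregulated miRNAs and regulator edges.
#' @examples
#' cohort <- simulate_cohort(simulation_config(
#'   n_genes = 100, n_paradox_genes = 4, aberrant_region_count = 2,
#'   samples_per_dataset = 10, normals_per_dataset = 4, seed = 7))
#' length(cohort$truth$paradox_gene_ids)
#' @export
simulate_cohort <- function(config) {
  reg <- simulate_regulatory_truth(config)
  cna <- simulate_cna_datasets(config)
  expr <- simulate_expression(config, cna, reg)
  rankings <- simulate_mirna_study_rankings(config, reg)
  list(config = config, genes = cna$genes, regions = cna$regions,
       cna = cna$datasets, cohorts = expr$cohorts,
       mirna_rankings = rankings, network = reg$network,
       truth = expr$truth)
}

#' Write a simulated cohort to disk in the package's file formats
#'
#' Emits BED gene annotations, SEG-like CNA call files, expression/miRNA/CNA
#' matrices with class sidecars, ranked miRNA study lists, the target network
#' and the planted-truth table.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, sprintf(...))
  files <- c(
    write_bed(cohort$genes, p("genes.bed")),
    if (!is.null(cohort$regions))
      write_bed(transform(cohort$regions,
                          id = sprintf("region%d", seq_len(nrow(cohort$regions)))),
                p("regions_truth.bed")))
  for (d in seq_along(cohort$cna))
    files <- c(files, write_seg_calls(cohort$cna[[d]], p("cna%d.seg.tsv", d)))
  for (cc in seq_along(cohort$cohorts)) {
    co <- cohort$cohorts[[cc]]
    files <- c(files,
      write_expression_matrix(co$expr, p("expr%d.tsv", cc),
                              p("expr%d.classes.tsv", cc)),
      write_expression_matrix(co$mirna, p("mirna%d.tsv", cc),
                              p("mirna%d.classes.tsv", cc)))
    cna_df <- data.frame(feature = rownames(co$gene_cna),
                         stringsAsFactors = FALSE)
    for (j in seq_len(ncol(co$gene_cna)))
      cna_df[[colnames(co$gene_cna)[j]]] <- .fmt_num(co$gene_cna[, j])
    files <- c(files, .write_tsv(cna_df, p("gene_cna%d.tsv", cc)))
  }
  for (s in seq_along(cohort$mirna_rankings))
    files <- c(files, write_ranked_list(cohort$mirna_rankings[[s]],
                                        p("mirna_study%d.tsv", s)))
  files <- c(files, write_target_network(cohort$network, p("targets.tsv")),
             write_truth(cohort$truth$table, p("truth.tsv")))
  invisible(unlist(files))
}
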