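# Paradox classification and sample-wise validation: gene-to-region
# assignment, association chi-square, z-scoring against normals, per-sample
# paradoxical/regular co-occurrence frequencies, and the randomization test.

#' Assign genes to aberrant regions by interval overlap
#'
#' A gene maps to a region when their intervals overlap by at least one base.
#' A gene overlapping regions of both directions maps to the direction with
#' the larger total overlap; exact ties map to none (with a message).
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `id` (0-based
#'   half-open, as from [read_bed()]).
#' @param regions data.frame with `chrom`, `start`, `end`, `direction` (as
#'   from [merge_significant_anchors()]).
#' @return named integer vector over all genes: +1 (gain region), -1 (loss
#'   region) or NA (no region).
#' @export
assign_genes_to_regions <- function(genes, regions) {
  out <- stats::setNames(rep(NA_integer_, nrow(genes)), genes$id)
  if (is.null(regions) || nrow(regions) == 0) return(out)
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start + 1, genes$end))
  r <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1, regions$end))
  hits <- GenomicRanges::findOverlaps(g, r)
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(GenomicRanges::pintersect(g[qh], r[sh]))
  dir <- regions$direction[sh]
  # total overlap per gene and direction
  key <- paste(qh, dir)
  tot <- tapply(ov, key, sum)
  gene_i <- as.integer(sub(" .*", "", names(tot)))
  d <- as.integer(sub(".* ", "", names(tot)))
  for (gi in unique(gene_i)) {
    rows <- gene_i == gi
    if (sum(rows) == 1L) {
      out[gi] <- d[rows]
    } else {
      w <- tot[rows]
      if (w[1] == w[2]) {
        message(sprintf(
          "gene %s overlaps gain and loss regions equally; unassigned",
          genes$id[gi]))
      } else {
        out[gi] <- d[rows][which.max(w)]
      }
    }
  }
  out
}

#' Chi-square association between aberrations and differential expression
#'
#' Builds the 2x2 table of differentially expressed genes inside aberrant
#' regions (rows: up/down; columns: in-gain/in-loss) and applies the Pearson
#' chi-square test with 1 df and no continuity correction.
#'
#' @param de_direction named vector of DE directions (+1/-1) for the
#'   significant genes.
#' @param region_map named region-direction vector from
#'   [assign_genes_to_regions()].
#' @return list with `chi2`, `p` and the 2x2 `counts` table.
#' @export
association_chi_square <- function(de_direction, region_map) {
  common <- intersect(names(de_direction), names(region_map)[!is.na(region_map)])
  if (!length(common)) stop("no DE gene lies inside an aberrant region")
  de <- factor(ifelse(de_direction[common] > 0, "up", "down"),
               levels = c("up", "down"))
  reg <- factor(ifelse(region_map[common] > 0, "gain", "loss"),
                levels = c("gain", "loss"))
  tab <- table(de, reg)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a zero marginal in the 2x2 table; consider an exact test")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value), counts = tab)
}

#' Classify deregulated genes in aberrant regions as paradoxical or regular
#'
#' One record per differentially expressed gene inside an aberrant region;
#' paradoxical means the expression direction opposes the region's
#' copy-number direction.
#'
#' @inheritParams association_chi_square
#' @return data.frame with `gene`, `de_direction`, `region_direction`,
#'   `is_paradoxical`.
#' @export
identify_paradoxical <- function(de_direction, region_map) {
  common <- intersect(names(de_direction), names(region_map)[!is.na(region_map)])
  data.frame(gene = common,
             de_direction = unname(de_direction[common]),
             region_direction = unname(region_map[common]),
             is_paradoxical = de_direction[common] * region_map[common] == -1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Standardize tumor expression against the normal-sample distribution
#'
#' `z[g,s] = (x[g,s] - mean_normals(g)) / sd_normals(g)` with the n-1 sample
#' SD.  Genes with constant normal expression get missing z-scores (with a
#' message).  Alternatively standardize against all samples.
#'
#' @param em an [expression_matrix()] with at least 2 normal samples.
#' @param reference `"normal"` (default) or `"all"`.
#' @return numeric gene x tumor-sample matrix of z-scores.
#' @export
zscore_expression <- function(em, reference = c("normal", "all")) {
  reference <- match.arg(reference)
  ref <- if (reference == "normal") .em_normals(em) else em$values
  if (ncol(ref) < 2) stop("need at least 2 reference samples")
  mu <- rowMeans(ref)
  sd <- sqrt(rowSums((ref - mu)^2) / (ncol(ref) - 1))
  degenerate <- sd == 0
  if (any(degenerate)) {
    message(sprintf("%d gene(s) with constant reference expression: z set missing",
                    sum(degenerate)))
    sd[degenerate] <- NA_real_
  }
  (.em_tumors(em) - mu) / sd
}

#' Per-sample paradoxical and regular co-occurrence frequencies
#'
#' For each classified gene, counts tumor samples where the gene is deregulated
#' on its consensus side (|z| beyond `z_cut`) while its copy number is beyond
#' `cna_cut` on the *opposite* side (paradoxical event) or the *same* side
#' (regular event), over samples with both values present.  Also reports the
#' marginal up/down/gain/loss frequencies.
#'
#' @param z gene x tumor-sample z-score matrix ([zscore_expression()]).
#' @param cna gene x tumor-sample log2 copy-number matrix, same samples.
#' @param records data.frame from [identify_paradoxical()].
#' @param thresholds an [analysis_thresholds()].
#' @return `records` with columns `freq_paradoxical`, `freq_regular`,
#'   `freq_up`, `freq_down`, `freq_gain`, `freq_loss`, `n_informative` added.
#' @export
sample_paradox_frequencies <- function(z, cna, records,
                                       thresholds = analysis_thresholds()) {
  stopifnot(identical(colnames(z), colnames(cna)))
  cols <- c("freq_paradoxical", "freq_regular", "freq_up", "freq_down",
            "freq_gain", "freq_loss")
  for (cl in cols) records[[cl]] <- NA_real_
  records$n_informative <- 0L
  for (i in seq_len(nrow(records))) {
    g <- records$gene[i]
    if (!(g %in% rownames(z) && g %in% rownames(cna))) next
    ev <- .paradox_events(z[g, ], cna[g, ], records$de_direction[i], thresholds)
    records$n_informative[i] <- ev$n
    if (ev$n == 0) next
    records$freq_paradoxical[i] <- ev$n_par / ev$n
    records$freq_regular[i] <- ev$n_reg / ev$n
    records$freq_up[i] <- ev$n_up / ev$n
    records$freq_down[i] <- ev$n_down / ev$n
    records$freq_gain[i] <- ev$n_gain / ev$n
    records$freq_loss[i] <- ev$n_loss / ev$n
  }
  records
}

# event counts for one gene; d is the gene's consensus DE direction
.paradox_events <- function(zv, cv, d, th) {
  ok <- !is.na(zv) & !is.na(cv)
  zv <- zv[ok]; cv <- cv[ok]
  dereg <- d * zv > th$z_cut            # deregulated on the consensus side
  gain <- cv > th$cna_cut
  loss <- cv < -th$cna_cut
  opp <- if (d > 0) loss else gain      # CNA opposing the expression change
  same <- if (d > 0) gain else loss
  list(n = length(zv),
       n_par = sum(dereg & opp), n_reg = sum(dereg & same),
       n_up = sum(zv > th$z_cut), n_down = sum(zv < -th$z_cut),
       n_gain = sum(gain), n_loss = sum(loss),
       dereg = dereg, n_opp = sum(opp), n_same = sum(same))
}

#' Randomization validation of a gene's paradoxical status
#'
#' Test statistic `T = freq_paradoxical - freq_regular`.  The null permutes
#' the sample labels of the gene's CNA vector relative to its z-score vector;
#' under such a permutation the numbers of opposite-side and same-side CNA
#' events landing on deregulated samples follow a multivariate hypergeometric
#' law, which is sampled directly (`n_rand` draws, add-one-corrected p).  The
#' gene is validated when `p < validation_alpha` *and* the paradoxical
#' frequency exceeds the regular one.
#'
#' @param zv,cv the gene's z-score and log2 CNA vectors over matched tumor
#'   samples.
#' @param de_direction the gene's consensus DE direction (+1/-1).
#' @param thresholds an [analysis_thresholds()].
#' @param n_rand number of randomizations (default 1e5 so p < 1e-4 is
#'   attainable).
#' @param seed RNG seed.
#' @return list with `statistic`, `p`, `validated`, `freq_paradoxical`,
#'   `freq_regular`, `n_informative`.
#' @export
validate_gene_randomization <- function(zv, cv, de_direction,
                                        thresholds = analysis_thresholds(),
                                        n_rand = 1e5, seed = 1L) {
  if (n_rand < 1) stop("n_rand must be at least 1")
  ev <- .paradox_events(zv, cv, de_direction, thresholds)
  if (ev$n == 0)
    return(list(statistic = NA_real_, p = NA_real_, validated = FALSE,
                freq_paradoxical = NA_real_, freq_regular = NA_real_,
                n_informative = 0L))
  s_obs <- ev$n_par - ev$n_reg
  k <- sum(ev$dereg)
  n_none <- ev$n - ev$n_opp - ev$n_same
  .with_seed(seed, {
    a <- stats::rhyper(n_rand, ev$n_opp, ev$n - ev$n_opp, k)
    b <- stats::rhyper(n_rand, ev$n_same, pmax(n_none, 0), k - a)
    p <- (sum(a - b >= s_obs) + 1) / (n_rand + 1)
  })
  fp <- ev$n_par / ev$n; fr <- ev$n_reg / ev$n
  list(statistic = (ev$n_par - ev$n_reg) / ev$n, p = p,
       validated = p < thresholds$validation_alpha && fp > fr,
       freq_paradoxical = fp, freq_regular = fr, n_informative = ev$n)
}

#' Validate all paradoxical records of a cohort
#'
#' Convenience wrapper running [validate_gene_randomization()] per gene with
#' per-gene sub-seeds derived from `seed`.
#'
#' @inheritParams sample_paradox_frequencies
#' @inheritParams validate_gene_randomization
#' @return `records` with `validation_p` and `validated` columns added (genes
#'   missing from `z`/`cna` keep NA / FALSE).
#' @export
validate_paradox_genes <- function(z, cna, records,
                                   thresholds = analysis_thresholds(),
                                   n_rand = 1e5, seed = 1L) {
  seeds <- .derive_seeds(seed, records$gene)
  records$validation_p <- NA_real_
  records$validated <- FALSE
  for (i in seq_len(nrow(records))) {
    g <- records$gene[i]
    if (!(g %in% rownames(z) && g %in% rownames(cna))) next
    v <- validate_gene_randomization(z[g, ], cna[g, ],
                                     records$de_direction[i], thresholds,
                                     n_rand = n_rand, seed = seeds[[g]])
    records$validation_p[i] <- v$p
    records$validated[i] <- v$validated
  }
  records
}
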