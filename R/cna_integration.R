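# CNA integration: discrete calling, anchor construction across heterogeneous
# probe grids, per-anchor permutation test, and merging of significant anchors
# into aberrant regions.

#' Discretize log2 copy-number ratios into calls
#'
#' Threshold caller: values strictly below `loss_cut` become -1, strictly above
#' `gain_cut` become +1, everything else (including values exactly at a cutoff)
#' is neutral.  Missing values stay missing.
#'
#' @param values numeric probe x sample matrix of log2 ratios.
#' @param loss_cut,gain_cut cutoffs with `loss_cut < 0 < gain_cut`; defaults
#'   are the +/-0.2 log2 convention used throughout the package.
#' @return matrix of calls in \{-1, 0, +1, NA\}.
#' @export
call_from_log_ratios <- function(values, loss_cut = -0.2, gain_cut = 0.2) {
  if (!is.finite(loss_cut) || !is.finite(gain_cut))
    stop("cutoffs must be finite")
  if (!(loss_cut < 0 && gain_cut > 0))
    stop("need loss_cut < 0 < gain_cut")
  calls <- matrix(0, nrow(values), ncol(values), dimnames = dimnames(values))
  calls[values < loss_cut] <- -1
  calls[values > gain_cut] <- 1
  calls[is.na(values)] <- NA
  calls
}

#' Integrate probe call datasets onto genome-wide anchors
#'
#' Anchors are the sorted unique starts and ends of all probes across all
#' datasets.  For each anchor and dataset, the call vector of the probe
#' covering the anchor position (half-open containment; on overlap the probe
#' with the smaller span wins, ties to the leftmost start) is assigned, or a
#' missing vector when no probe covers it.  Anchors missing from more than one
#' dataset are dropped; pooled gain/loss counts and frequencies are computed
#' over all informative sample-calls.
#'
#' @param datasets list of [probe_call_dataset()] objects.
#' @return an object of class `anchor_table`: list with `anchors` (data.frame
#'   chrom, pos, gain_count, loss_count, n_informative, gain_freq, loss_freq,
#'   p_gain, p_loss), `calls` (anchor x pooled-sample matrix, NA = missing) and
#'   `sample_dataset` (dataset index per pooled sample).
#' @export
build_anchor_table <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  chrom_sets <- lapply(datasets, function(d) unique(d$probes$chrom))
  if (length(datasets) > 1 && !length(Reduce(intersect, chrom_sets)))
    stop("datasets share no chromosomes: no common genome to anchor")

  pos_df <- unique(do.call(rbind, lapply(datasets, function(d)
    data.frame(chrom = rep(d$probes$chrom, 2L),
               pos = c(d$probes$start, d$probes$end),
               stringsAsFactors = FALSE))))
  pos_df <- pos_df[order(pos_df$chrom, pos_df$pos), ]
  rownames(pos_df) <- NULL
  A <- nrow(pos_df)

  call_blocks <- vector("list", length(datasets))
  missing_ds <- matrix(FALSE, A, length(datasets))
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    # anchor pos covered by probe [start, end): 1-based ranges (start+1, end)
    anchors_gr <- GenomicRanges::GRanges(pos_df$chrom,
                                         IRanges::IRanges(pos_df$pos + 1,
                                                          pos_df$pos + 1))
    probes_gr <- GenomicRanges::GRanges(ds$probes$chrom,
                                        IRanges::IRanges(ds$probes$start + 1,
                                                         ds$probes$end))
    hits <- GenomicRanges::findOverlaps(anchors_gr, probes_gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    # smaller span wins, ties to leftmost start
    span <- ds$probes$end[sh] - ds$probes$start[sh]
    o <- order(qh, span, ds$probes$start[sh])
    qh <- qh[o]; sh <- sh[o]
    first <- !duplicated(qh)
    assign_probe <- rep(NA_integer_, A)
    assign_probe[qh[first]] <- sh[first]

    block <- matrix(NA_real_, A, length(ds$sample_ids))
    covered <- !is.na(assign_probe)
    block[covered, ] <- ds$calls[assign_probe[covered], , drop = FALSE]
    colnames(block) <- paste0("d", d, ".", ds$sample_ids)
    call_blocks[[d]] <- block
    missing_ds[, d] <- !covered
  }
  keep <- rowSums(missing_ds) <= 1L
  calls <- do.call(cbind, call_blocks)[keep, , drop = FALSE]
  pos_df <- pos_df[keep, , drop = FALSE]

  gain_count <- rowSums(calls == 1, na.rm = TRUE)
  loss_count <- rowSums(calls == -1, na.rm = TRUE)
  n_informative <- rowSums(!is.na(calls))
  anchors <- data.frame(
    pos_df,
    gain_count = gain_count, loss_count = loss_count,
    n_informative = n_informative,
    gain_freq = ifelse(n_informative > 0, gain_count / n_informative, NA),
    loss_freq = ifelse(n_informative > 0, loss_count / n_informative, NA),
    p_gain = NA_real_, p_loss = NA_real_)
  rownames(anchors) <- NULL
  structure(list(anchors = anchors, calls = calls,
                 sample_dataset = rep(seq_along(datasets),
                                      vapply(call_blocks, ncol, 0L))),
            class = "anchor_table")
}

#' @export
print.anchor_table <- function(x, ...) {
  cat(sprintf("<anchor_table> %d anchors x %d pooled samples (%d datasets)\n",
              nrow(x$anchors), ncol(x$calls), max(x$sample_dataset)))
  invisible(x)
}

#' Permutation test of per-anchor gain/loss frequencies
#'
#' Null model: independently for every sample, that sample's calls are shuffled
#' across its informative anchors, preserving the sample's aberration burden
#' (its total numbers of gains and losses).  Empirical p-values use the add-one
#' correction, `p = (#\{permuted count >= observed\} + 1) / (n_perm + 1)`,
#' separately for gains and losses.
#'
#' @param table an [build_anchor_table()] result.
#' @param n_perm number of permutations (default 1e4; use 1e6 to match the
#'   convention of large production runs).
#' @param seed RNG seed.
#' @param alpha significance level stored alongside (default 0.05).
#' @return the `anchor_table` with `p_gain`, `p_loss`, `sig_gain`, `sig_loss`
#'   columns filled in.
#' @export
anchor_frequency_test <- function(table, n_perm = 1e4, seed = 1L,
                                  alpha = 0.05) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  calls <- table$calls
  A <- nrow(calls)
  obs_gain <- table$anchors$gain_count
  obs_loss <- table$anchors$loss_count

  inf_idx <- g_idx <- l_idx <- vector("list", ncol(calls))
  for (s in seq_len(ncol(calls))) {
    col <- calls[, s]
    inf_idx[[s]] <- which(!is.na(col))
    g_idx[[s]] <- sum(col == 1, na.rm = TRUE)
    l_idx[[s]] <- sum(col == -1, na.rm = TRUE)
  }
  ng <- unlist(g_idx); nl <- unlist(l_idx)
  active <- which(ng + nl > 0)

  exceed_gain <- exceed_loss <- integer(A)
  .with_seed(seed, {
    for (i in seq_len(n_perm)) {
      gains <- losses <- vector("list", length(active))
      for (j in seq_along(active)) {
        s <- active[j]
        pick <- inf_idx[[s]][sample.int(length(inf_idx[[s]]), ng[s] + nl[s])]
        if (ng[s]) gains[[j]] <- pick[seq_len(ng[s])]
        if (nl[s]) losses[[j]] <- pick[seq.int(ng[s] + 1, length.out = nl[s])]
      }
      cg <- tabulate(as.integer(unlist(gains)), nbins = A)
      cl <- tabulate(as.integer(unlist(losses)), nbins = A)
      exceed_gain <- exceed_gain + (cg >= obs_gain)
      exceed_loss <- exceed_loss + (cl >= obs_loss)
    }
  })
  table$anchors$p_gain <- (exceed_gain + 1) / (n_perm + 1)
  table$anchors$p_loss <- (exceed_loss + 1) / (n_perm + 1)
  table$anchors$sig_gain <- table$anchors$p_gain < alpha
  table$anchors$sig_loss <- table$anchors$p_loss < alpha
  table$alpha <- alpha
  table
}

#' Merge runs of significant anchors into aberrant regions
#'
#' Maximal runs of same-direction significant anchors, with inter-anchor gaps
#' of at most `max_gap` bases, become one region spanning
#' `[first anchor, last anchor + 1)`.  A significant anchor of the opposite
#' direction interrupts a run.  An anchor significant in both directions is
#' assigned its more significant one (ties to gain, with a message).  The
#' region's frequency (and p-value) are the peak anchor values of the run.
#'
#' @param table an `anchor_table` after [anchor_frequency_test()].
#' @param max_gap maximal within-region inter-anchor gap, bases.
#' @param alpha significance level (defaults to the one used in the test).
#' @return data.frame with columns `chrom`, `start`, `end`, `direction`
#'   (+1 gain / -1 loss), `frequency`, `p`, `n_anchors`.
#' @export
merge_significant_anchors <- function(table, max_gap, alpha = NULL) {
  an <- table$anchors
  if (all(is.na(an$p_gain))) stop("run anchor_frequency_test() first")
  if (is.null(alpha)) alpha <- if (!is.null(table$alpha)) table$alpha else 0.05
  sg <- an$p_gain < alpha
  sl <- an$p_loss < alpha
  both <- sg & sl
  if (any(both)) {
    to_gain <- an$p_gain[both] <= an$p_loss[both]
    if (any(an$p_gain[both] == an$p_loss[both]))
      message("anchor(s) equally significant for gain and loss; kept as gain")
    sl[both] <- !to_gain
    sg[both] <- to_gain
  }
  sig <- sg | sl
  if (!any(sig))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = integer(), frequency = numeric(),
                      p = numeric(), n_anchors = integer(),
                      stringsAsFactors = FALSE))
  df <- an[sig, ]
  df$direction <- ifelse(sg[sig], 1L, -1L)
  df$freq <- ifelse(df$direction == 1L, df$gain_freq, df$loss_freq)
  df$p <- ifelse(df$direction == 1L, df$p_gain, df$p_loss)
  df <- df[order(df$chrom, df$pos), ]
  new_run <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                 df$direction[-1] != df$direction[-nrow(df)] |
                 (df$pos[-1] - df$pos[-nrow(df)]) > max_gap)
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(df, run), function(r)
    data.frame(chrom = r$chrom[1], start = min(r$pos), end = max(r$pos) + 1,
               direction = r$direction[1], frequency = max(r$freq),
               p = min(r$p), n_anchors = nrow(r), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), ]
}
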