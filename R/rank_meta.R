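# Robust rank aggregation meta-analysis: per-cohort differential ranking,
# order-statistic rho score, Bonferroni-style p, leave-one-out correction.
# Shared by the gene meta-analysis and the miRNA meta-analysis.

#' Rank features by tumor-vs-normal differential expression
#'
#' Per-feature Welch two-sample statistic with Benjamini-Hochberg adjustment
#' over all features; features split into up-/downregulated by the sign of the
#' tumor-minus-normal mean difference and ranked by adjusted p ascending, ties
#' broken by absolute mean difference descending then id.  Constant features
#' (zero difference) rank last in the up list.
#'
#' @param em an [expression_matrix()] with at least 2 tumors and 2 normals.
#' @return a [ranked_study()] whose `measured` set is all features tested.
#' @export
rank_differential <- function(em) {
  tum <- .em_tumors(em); nor <- .em_normals(em)
  if (ncol(tum) < 2 || ncol(nor) < 2)
    stop("need at least 2 samples in each class")
  n1 <- ncol(tum); n0 <- ncol(nor)
  m1 <- rowMeans(tum); m0 <- rowMeans(nor)
  v1 <- rowSums((tum - m1)^2) / (n1 - 1)
  v0 <- rowSums((nor - m0)^2) / (n0 - 1)
  dm <- m1 - m0
  se2 <- v1 / n1 + v0 / n0
  t <- ifelse(se2 > 0, dm / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)), 1)
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- 1
  padj <- stats::p.adjust(p, method = "BH")

  ids <- rownames(em$values)
  ord <- order(padj, -abs(dm), ids)
  up <- ids[ord][dm[ord] >= 0]
  down <- ids[ord][dm[ord] < 0]
  ranked_study(up = up, down = down, measured = ids)
}

#' Robust rank aggregation score for one feature
#'
#' Given the feature's normalized ranks across the lists where it is measured,
#' sorts them ascending and computes, for each order statistic k, the
#' probability that at least k of `n_lists` independent uniforms fall at or
#' below the k-th smallest rank:
#' `beta_k = sum_{j >= k} C(n, j) r_(k)^j (1 - r_(k))^(n-j)`.
#' The score is `rho = min_k beta_k` and the (Bonferroni-corrected) p-value is
#' `min(1, n * rho)`.  If fewer ranks than `n_lists` are supplied the vector is
#' padded with worst ranks (1), which leaves the order statistics unchanged.
#'
#' @param r numeric vector of normalized ranks, each in (0, 1].
#' @param n_lists number of lists (defaults to `length(r)`).
#' @return list with `rho` and `p`.
#' @examples
#' rra_rho(c(0.1, 0.2))  # rho = 0.04, p = 0.08
#' @export
rra_rho <- function(r, n_lists = length(r)) {
  if (!length(r)) stop("empty rank vector")
  if (any(r <= 0 | r > 1)) stop("normalized ranks must lie in (0, 1]")
  if (n_lists < length(r)) stop("n_lists smaller than the number of ranks")
  n <- as.integer(n_lists)
  r <- sort(c(r, rep(1, n - length(r))))
  beta <- stats::pbinom(seq_len(n) - 1L, n, r, lower.tail = FALSE)
  rho <- min(beta)
  list(rho = rho, p = min(1, n * rho))
}

# vectorized rho/p over a feature x list matrix of normalized ranks
# (NA = feature unmeasured in that list); returns data.frame rho, p, n_used
.rra_matrix <- function(M) {
  res <- t(apply(M, 1, function(r) {
    r <- r[!is.na(r)]
    n <- length(r)
    if (!n) return(c(NA_real_, NA_real_, 0))
    r <- sort(r)
    rho <- min(stats::pbinom(seq_len(n) - 1L, n, r, lower.tail = FALSE))
    c(rho, min(1, n * rho), n)
  }))
  data.frame(rho = res[, 1], p = res[, 2], n_used = as.integer(res[, 3]))
}

# build the normalized-rank matrix for one direction across studies.
# universe = "union": every feature counts as measured everywhere and the
# denominator is the union size (the convention for truncated published
# lists); "per_list": each study's own measured set and universe size.
.rank_matrix <- function(studies, features, direction,
                         universe = c("union", "per_list")) {
  universe <- match.arg(universe)
  M <- matrix(NA_real_, length(features), length(studies),
              dimnames = list(features, NULL))
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    lst <- st[[direction]]
    if (universe == "union") {
      us <- length(features)
      measured <- features
    } else {
      measured <- st$measured
      if (is.null(measured))
        stop("per-list universe requires studies with a `measured` set")
      us <- if (is.na(st$universe_size)) length(measured) else st$universe_size
    }
    M[match(measured, features), i] <- 1
    pos <- match(lst, features)
    M[pos[!is.na(pos)], i] <- seq_along(lst)[!is.na(pos)] / us
  }
  M
}

#' Aggregate ranked up/down lists across studies
#'
#' For each direction and feature, normalized ranks are position / universe
#' size in each study where the feature is measured (worst rank 1 when
#' measured but unlisted; no entry when unmeasured, reducing the number of
#' lists used).  [rra_rho()] gives the score and p; the leave-one-out
#' corrected `p_loo` is the mean of the p-values obtained when excluding each
#' study in turn.  A feature scored in both directions keeps the direction
#' with the smaller `p_loo` (ties are dropped with a message).
#'
#' @param studies list of at least two [ranked_study()] objects.
#' @param alpha significance level applied to `p_loo`.
#' @param universe `"per_list"` (each study's measured set and universe size;
#'   use for full rankings such as [rank_differential()] output) or `"union"`
#'   (truncated published lists; denominator is the union of all studies'
#'   features).
#' @return data.frame with columns `id`, `direction`, `rho`, `p`, `p_loo`,
#'   `n_lists_used`, `significant`, ordered by `p_loo`.
#' @export
aggregate_ranked_lists <- function(studies, alpha = 0.05,
                                   universe = c("union", "per_list")) {
  universe <- match.arg(universe)
  if (length(studies) < 2) stop("need at least two studies")
  features <- sort(unique(unlist(lapply(studies, function(st)
    c(st$up, st$down, st$measured)))))
  if (!length(features)) stop("empty feature universe")

  per_dir <- lapply(c(up = "up", down = "down"), function(dir) {
    M <- .rank_matrix(studies, features, dir, universe)
    full <- .rra_matrix(M)
    loo_p <- vapply(seq_along(studies), function(j) {
      sub <- .rra_matrix(M[, -j, drop = FALSE])
      ifelse(is.na(sub$p), 1, sub$p)   # no remaining evidence: p = 1
    }, numeric(length(features)))
    keep <- full$n_used > 0
    data.frame(id = features,
               direction = if (dir == "up") 1L else -1L,
               rho = full$rho, p = full$p,
               p_loo = rowMeans(loo_p),
               n_lists_used = full$n_used,
               stringsAsFactors = FALSE)[keep, ]
  })
  res <- rbind(per_dir$up, per_dir$down)
  # one row per feature: the direction with smaller p_loo; exact ties dropped
  res <- res[order(res$id, res$p_loo), ]
  dup <- duplicated(res$id)
  firsts <- res[!dup, ]
  seconds <- res[dup, ]
  tied_ids <- intersect(firsts$id, seconds$id)
  tied_ids <- tied_ids[firsts$p_loo[match(tied_ids, firsts$id)] ==
                         seconds$p_loo[match(tied_ids, seconds$id)]]
  if (length(tied_ids)) {
    message(sprintf("%d feature(s) tied between directions; excluded: %s",
                    length(tied_ids),
                    paste(utils::head(tied_ids, 5), collapse = ", ")))
    firsts <- firsts[!firsts$id %in% tied_ids, ]
  }
  firsts$significant <- firsts$p_loo < alpha
  firsts <- firsts[order(firsts$p_loo, firsts$id), ]
  rownames(firsts) <- NULL
  firsts
}

#' Leave-one-out corrected aggregation p-value for one feature
#'
#' Re-runs the aggregation once per study with that study excluded and
#' averages the resulting p-values.  Exposed mainly for inspection; the same
#' correction is applied to every feature by [aggregate_ranked_lists()].
#'
#' @param studies list of at least two [ranked_study()] objects.
#' @param id feature id.
#' @param direction `"up"` or `"down"`.
#' @inheritParams aggregate_ranked_lists
#' @return the corrected p-value (mean of the leave-one-out p-values).
#' @export
loo_correct <- function(studies, id, direction = c("up", "down"),
                        universe = c("union", "per_list")) {
  direction <- match.arg(direction)
  universe <- match.arg(universe)
  if (length(studies) < 2) stop("leave-one-out undefined for a single list")
  features <- sort(unique(unlist(lapply(studies, function(st)
    c(st$up, st$down, st$measured)))))
  if (!id %in% features) stop(sprintf("feature '%s' not present in any study", id))
  M <- .rank_matrix(studies, features, direction, universe)
  r_all <- M[id, ]
  mean(vapply(seq_along(studies), function(j) {
    r <- r_all[-j]
    r <- r[!is.na(r)]
    if (!length(r)) return(1)
    rra_rho(r)$p
  }, 0))
}
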