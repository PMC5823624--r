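# miRNA:gene association: target-overlap enrichment, CNA-controlled partial
# correlation with an empirical null, explanatory classification, and the
# coefficient of multiple correlation (CMC) with empirical percentiles.

# strict upper-tail hypergeometric probability P(X > observed)
.hyper_tail <- function(overlap, N, K, n) {
  if (K > N || n > N || overlap > min(K, n))
    stop("inconsistent hypergeometric parameters")
  stats::phyper(overlap, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric overlap test between a gene set and miRNA targets
#'
#' Tests whether the hit set is enriched for genes targeted by the deregulated
#' miRNAs, against a population of eligible genes.  The reported p-value is
#' the strict upper tail, `P(X > overlap)`.
#'
#' @param hit_genes character vector (e.g. validated paradoxical genes); must
#'   be a subset of `population`.
#' @param targeted character vector of population genes with at least one edge
#'   from the deregulated miRNA set.
#' @param population character vector of all eligible genes, or a single
#'   count.
#' @return list with `overlap`, `n_hits`, `n_targeted`, `n_population`, `p`.
#' @examples
#' # toy: 10 genes, 5 targeted, draw 2, overlap 0 -> p = 7/9
#' target_overlap_test(c("a", "b"), letters[3:7], letters[1:10])$p
#' @export
target_overlap_test <- function(hit_genes, targeted, population) {
  if (is.character(population)) {
    if (!all(hit_genes %in% population))
      stop("hit genes must be drawn from the population")
    targeted <- intersect(targeted, population)
    N <- length(population)
  } else {
    N <- as.integer(population)
  }
  K <- length(unique(targeted))
  n <- length(unique(hit_genes))
  overlap <- length(intersect(hit_genes, targeted))
  list(overlap = overlap, n_hits = n, n_targeted = K, n_population = N,
       p = .hyper_tail(overlap, N, K, n))
}

#' First-order partial correlation
#'
#' Pearson correlation of `x` and `y` after linearly removing a controlling
#' variable `z`:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' Undefined (returned as NA with a warning) when `x` or `y` is collinear
#' with `z`.
#'
#' @param x,y,z numeric vectors of equal length >= 4, each non-constant.
#' @return the partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("vectors must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("constant input vector")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den2 <- (1 - rxz^2) * (1 - ryz^2)
  if (den2 <= .Machine$double.eps) {
    warning("controlling variable collinear with an input; partial correlation undefined")
    return(NA_real_)
  }
  (rxy - rxz * ryz) / sqrt(den2)
}

# vectorized partial correlations for (gene, mirna) pairs, controlling each
# pair by the *gene's* CNA vector.  All matrices are feature x sample over the
# same samples.  Returns NA for pairs with constant/collinear inputs.
.pair_partial <- function(pairs, gene_expr, mirna_expr, gene_cna) {
  zs <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2))
    sw <- ifelse(s > 0, s, NA_real_)
    (m - mu) / sw
  }
  n <- ncol(gene_expr)
  Zg <- zs(gene_expr); Zm <- zs(mirna_expr); Zc <- zs(gene_cna)
  gi <- match(pairs$gene, rownames(gene_expr))
  mi <- match(pairs$mirna, rownames(mirna_expr))
  ci <- match(pairs$gene, rownames(gene_cna))
  rxy <- rowSums(Zg[gi, , drop = FALSE] * Zm[mi, , drop = FALSE])
  rxz <- rowSums(Zg[gi, , drop = FALSE] * Zc[ci, , drop = FALSE])
  ryz <- rowSums(Zm[mi, , drop = FALSE] * Zc[ci, , drop = FALSE])
  den2 <- (1 - rxz^2) * (1 - ryz^2)
  out <- (rxy - rxz * ryz) / sqrt(den2)
  out[den2 <= .Machine$double.eps] <- NA_real_
  out
}

#' Empirical significance of miRNA:gene partial correlations
#'
#' Computes the CNA-controlled partial correlation for each tested pair and
#' compares it two-sidedly with the distribution of the same measure over
#' `n_null` random (gene, miRNA) pairs drawn uniformly (with replacement) from
#' the full universes, excluding the tested pair itself.  Empirical p-values
#' use rank-based tails with the add-one correction,
#' `p = min(1, 2 min(lower, upper))`.
#'
#' @param pairs data.frame with columns `mirna`, `gene`.
#' @param gene_expr,mirna_expr,gene_cna feature x sample matrices over the
#'   same (tumor) samples; `gene_cna` holds each gene's log2 copy number, the
#'   controlling variable.
#' @param n_null number of random null pairs (>= 100; default 1e4).
#' @param seed RNG seed (recorded in the output attributes).
#' @param alpha significance level (default 0.05).
#' @return `pairs` with `r_partial`, `empirical_p`, `significant` added;
#'   attribute `null_r` holds the null draws.
#' @export
empirical_pair_test <- function(pairs, gene_expr, mirna_expr, gene_cna,
                                n_null = 1e4, seed = 1L, alpha = 0.05) {
  if (n_null < 100) stop("n_null must be at least 100")
  if (nrow(gene_expr) < 2 || nrow(mirna_expr) < 2)
    stop("gene and miRNA universes must have at least 2 features")
  pairs$r_partial <- .pair_partial(pairs, gene_expr, mirna_expr, gene_cna)
  null_pairs <- .with_seed(seed, data.frame(
    gene = rownames(gene_expr)[sample.int(nrow(gene_expr), n_null,
                                          replace = TRUE)],
    mirna = rownames(mirna_expr)[sample.int(nrow(mirna_expr), n_null,
                                            replace = TRUE)],
    stringsAsFactors = FALSE))
  null_r <- .pair_partial(null_pairs, gene_expr, mirna_expr, gene_cna)
  pairs$empirical_p <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    r <- pairs$r_partial[i]
    if (is.na(r)) next
    keep <- !(null_pairs$gene == pairs$gene[i] &
                null_pairs$mirna == pairs$mirna[i]) & !is.na(null_r)
    nr <- null_r[keep]
    m <- length(nr)
    lower <- (sum(nr <= r) + 1) / (m + 1)
    upper <- (sum(nr >= r) + 1) / (m + 1)
    pairs$empirical_p[i] <- min(1, 2 * min(lower, upper))
  }
  pairs$significant <- !is.na(pairs$empirical_p) & pairs$empirical_p < alpha
  attr(pairs, "null_r") <- null_r
  attr(pairs, "seed") <- seed
  pairs
}

#' Classify a significant pair as explanatory
#'
#' A pair is explanatory when it is significant and the sign of its partial
#' correlation matches the product of the deregulation directions: positive
#' correlation for same-direction deregulation, negative for inverse
#' deregulation.  A correlation of exactly zero is never explanatory.
#'
#' @param mirna_direction,gene_direction deregulation directions (+1/-1),
#'   vectorized.
#' @param r_partial partial correlation(s).
#' @param significant logical significance flag(s).
#' @return logical vector.
#' @export
classify_explanatory <- function(mirna_direction, gene_direction, r_partial,
                                 significant) {
  stopifnot(all(mirna_direction %in% c(-1, 1)),
            all(gene_direction %in% c(-1, 1)))
  !is.na(r_partial) & significant &
    sign(r_partial) == mirna_direction * gene_direction
}

#' Coefficient of multiple correlation
#'
#' `C = sqrt(c' R^-1 c)` where `c` is the vector of Pearson correlations of
#' the gene with each miRNA and `R` the miRNA x miRNA correlation matrix: the
#' correlation between the gene and its best linear prediction from the
#' miRNAs.  When `R` is singular, or `C^2` falls outside [0, 1] by more than
#' numerical tolerance, the least-squares pseudo-solution is used, the value
#' is clipped, and a condition-number warning is raised.
#'
#' @param c_vector numeric vector of gene:miRNA correlations.
#' @param r_matrix symmetric miRNA correlation matrix with unit diagonal.
#' @return the multiple correlation coefficient in [0, 1].
#' @export
multiple_correlation <- function(c_vector, r_matrix) {
  r_matrix <- as.matrix(r_matrix)
  if (length(c_vector) != nrow(r_matrix) || nrow(r_matrix) != ncol(r_matrix))
    stop("dimension mismatch between c and R")
  sol <- tryCatch(solve(r_matrix, c_vector), error = function(e) NULL)
  C2 <- if (!is.null(sol)) sum(c_vector * sol) else NA_real_
  if (is.null(sol) || !is.finite(C2) || C2 < -.C2_TOL || C2 > 1 + .C2_TOL) {
    sv <- svd(r_matrix)
    pos <- sv$d > max(sv$d) * 1e-12
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    C2 <- drop(crossprod(c_vector, pinv %*% c_vector))
    warning(sprintf(
      "ill-conditioned miRNA correlation matrix (condition number %.3g); C clipped",
      max(sv$d) / min(sv$d[pos])))
    C2 <- min(max(C2, 0), 1)
  }
  sqrt(min(max(C2, 0), 1))
}

#' Per-gene multiple correlation with a miRNA panel
#'
#' Computes [multiple_correlation()] for every gene against the same panel of
#' miRNAs, sharing one inverse of the miRNA correlation matrix.
#'
#' @param gene_expr,mirna_expr feature x sample matrices over the same
#'   samples.
#' @return named numeric vector of C values (NA for constant genes).
#' @export
gene_cmc <- function(gene_expr, mirna_expr) {
  keep <- apply(gene_expr, 1, stats::sd) > 0
  cmat <- stats::cor(t(gene_expr[keep, , drop = FALSE]), t(mirna_expr))
  R <- stats::cor(t(mirna_expr))
  RI <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(RI)) {
    sv <- svd(R)
    pos <- sv$d > max(sv$d) * 1e-12
    RI <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    warning("singular miRNA correlation matrix; using pseudo-inverse")
  }
  C2 <- rowSums((cmat %*% RI) * cmat)
  C2 <- pmin(pmax(C2, 0), 1)
  out <- stats::setNames(rep(NA_real_, nrow(gene_expr)), rownames(gene_expr))
  out[rownames(cmat)] <- sqrt(C2)
  out
}

#' Background percentile of multiple-correlation coefficients
#'
#' For each gene of interest, the fraction of background genes with strictly
#' smaller C; reports the genes at or above the 95th percentile and the
#' strict-tail hypergeometric enrichment of that count (successes = the floor
#' of 5% of the background).
#'
#' @param target_cmc named numeric vector of C values for the genes of
#'   interest.
#' @param background_cmc numeric vector of background C values (the full gene
#'   universe; may include the targets).
#' @param top_fraction the "top" definition (default 0.05).
#' @return list with `percentile` (named vector), `top` (logical), `n_top`,
#'   `enrichment_p`.
#' @export
cmc_percentile <- function(target_cmc, background_cmc, top_fraction = 0.05) {
  background_cmc <- background_cmc[!is.na(background_cmc)]
  if (!length(background_cmc)) stop("empty background")
  pct <- vapply(target_cmc, function(C)
    if (is.na(C)) NA_real_ else mean(background_cmc < C), 0)
  top <- !is.na(pct) & pct >= 1 - top_fraction
  N <- length(background_cmc)
  K <- floor(top_fraction * N)
  n <- sum(!is.na(pct))
  # strict upper tail; phyper handles counts beyond K (possible when the
  # targets are not themselves part of the background) by returning 0
  list(percentile = pct, top = top, n_top = sum(top),
       enrichment_p = stats::phyper(sum(top), K, N - K, n, lower.tail = FALSE))
}
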