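#' Construct an expression matrix with tumor/normal labels
#'
#' Light container used throughout the package: a numeric feature x sample
#' matrix plus a class label per sample.  Values are assumed to be on the log
#' scale (log2 microarray summaries or log-transformed counts).
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_class character vector of "tumor"/"normal", either named by
#'   sample id or in column order.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values` and `sample_class` (named character vector).
#' @examples
#' m <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' em <- expression_matrix(m, c("tumor", "tumor", "normal", "normal"))
#' @export
expression_matrix <- function(values, sample_class) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (is.null(names(sample_class))) {
    if (length(sample_class) != ncol(values))
      stop("`sample_class` length does not match the number of samples")
    names(sample_class) <- colnames(values)
  }
  sample_class <- sample_class[colnames(values)]
  if (anyNA(sample_class))
    stop("`sample_class` is missing for some samples")
  if (!all(sample_class %in% c("tumor", "normal")))
    stop("sample classes must be 'tumor' or 'normal'")
  if (!any(sample_class == "tumor"))
    stop("at least one tumor sample is required")
  structure(list(values = values, sample_class = sample_class),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_class == "tumor"), sum(x$sample_class == "normal")))
  invisible(x)
}

# internal accessors
.em_tumors  <- function(em) em$values[, em$sample_class == "tumor", drop = FALSE]
.em_normals <- function(em) em$values[, em$sample_class == "normal", drop = FALSE]

#' Construct a probe-level CNA call dataset
#'
#' One cohort's discretized copy number data: probe genomic intervals (0-based
#' half-open coordinates) and a probe x sample matrix of calls in
#' \{-1 (loss), 0 (neutral), +1 (gain)\}, with `NA` marking missing cells.
#'
#' @param probes data.frame with columns `chrom`, `start`, `end` and optionally
#'   `id`; coordinates 0-based half-open.
#' @param calls integer/numeric matrix, `nrow(probes)` rows, one column per
#'   sample (colnames = sample ids); values in \{-1, 0, 1, NA\}.
#' @return object of class `probe_call_dataset`.
#' @export
probe_call_dataset <- function(probes, calls) {
  stopifnot(is.data.frame(probes),
            all(c("chrom", "start", "end") %in% names(probes)))
  if (!is.matrix(calls) || nrow(calls) != nrow(probes))
    stop("`calls` must be a matrix with one row per probe")
  if (is.null(colnames(calls)))
    stop("`calls` must have sample ids as colnames")
  bad <- !(calls %in% c(-1, 0, 1) | is.na(calls))
  if (any(bad))
    stop("calls must be -1, 0, +1 or NA")
  if (any(probes$start >= probes$end))
    stop("probe intervals must satisfy start < end")
  structure(list(probes = probes, sample_ids = colnames(calls), calls = calls),
            class = "probe_call_dataset")
}

#' @export
print.probe_call_dataset <- function(x, ...) {
  cat(sprintf("<probe_call_dataset> %d probes x %d samples on %s\n",
              nrow(x$probes), length(x$sample_ids),
              paste(unique(x$probes$chrom), collapse = ",")))
  invisible(x)
}

#' Construct a ranked study (one up-list and one down-list)
#'
#' Carrier for one study's ranked differential-expression result: two ordered
#' id vectors, best first.  `measured`, when known, is the full set of features
#' the study could have reported; features measured but absent from a list are
#' treated as worst-ranked during aggregation, features never measured are
#' excluded from it.  For published truncated lists (typical for miRNA
#' studies) `measured` is unknown and left `NULL`.
#'
#' @param up,down character vectors of feature ids, best rank first.
#' @param universe_size number of features eligible in the source; defaults to
#'   `length(measured)` when `measured` is given, otherwise `NA` (resolved at
#'   aggregation time from the union of all studies).
#' @param measured character vector of all measured feature ids, or `NULL`.
#' @return object of class `ranked_study`.
#' @export
ranked_study <- function(up, down, universe_size = NULL, measured = NULL) {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up)) stop("duplicate id in the up list")
  if (anyDuplicated(down)) stop("duplicate id in the down list")
  if (!is.null(measured)) {
    measured <- as.character(measured)
    if (!all(c(up, down) %in% measured))
      stop("listed features missing from `measured`")
    if (is.null(universe_size)) universe_size <- length(measured)
  }
  if (is.null(universe_size)) universe_size <- NA_integer_
  if (!is.na(universe_size) &&
      (length(up) > universe_size || length(down) > universe_size))
    stop("list longer than its universe")
  structure(list(up = up, down = down,
                 universe_size = as.integer(universe_size),
                 measured = measured),
            class = "ranked_study")
}

#' @export
print.ranked_study <- function(x, ...) {
  cat(sprintf("<ranked_study> %d up, %d down (universe %s)\n",
              length(x$up), length(x$down),
              ifelse(is.na(x$universe_size), "unset", x$universe_size)))
  invisible(x)
}

#' Analysis thresholds for sample-wise paradox validation
#'
#' Bundles the cutoffs used when counting per-sample co-occurrence of
#' deregulation and copy-number change: a standard-score cutoff on expression
#' (default 1.647, the convention adopted throughout), a log2 copy-number
#' cutoff (default 0.2), the significance level for the randomization
#' validation (default 1e-4) and for the gene meta-analysis (default 0.01).
#'
#' @param z_cut positive expression z-score cutoff.
#' @param cna_cut positive log2 copy-number cutoff.
#' @param validation_alpha significance level of the randomization test.
#' @param gene_alpha significance level of the gene meta-analysis.
#' @return a list of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(z_cut = 1.647, cna_cut = 0.2,
                                validation_alpha = 1e-4, gene_alpha = 0.01) {
  stopifnot(z_cut > 0, cna_cut > 0,
            validation_alpha > 0, validation_alpha < 1,
            gene_alpha > 0, gene_alpha < 1)
  structure(list(z_cut = z_cut, cna_cut = cna_cut,
                 validation_alpha = validation_alpha, gene_alpha = gene_alpha),
            class = "analysis_thresholds")
}

# run `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# derive k reproducible sub-seeds from one master seed
.derive_seeds <- function(seed, labels) {
  s <- .with_seed(seed, sample.int(2147483646L, length(labels)))
  stats::setNames(as.integer(s), labels)
}
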