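# Shared fixture builders.  Everything is generated in code at test time.

# a small expression matrix with a known tumor-minus-normal shift per feature
make_em <- function(shifts, n_tumor = 6, n_normal = 4, sd = 0.2, seed = 42) {
  withr::with_seed(seed, {
    g <- length(shifts)
    vals <- matrix(rnorm(g * (n_tumor + n_normal), 0, sd), g)
    vals[, seq_len(n_tumor)] <- vals[, seq_len(n_tumor)] + shifts
    dimnames(vals) <- list(names(shifts),
                           sprintf("s%02d", seq_len(n_tumor + n_normal)))
    expression_matrix(vals, c(rep("tumor", n_tumor), rep("normal", n_normal)))
  })
}

# a fast small-scale simulation configuration; ... overrides any default
small_config <- function(seed = 7, ...) {
  args <- list(n_genes = 300, n_mirnas = 20, n_deregulated_mirnas = 6,
               n_cna_datasets = 2, n_expr_datasets = 2,
               samples_per_dataset = 30, normals_per_dataset = 10,
               n_chromosomes = 2, aberrant_region_count = 4,
               n_paradox_genes = 12, probe_length = 5e6,
               decoy_targets_per_mirna = 8, seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

small_pipeline_config <- function(seed = 7, ...) {
  pipeline_config(sim = small_config(), n_perm = 200, n_rand = 500,
                  n_null = 200, seed = seed, ...)
}

# probe call dataset from a compact spec: probes as data.frame, calls matrix
make_pcd <- function(chrom, start, end, calls) {
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(start))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("s%d", seq_len(ncol(calls)))
  probe_call_dataset(data.frame(chrom = chrom, start = start, end = end,
                                stringsAsFactors = FALSE), calls)
}

# exhaustive oracle for the order-statistic probability P(at least k of n
# i.i.d. uniforms <= t), enumerating all 2^n inclusion patterns (no binomial
# shortcut, independent of the implementation under test)
enum_at_least <- function(k, n, t) {
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), n))
  tot <- 0
  for (i in seq_len(nrow(patterns))) {
    inc <- unlist(patterns[i, ])
    if (sum(inc) >= k) tot <- tot + prod(ifelse(inc, t, 1 - t))
  }
  tot
}

# oracle rho: min over k of the enumerated order-statistic probabilities
enum_rho <- function(r) {
  r <- sort(r)
  n <- length(r)
  min(vapply(seq_len(n), function(k) enum_at_least(k, n, r[k]), 0))
}

expect_setequal_chr <- function(a, b) expect_setequal(as.character(a),
                                                      as.character(b))
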