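test_that("genes map to regions by overlap, larger overlap winning", {
  genes <- data.frame(chrom = "chr1",
                      start = c(100, 1000, 140, 149),
                      end = c(200, 1100, 210, 151),
                      id = c("in_gain", "nowhere", "both", "tie"),
                      stringsAsFactors = FALSE)
  regions <- data.frame(chrom = "chr1",
                        start = c(150, 140, 151),
                        end = c(300, 150, 153),
                        direction = c(1L, -1L, -1L),
                        stringsAsFactors = FALSE)
  # in_gain: gain overlap 50 vs loss overlaps 10 + 2 -> gain
  # both: gain overlap 60 vs loss overlaps 10 + 2 -> gain
  # tie: 1 base in the gain region, 1 base in a loss region -> unassigned
  expect_message(map <- assign_genes_to_regions(genes, regions), "equally")
  expect_equal(unname(map[c("in_gain", "both")]), c(1L, 1L))
  expect_true(is.na(map["nowhere"]))
  expect_true(is.na(map["tie"]))
  # no regions at all
  expect_true(all(is.na(assign_genes_to_regions(genes, regions[0, ]))))
})

test_that("association chi-square matches the closed form on a perfect table", {
  de <- setNames(c(rep(1L, 50), rep(-1L, 50)), sprintf("g%03d", 1:100))
  region <- setNames(c(rep(1L, 50), rep(-1L, 50)), sprintf("g%03d", 1:100))
  res <- association_chi_square(de, region)
  expect_equal(res$chi2, 100, tolerance = 1e-10)  # chi2 = N for a perfect 2x2
  expect_lt(res$p, 1.6e-23)

  balanced_region <- setNames(rep(c(1L, -1L), 50), names(de))
  res2 <- association_chi_square(de, balanced_region)
  expect_equal(res2$chi2, 0, tolerance = 1e-10)
  expect_equal(res2$p, 1)

  all_gain <- setNames(rep(1L, 100), names(de))
  expect_error(association_chi_square(de, all_gain), "zero marginal")
  expect_error(association_chi_square(de["g001"], setNames(NA_integer_, "g001")),
               "no DE gene")
})

test_that("paradox classification is the direction product, and flips with regions", {
  de <- c(a = -1L, b = 1L, c = -1L, d = 1L)
  region <- c(a = 1L, b = 1L, c = NA_integer_, d = -1L)
  rec <- identify_paradoxical(de, region)
  expect_setequal_chr(rec$gene, c("a", "b", "d"))     # c has no region
  expect_equal(rec$is_paradoxical[rec$gene == "a"], TRUE)   # down in gain
  expect_equal(rec$is_paradoxical[rec$gene == "b"], FALSE)  # up in gain
  expect_equal(rec$is_paradoxical[rec$gene == "d"], TRUE)   # up in loss
  # involution: flipping all region directions negates every flag
  rec2 <- identify_paradoxical(de, -region)
  expect_equal(rec2$is_paradoxical, !rec$is_paradoxical)
})

test_that("z-scores standardize against the normal samples", {
  vals <- rbind(g1 = c(1, 3, 0, 0, 2, 2),
                g2 = c(5, 5, 5, 5, 5, 5))
  colnames(vals) <- sprintf("s%d", 1:6)
  em <- expression_matrix(vals, c("tumor", "tumor", rep("normal", 4)))
  expect_message(z <- zscore_expression(em), "constant reference")
  # normals of g1: {0,0,2,2}, mean 1, sd 1.1547
  expect_equal(z["g1", "s1"], 0, tolerance = 1e-4)
  expect_equal(z["g1", "s2"], 1.732, tolerance = 1e-3)
  expect_true(all(is.na(z["g2", ])))
  one_normal <- expression_matrix(vals[, 1:3],
                                  c("tumor", "tumor", "normal"))
  expect_error(zscore_expression(one_normal), "at least 2")
})

test_that("paradoxical and regular co-occurrence frequencies count events", {
  th <- analysis_thresholds()
  # down-regulated gene in a gain region: paradox = dereg & gain
  z <- matrix(c(-2, -2, -2, -2, -2, -1, 0, 1, -2, -2), 1,
              dimnames = list("g", sprintf("s%d", 1:10)))
  cna <- matrix(c(0.5, 0.5, 0.5, 0.3, 0, 0.5, 0.5, 0.5, -0.5, 0), 1,
                dimnames = list("g", sprintf("s%d", 1:10)))
  rec <- data.frame(gene = "g", de_direction = -1L, region_direction = 1L,
                    is_paradoxical = TRUE, stringsAsFactors = FALSE)
  out <- sample_paradox_frequencies(z, cna, rec, th)
  expect_equal(out$freq_paradoxical, 0.4)  # s1-s4 deregulated & gained
  expect_equal(out$freq_regular, 0.1)      # s9 deregulated & lost
  expect_equal(out$freq_down, 0.7)
  expect_equal(out$freq_gain, 0.7)         # 0.3 and 0.5 both exceed 0.2
  expect_equal(out$freq_loss, 0.1)
  expect_equal(out$n_informative, 10L)
  # z inside the cutoff never counts, whatever the CNA
  z2 <- z; z2[] <- -1.0
  out2 <- sample_paradox_frequencies(z2, cna, rec, th)
  expect_equal(out2$freq_paradoxical, 0)
  expect_true(out$freq_paradoxical + out$freq_regular <= 1)
})

test_that("the randomization null matches exhaustive permutation on a toy", {
  # 5 samples: 2 deregulated; categories: 2 opposite, 1 same, 2 none.
  # Under cna-label permutation the deregulated pair receives each of the
  # C(5,2) = 10 category subsets equally often; enumerate S = n_opp - n_same.
  th <- analysis_thresholds(validation_alpha = 0.05)
  zv <- c(-3, -3, 0, 0, 0)          # de_direction -1: s1, s2 deregulated
  cv <- c(0.5, 0.5, -0.5, 0, 0)     # opp = gains (2), same = losses (1)
  cats <- c(1, 1, -1, 0, 0)         # opp = +1, same = -1
  pairs <- utils::combn(5, 2)
  S_exhaustive <- apply(pairs, 2, function(ix) sum(cats[ix]))
  s_obs <- 2   # both deregulated samples sit on gains
  p_exact <- mean(S_exhaustive >= s_obs)  # = 1/10
  n_rand <- 4000
  v <- validate_gene_randomization(zv, cv, -1L, th, n_rand = n_rand, seed = 3)
  mc_sd <- sqrt(p_exact * (1 - p_exact) / n_rand)
  expect_lt(abs(v$p - p_exact), 3 * mc_sd + 2 / n_rand)
  expect_equal(v$statistic, 2 / 5)
})

test_that("perfect coupling attains the minimal randomization p", {
  n <- 200
  zv <- c(rep(-3, 50), rep(0, 150))
  cv <- c(rep(0.5, 50), rep(0, 150))  # every deregulated sample paradoxical
  v <- validate_gene_randomization(zv, cv, -1L, analysis_thresholds(),
                                   n_rand = 999, seed = 5)
  expect_equal(v$p, 1 / 1000)
  expect_false(v$validated)  # p floor 1e-3 cannot undercut alpha 1e-4
  v2 <- validate_gene_randomization(zv, cv, -1L,
                                    analysis_thresholds(validation_alpha = 0.01),
                                    n_rand = 999, seed = 5)
  expect_true(v2$validated)
})

test_that("an excess of regular events blocks validation regardless of p", {
  zv <- c(rep(-3, 50), rep(0, 150))
  cv <- c(rep(-0.5, 50), rep(0.5, 150))  # deregulation co-occurs with loss
  v <- validate_gene_randomization(zv, cv, -1L,
                                   analysis_thresholds(validation_alpha = 0.5),
                                   n_rand = 499, seed = 7)
  expect_lt(v$freq_paradoxical, v$freq_regular)
  expect_false(v$validated)
  expect_error(validate_gene_randomization(zv, cv, -1L, n_rand = 0), "n_rand")
})
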