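test_that("generators are deterministic given the seed", {
  cfg <- small_config(seed = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cna[[1]]$calls, b$cna[[1]]$calls)
  expect_identical(a$cohorts[[1]]$expr$values, b$cohorts[[1]]$expr$values)
  expect_identical(lapply(a$mirna_rankings, `[[`, "up"),
                   lapply(b$mirna_rankings, `[[`, "up"))
  expect_identical(a$truth$table, b$truth$table)
  # a different seed changes the data
  c <- simulate_cohort(small_config(seed = 4))
  expect_false(identical(a$cohorts[[1]]$expr$values,
                         c$cohorts[[1]]$expr$values))
})

test_that("zero aberration and background rates give all-neutral calls", {
  cfg <- small_config(seed = 5, aberration_frequency = 0, background_rate = 0,
                      n_paradox_genes = 0)
  cna <- simulate_cna_datasets(cfg)
  for (ds in cna$datasets) expect_true(all(ds$calls == 0))
})

test_that("planted region call frequency is binomially consistent", {
  cfg <- simulation_config(n_genes = 50, n_mirnas = 10,
                           n_deregulated_mirnas = 2, n_cna_datasets = 1,
                           n_expr_datasets = 1, samples_per_dataset = 200,
                           normals_per_dataset = 5, n_chromosomes = 1,
                           aberrant_region_count = 1,
                           aberration_frequency = 0.4, background_rate = 0,
                           n_paradox_genes = 0, seed = 11)
  cna <- simulate_cna_datasets(cfg)
  ds <- cna$datasets[[1]]
  r <- cna$regions[1, ]
  inside <- ds$probes$start < r$end & ds$probes$end > r$start
  expect_equal(r$direction, 1L)  # first planted region is a gain
  freq <- rowMeans(ds$calls[inside, , drop = FALSE] == 1)
  bound <- 3 * sqrt(0.4 * 0.6 / 200)
  expect_true(all(abs(freq - 0.4) <= bound))
})

test_that("planted paradox genes invert their region's direction by >= 2 noise SDs", {
  cohort <- simulate_cohort(small_config(seed = 9))
  truth <- cohort$truth
  for (co in cohort$cohorts) {
    em <- co$expr
    pg <- intersect(truth$paradox_gene_ids, rownames(em$values))
    dm <- rowMeans(em$values[pg, em$sample_class == "tumor", drop = FALSE]) -
      rowMeans(em$values[pg, em$sample_class == "normal", drop = FALSE])
    rd <- truth$gene_region_direction[pg]
    expect_true(all(sign(dm) == -rd))
    # enforced magnitude, with sampling slack (SE of the mean difference)
    expect_true(mean(abs(dm) > 2 * 0.5 - 0.3) > 0.9)
  }
})

test_that("dosage-only model shifts region genes with their region", {
  cfg <- simulation_config(n_genes = 800, n_mirnas = 10,
                           n_deregulated_mirnas = 2, n_cna_datasets = 1,
                           n_expr_datasets = 1, samples_per_dataset = 80,
                           normals_per_dataset = 30, n_chromosomes = 2,
                           aberrant_region_count = 4,
                           aberration_frequency = 0.45,
                           dosage_effect = 0.5, mirna_repression = 0,
                           decoy_coupling = 0, n_paradox_genes = 0,
                           noise_sd = 0.3, seed = 13)
  cohort <- simulate_cohort(cfg)
  em <- cohort$cohorts[[1]]$expr
  genes <- cohort$genes
  inreg <- genes$id[genes$region_direction != 0]
  inreg <- intersect(inreg, rownames(em$values))
  dm <- rowMeans(em$values[inreg, em$sample_class == "tumor", drop = FALSE]) -
    rowMeans(em$values[inreg, em$sample_class == "normal", drop = FALSE])
  rd <- genes$region_direction[match(inreg, genes$id)]
  expect_gte(mean(sign(dm) == rd), 0.95)
})

test_that("the noiseless dosage limit reproduces the dosage effect exactly", {
  cfg <- simulation_config(n_genes = 60, n_mirnas = 4,
                           n_deregulated_mirnas = 0, n_cna_datasets = 1,
                           n_expr_datasets = 1, samples_per_dataset = 10,
                           normals_per_dataset = 5, n_chromosomes = 1,
                           aberrant_region_count = 1, region_length = 4e7,
                           aberration_frequency = 1, background_rate = 0,
                           dosage_effect = 1, mirna_repression = 0,
                           decoy_coupling = 0, noise_sd = 1e-9,
                           mirna_noise_sd = 0, n_paradox_genes = 0,
                           gene_dropout = 0, seed = 17)
  cohort <- simulate_cohort(cfg)
  em <- cohort$cohorts[[1]]$expr
  genes <- cohort$genes
  g <- genes$id[genes$region_direction == 1L][1]
  dm <- mean(em$values[g, em$sample_class == "tumor"]) -
    mean(em$values[g, em$sample_class == "normal"])
  expect_equal(dm, 1, tolerance = 1e-6)
})

test_that("perfect-detection study lists report exactly the planted miRNAs", {
  cfg <- small_config(seed = 19, detection_rate = 1, fp_mean = 0)
  reg <- simulate_regulatory_truth(cfg)
  rankings <- simulate_mirna_study_rankings(cfg, reg)
  up <- names(reg$deregulated)[reg$deregulated == 1L]
  down <- names(reg$deregulated)[reg$deregulated == -1L]
  for (st in rankings) {
    expect_setequal_chr(st$up, up)
    expect_setequal_chr(st$down, down)
  }
})

test_that("planted miRNAs appear in most studies at the default detection rate", {
  hits <- unlist(lapply(1:12, function(s) {
    cfg <- small_config(seed = 100 + s)
    reg <- simulate_regulatory_truth(cfg)
    rankings <- simulate_mirna_study_rankings(cfg, reg)
    vapply(names(reg$deregulated), function(m)
      sum(vapply(rankings, function(st) m %in% c(st$up, st$down), TRUE)), 0)
  }))
  # binomial(9, 0.8): P(>= 5 appearances) ~ 0.98
  expect_gte(mean(hits >= 5), 0.94)
})

test_that("planted truth is internally consistent", {
  cohort <- simulate_cohort(small_config(seed = 23))
  truth <- cohort$truth
  pg <- truth$paradox_gene_ids
  expect_true(all(truth$de_direction[pg] *
                    truth$gene_region_direction[pg] == -1))
  # every paradox gene has a regulator deregulated with its region
  edges <- truth$regulator_edges
  expect_true(all(pg %in% edges$gene))
  md <- truth$deregulated_mirnas[edges$mirna]
  rd <- truth$gene_region_direction[edges$gene]
  expect_true(all(md == rd))
  # truth table mirrors the maps
  tab <- truth$table
  expect_setequal_chr(tab$gene[tab$is_paradox], pg)
})

test_that("oversized requests fail loudly", {
  expect_error(simulation_config(aberrant_region_count = 50,
                                 n_chromosomes = 1, region_length = 1e7),
               "genome capacity")
  expect_error(simulate_cohort(small_config(n_paradox_genes = 290)),
               "exceeds the number of genes inside")
  reg_a <- simulate_regulatory_truth(small_config(seed = 1))
  cna_b <- simulate_cna_datasets(small_config(seed = 2))
  expect_error(simulate_expression(small_config(seed = 1), cna_b, reg_a),
               "inconsistent")
})

test_that("a cohort written to disk reads back consistently", {
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(small_config(seed = 29))
  write_cohort(cohort, dir)
  genes <- read_bed(file.path(dir, "genes.bed"))
  expect_equal(nrow(genes), 300L)
  ds <- read_seg_calls(file.path(dir, "cna1.seg.tsv"))
  expect_equal(ds$calls[, colnames(cohort$cna[[1]]$calls)],
               cohort$cna[[1]]$calls)
  tr <- read_truth(file.path(dir, "truth.tsv"))
  expect_setequal_chr(tr$gene[tr$is_paradox], cohort$truth$paradox_gene_ids)
  st <- read_ranked_list(file.path(dir, "mirna_study1.tsv"))
  expect_equal(st$up, cohort$mirna_rankings[[1]]$up)
})

test_that("log-ratio mode recovers calls through the threshold caller", {
  cohort <- simulate_cna_datasets(small_config(seed = 31))
  ds <- cohort$datasets[[1]]
  lr <- simulate_log_ratios(ds, sd = 0.05, seed = 1)
  called <- call_from_log_ratios(lr$values)
  expect_gte(mean(called == ds$calls), 0.99)
})
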