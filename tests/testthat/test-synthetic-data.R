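test_that("config validation rejects bad fields by name", {
  expect_error(sim_config(n_genes = -1), "n_genes")
  expect_error(sim_config(frac_strain_de = 1.2), "frac_strain_de")
  expect_error(sim_config(frac_off = 0.5, frac_strain_de = 0.3), "frac_off")
  expect_error(sim_config(strains = character(0)), "strains")
  expect_error(sim_config(reference_strain = "nope"), "reference_strain")
  expect_error(sim_config(control_treatment = "nope"), "control_treatment")
  expect_error(sim_config(effect_size_log2 = 0), "effect_size_log2")
})

test_that("degenerate and null configurations behave as contracted", {
  empty <- simulate_experiment(sim_config(n_genes = 0))
  expect_equal(nrow(empty$counts), 0)
  expect_length(empty$truth$mu, 0)

  cfg <- sim_config(n_genes = 50, frac_strain_de = 0, frac_off = 0,
                    frac_interaction = 0, frac_treatment_de = 0, seed = 3)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$beta1 == 0))
  expect_true(all(sim$truth$beta2 == 0))
  expect_true(all(sim$truth$beta3 == 0))
  expect_false(any(sim$truth$off))
})

test_that("identical configs give bit-identical output", {
  cfg <- sim_config(n_genes = 40, seed = 9)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  expect_identical(simulate_coverage(simulate_annotation(cfg), a$truth, cfg),
                   simulate_coverage(simulate_annotation(cfg), b$truth, cfg))
})

test_that("sample means match planted NB moments (4-SE check)", {
  cfg <- sim_config(n_genes = 2000, dispersion_alpha = 0.05,
                    frac_strain_de = 0, frac_off = 0,
                    frac_interaction = 0, frac_treatment_de = 0, seed = 7)
  sim <- simulate_experiment(cfg)
  ref <- sim$design$strain == cfg$reference_strain
  s_j <- sim$truth$size_factors[ref]
  y <- sim$counts[, ref, drop = FALSE]
  mu <- sim$truth$mu
  expected <- mean(s_j) * mu
  mu_mat <- outer(mu, s_j)
  var_mean <- rowSums(mu_mat + 0.05 * mu_mat^2) / sum(ref)^2
  ok <- abs(rowMeans(y) - expected) <= 4 * sqrt(var_mean)
  expect_gte(mean(ok), 0.99)
})

test_that("off genes are structural zeros in their silent strains", {
  cfg <- sim_config(n_genes = 400, frac_strain_de = 0.4, frac_off = 0.05,
                    seed = 13)
  sim <- simulate_experiment(cfg)
  expect_gt(length(sim$truth$off_genes), 0)
  for (g in sim$truth$off_genes) {
    silent <- colnames(sim$truth$off)[sim$truth$off[g, ]]
    expect_true(length(silent) >= 1 && length(silent) < length(cfg$strains))
    cols <- sim$design$strain %in% silent
    expect_true(all(sim$counts[g, cols] == 0))
  }
  # off genes are a subset of strain-DE genes
  expect_true(all(sim$truth$off_genes %in% sim$truth$de_genes))
})

test_that("annotation respects bounds, overlap knob, and GTF convention", {
  cfg1 <- sim_config(n_genes = 1, seed = 2)
  ann1 <- simulate_annotation(cfg1, overlap_frac = 0, max_exons = 1)
  expect_equal(nrow(ann1), 1)
  expect_true(all(ann1$start >= 1 & ann1$start <= ann1$end))

  cfg <- sim_config(n_genes = 30, seed = 2)
  ann <- simulate_annotation(cfg, overlap_frac = 1)
  expect_true(all(table(ann$gene_id) >= 2))
  # every gene has at least one duplicated (shared) exon interval
  shared <- vapply(split(ann, ann$gene_id), function(d) {
    anyDuplicated(paste(d$start, d$end)) > 0
  }, logical(1))
  expect_true(all(shared))
  expect_true(all(ann$end <= attr(ann, "chrom_lengths")[ann$chrom]))
})

test_that("coverage construction plants classes faithfully", {
  cfg <- sim_config(n_genes = 300, frac_missing_cov = 0.05,
                    frac_low_cov = 0.05, coverage_noise_sd = 0, seed = 5)
  sim <- simulate_experiment(cfg)
  ann <- simulate_annotation(cfg)
  dep <- simulate_coverage(ann, sim$truth, cfg)
  expect_named(dep, cfg$strains)
  merged <- merge_exons(ann)
  for (s in cfg$strains) {
    raw <- gene_coverage(merged, dep[[s]])
    planted <- sim$truth$coverage_class[names(raw), s]
    expect_true(all(raw[planted == "missing"] == 0))
    expect_true(all(raw[planted != "missing"] > 0))
  }
  # a truth gene absent from the annotation is an error naming it
  ann2 <- ann[ann$gene_id != "gene00007", ]
  expect_error(simulate_coverage(ann2, sim$truth, cfg), "gene00007")
})

test_that("zero-noise coverage round-trips through classification", {
  cfg <- sim_config(n_genes = 1000, frac_missing_cov = 0.02,
                    frac_low_cov = 0.03, coverage_noise_sd = 0, seed = 3)
  sim <- simulate_experiment(cfg)
  ann <- simulate_annotation(cfg)
  dep <- simulate_coverage(ann, sim$truth, cfg)
  merged <- merge_exons(ann)
  tbl <- classify_coverage(lapply(dep, function(d) gene_coverage(merged, d)))
  got <- tbl$cov_class[order(tbl$strain, tbl$gene_id)]
  want <- as.vector(sim$truth$coverage_class[
    order(rownames(sim$truth$coverage_class)),
    order(colnames(sim$truth$coverage_class))])
  tbl2 <- tbl[order(tbl$strain, tbl$gene_id), ]
  key <- cbind(tbl2$gene_id, tbl2$strain)
  expect_identical(unname(tbl2$cov_class),
                   unname(sim$truth$coverage_class[key]))
})
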