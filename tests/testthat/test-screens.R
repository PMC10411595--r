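# LRT and Wald screens on small simulated designs; dispersions are the
# planted values where the check targets the test statistic itself.

test_that("identical full and reduced models give stat 0, p 1", {
  d <- tiny_design()
  set.seed(2)
  m <- counts_matrix(matrix(rnbinom(30 * nrow(d), mu = 50, size = 10), 30),
                     samples = d$sample)
  res <- lrt_screen(m, d, ~strain, ~strain, sf = rep(1, ncol(m)),
                    alpha = 0.1)
  expect_true(all(res$stat == 0))
  expect_true(all(res$pvalue == 1))
  expect_equal(unique(res$df), 0)
})

test_that("non-nested models are rejected", {
  d <- tiny_design()
  m <- counts_matrix(matrix(5, 4, nrow(d)), samples = d$sample)
  expect_error(lrt_screen(m, d, ~treatment, ~strain, sf = rep(1, ncol(m)),
                          alpha = 0.1), "nested")
})

test_that("LRT results are invariant to sample and gene reordering", {
  d <- tiny_design()
  set.seed(3)
  m <- counts_matrix(matrix(rnbinom(40 * nrow(d), mu = 80, size = 8), 40),
                     samples = d$sample)
  sf <- rep(1, ncol(m))
  names(sf) <- colnames(m)
  r1 <- lrt_screen(m, d, ~strain, ~1, sf = sf, alpha = 0.1)
  perm <- sample(ncol(m))
  r2 <- lrt_screen(m[, perm], d[perm, ], ~strain, ~1, sf = sf[perm],
                   alpha = 0.1)
  expect_equal(r1$stat, r2$stat, tolerance = 1e-6)
  gperm <- sample(nrow(m))
  r3 <- lrt_screen(m[gperm, ], d, ~strain, ~1, sf = sf, alpha = 0.1)
  expect_equal(r3$stat[order(r3$gene_id)], r1$stat[order(r1$gene_id)],
               tolerance = 1e-12)
})

test_that("planted strain effects are detected with high power", {
  cfg <- sim_config(n_genes = 500, baseline_mean_log2 = 9,
                    baseline_sd_log2 = 0.5, frac_strain_de = 0.3,
                    frac_off = 0, frac_interaction = 0,
                    frac_treatment_de = 0, seed = 31)
  sim <- simulate_experiment(cfg)
  filt <- filter_low_counts(sim$counts)
  sf <- size_factors(filt)
  ctrl <- sim$design$treatment == "control"
  res <- lrt_screen(filt[, ctrl], sim$design[ctrl, ], ~strain, ~1,
                    sf = sf[ctrl], alpha = sim$truth$alpha[rownames(filt)])
  planted <- res$gene_id %in% sim$truth$de_genes
  expect_gte(mean(res$padj[planted] < 0.1, na.rm = TRUE), 0.9)
})

test_that("Wald contrast: null, antisymmetry, and knockdown recovery", {
  d <- tiny_design()
  # treatment counts identical to control counts -> FC 0, ns
  block <- matrix(rep(c(30, 45, 60), times = 4), nrow = 1)
  m <- counts_matrix(block[rep(1, 10), ], samples = d$sample)
  wc <- wald_contrast(m, d, "A", "rnai", sf = rep(1, ncol(m)), alpha = 0.05)
  expect_equal(max(abs(wc$lfc_raw)), 0, tolerance = 1e-8)
  expect_true(all(wc$call == "ns"))

  # swapping treatment and control labels negates the raw FC
  set.seed(9)
  m2 <- counts_matrix(matrix(rnbinom(20 * nrow(d), mu = 100, size = 10), 20),
                      samples = d$sample)
  dflip <- sample_design(d$sample, d$strain,
                         ifelse(d$treatment == "ctrl", "rnai", "ctrl"),
                         d$replicate, "A", "ctrl")
  w1 <- wald_contrast(m2, d, "A", "rnai", sf = rep(1, ncol(m2)), alpha = 0.05)
  w2 <- wald_contrast(m2, dflip, "A", "rnai", sf = rep(1, ncol(m2)),
                      alpha = 0.05)
  expect_equal(w1$lfc_raw, -w2$lfc_raw, tolerance = 1e-5)

  expect_error(wald_contrast(m2, d, "A", "nope", sf = rep(1, ncol(m2))),
               "cell")
})

test_that("planted 4-fold knockdowns are called down", {
  cfg <- sim_config(n_genes = 400, baseline_mean_log2 = 10,
                    baseline_sd_log2 = 0.5, dispersion_alpha = 0.05,
                    frac_strain_de = 0, frac_interaction = 0,
                    frac_treatment_de = 0.5, frac_off = 0, seed = 41)
  sim <- simulate_experiment(cfg)
  filt <- filter_low_counts(sim$counts)
  wc <- wald_contrast(filt, sim$design, "N2", "par1",
                      sf = size_factors(filt),
                      alpha = sim$truth$alpha[rownames(filt)])
  dn <- sim$truth$beta2[rownames(filt), "par1"] == -2
  expect_gte(mean(wc$call[dn] == "down"), 0.95)
})

test_that("Wald and LRT p-values agree in rank for a 2-level factor", {
  d <- tiny_design(strains = c("A", "B"), treatments = "ctrl")
  cfgless <- 0.08
  set.seed(17)
  mu <- exp(rnorm(300, log(150), 1))
  shift <- rnorm(300, 0, 0.5)
  m <- sapply(seq_len(nrow(d)), function(j) {
    q <- mu * ifelse(d$strain[j] == "B", exp(shift), 1)
    rnbinom(300, mu = q, size = 1 / cfgless)
  })
  m <- counts_matrix(m, samples = d$sample)
  lrt <- lrt_screen(m, d, ~strain, ~1, sf = rep(1, ncol(m)), alpha = cfgless)
  X <- stats::model.matrix(~strain, as.data.frame(d))
  wp <- apply(m, 1, function(y) {
    f <- fit_nb_glm(y, X, rep(1, ncol(m)), cfgless)
    2 * pnorm(-abs(f$coef_log2[2] / f$se_log2[2]))
  })
  expect_gt(cor(lrt$pvalue, wp, method = "spearman"), 0.99)
})

test_that("strain LRT p-values track DESeq2 on a shared dataset", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(n_genes = 150, baseline_mean_log2 = 8,
                    baseline_sd_log2 = 1, frac_strain_de = 0.3,
                    frac_off = 0, frac_interaction = 0,
                    frac_treatment_de = 0, seed = 23)
  sim <- simulate_experiment(cfg)
  ctrl <- sim$design$treatment == "control"
  m <- filter_low_counts(sim$counts[, ctrl])
  d <- sim$design[ctrl, ]
  mine <- lrt_screen(m, d, ~strain, ~1, sf = size_factors(m))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, S4Vectors::DataFrame(strain = d$strain), ~strain)
  dds <- suppressMessages(DESeq2::DESeq(dds, test = "LRT", reduced = ~1,
                                        quiet = TRUE))
  ref <- DESeq2::results(dds)
  ok <- is.finite(mine$pvalue) & is.finite(ref$pvalue)
  expect_gt(cor(-log10(mine$pvalue[ok] + 1e-300),
                -log10(ref$pvalue[ok] + 1e-300),
                method = "spearman"), 0.95)
})
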