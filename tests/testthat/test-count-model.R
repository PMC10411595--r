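test_that("low-count filter keeps exactly the genes at threshold", {
  m <- counts_matrix(rbind(c(4, 5), c(4, 6), c(0, 0)))
  f <- filter_low_counts(m, 10)
  expect_identical(rownames(f), c("g02"))  # sums 9, 10, 0
  expect_identical(filter_low_counts(m, 0), m)
  allz <- counts_matrix(matrix(0, 3, 2))
  expect_equal(nrow(filter_low_counts(allz)), 0)
})

test_that("size factors follow the median-of-ratios construction", {
  # both genes (2, 8): geometric mean 4, ratios 0.5 and 2
  m <- counts_matrix(rbind(c(2, 8), c(2, 8)))
  expect_equal(unname(size_factors(m)), c(0.5, 2.0))
  # identical samples -> unit factors
  m2 <- counts_matrix(rbind(c(5, 5), c(9, 9)))
  expect_equal(unname(size_factors(m2)), c(1, 1))
  # zero-containing genes are excluded from the reference set
  m3 <- rbind(m, counts_matrix(matrix(c(0, 7), 1), genes = "gz"))
  expect_equal(size_factors(m3), size_factors(m))
  # global rescaling leaves factors unchanged
  expect_equal(size_factors(m * 5), size_factors(m))
  expect_error(size_factors(counts_matrix(rbind(c(0, 3), c(4, 0)))),
               "no gene")
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- counts_matrix(matrix(rnbinom(600, mu = 50, size = 5), 60, 10))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("NB GLM recovers closed-form fits", {
  # single group, equal counts, unit sf: intercept = log2(k)
  y <- rep(12, 6)
  X <- matrix(1, 6, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_nb_glm(y, X, alpha = 0.05)
  expect_equal(unname(f$coef_log2[1]), log2(12), tolerance = 1e-6)
  # two groups at alpha -> 0: coefficient = log2(m2/m1)
  y2 <- c(10, 12, 14, 40, 44, 36)
  X2 <- cbind(1, rep(c(0, 1), each = 3))
  colnames(X2) <- c("(Intercept)", "grp")
  f2 <- fit_nb_glm(y2, X2, alpha = 1e-10)
  expect_equal(unname(f2$coef_log2["grp"]), log2(mean(y2[4:6]) / mean(y2[1:3])),
               tolerance = 1e-6)
  # doubling counts and size factors leaves coefficients unchanged
  f3a <- fit_nb_glm(y2, X2, sf = rep(1, 6), alpha = 0.1)
  f3b <- fit_nb_glm(y2 * 2, X2, sf = rep(2, 6), alpha = 0.1)
  expect_equal(f3a$coef_log2, f3b$coef_log2, tolerance = 1e-4)
  # rank-deficient design errors and names the collinear column
  Xbad <- cbind(X2, dup = X2[, 2])
  expect_error(fit_nb_glm(y2, Xbad, alpha = 0.1), "dup")
  # all-zero gene: guarded degenerate fit
  fz <- fit_nb_glm(rep(0, 6), X2, alpha = 0.1)
  expect_true(fz$degenerate)
  expect_equal(fz$loglik, 0)
})

test_that("dispersion estimation hits the floor and the Poisson limit", {
  d <- tiny_design(r = 5)
  # constant counts in every sample: no overdispersion signal
  m <- counts_matrix(matrix(20, 2, nrow(d)),
                     samples = d$sample)
  est <- estimate_dispersion(m, d, rep(1, nrow(d)), formula = ~1)
  expect_true(all(est$alpha <= 1e-6))
  # Poisson counts: median alpha-hat below 0.01
  set.seed(8)
  mp <- counts_matrix(matrix(rpois(150 * nrow(d), 500), 150),
                      samples = d$sample)
  estp <- estimate_dispersion(mp, d, rep(1, nrow(d)), formula = ~1)
  expect_lt(median(estp$alpha), 0.01)
})

test_that("dispersion estimation recovers a planted alpha", {
  cfg <- sim_config(n_genes = 400, baseline_mean_log2 = log2(500),
                    baseline_sd_log2 = 0, dispersion_alpha = 0.1,
                    frac_strain_de = 0, frac_interaction = 0,
                    frac_treatment_de = 0, frac_off = 0, seed = 21)
  sim <- simulate_experiment(cfg)
  est <- estimate_dispersion(sim$counts, sim$design,
                             size_factors(sim$counts), formula = ~1)
  expect_gte(median(est$alpha), 0.07)
  expect_lte(median(est$alpha), 0.13)
})

test_that("BH adjustment matches hand values and the brute-force oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # filtering off: every gene receives an adjusted p
  p <- runif(30)
  expect_false(anyNA(bh_adjust(p)))
  # filtering on: low-base-mean genes may be dropped, never gain NA p
  adj <- bh_adjust(p, base_means = seq_along(p),
                   independent_filtering = TRUE)
  expect_true(all(is.na(adj) | adj >= p - 1e-12))
})

test_that("fold-change shrinkage is a conjugate posterior mean", {
  # prior sd 0.5, raw 2, se 1 -> 2 * 0.25 / 1.25 = 0.4
  expect_equal(shrink_lfc(2, 1, prior_sd = 0.5)$shrunk, 0.4)
  expect_equal(shrink_lfc(0, 1, prior_sd = 0.7)$shrunk, 0)
  # se -> 0 recovers the raw value; shrinkage never inflates
  expect_equal(shrink_lfc(1, 1e-8, prior_sd = 0.5)$shrunk, 1,
               tolerance = 1e-6)
  set.seed(4)
  raw <- rnorm(200, 0, 1)
  se <- runif(200, 0.1, 2)
  sh <- shrink_lfc(raw, se)
  expect_true(all(abs(sh$shrunk) <= abs(raw) + 1e-12))
  # nonfinite se flagged out
  expect_true(is.na(shrink_lfc(c(1, 2), c(1, NA))$shrunk[2]))
})

test_that("vst PCA separates planted groups and orders variance", {
  d <- tiny_design(r = 5)
  set.seed(6)
  base <- matrix(rnbinom(600 * nrow(d), mu = 100, size = 10), 600)
  grp <- d$strain == "B"
  base[1:500, grp] <- matrix(
    rnbinom(500 * sum(grp), mu = 800, size = 10), 500)
  m <- counts_matrix(base, samples = d$sample)
  p <- vst_pca(m, sf = rep(1, ncol(m)), n_top = 500)
  expect_true(max(p$scores[grp, 1]) < min(p$scores[!grp, 1]) ||
              min(p$scores[grp, 1]) > max(p$scores[!grp, 1]))
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # identical samples -> all scores zero
  mi <- counts_matrix(matrix(7, 20, 4))
  pz <- vst_pca(mi, sf = rep(1, 4), n_top = 10, n_pcs = 2)
  expect_equal(max(abs(pz$scores)), 0)
  expect_error(vst_pca(m[, 1, drop = FALSE], n_top = 5), "2 samples")
  expect_error(vst_pca(m, sf = rep(1, ncol(m)), n_top = 1e5), "n_top")
})
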