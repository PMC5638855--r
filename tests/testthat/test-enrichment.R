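make_counts <- function(mat, genes = sprintf("g%d", seq_len(nrow(mat))),
                        samples = sprintf("s%d", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(genes, samples)
  mat
}

test_that("log-cpm matches its closed form and scale invariance", {
  m <- make_counts(matrix(c(0, 1e6 - 0), 2, 1))
  m[2, 1] <- 1e6
  lc <- log_cpm(m)
  expect_equal(lc[1, 1], log2(0.5 / (1e6 + 1) * 1e6))
  expect_equal(lc[2, 1], log2((1e6 + 0.5) / (1e6 + 1) * 1e6))

  set.seed(5)
  a <- make_counts(matrix(rpois(40, 50), 10, 4))
  doubled <- a * 2
  expect_equal(log_cpm(a, prior_count = 0), log_cpm(doubled, prior_count = 0))
  expect_error(log_cpm(make_counts(matrix(0, 2, 1))),
               class = "periloc_zero_library")
})

test_that("the expression filter keeps genes above threshold in any sample", {
  lcpm <- rbind(g1 = c(0.4, 0.4, 0.4), g2 = c(0.1, 0.6, 0.2),
                g3 = c(0.5, 0.5, 0.5))
  expect_identical(filter_expressed(lcpm), "g2") # 0.5 is not > 0.5
  expect_identical(filter_expressed(lcpm, threshold = 0), c("g1", "g2", "g3"))
})

test_that("a gene with identical Ps and CB replicates is exactly null", {
  counts <- make_counts(matrix(rep(c(100, 200, 150), each = 4), 3, 4,
                               byrow = TRUE))
  info <- tibble::tibble(sample = colnames(counts),
                         fraction = c("Ps", "Ps", "CB", "CB"),
                         condition = "control", replicate = c(1, 2, 1, 2))
  fit <- enrichment_test(counts, info, prior_df = 4, prior_var = 0.01)
  expect_equal(fit$log2fc, rep(0, 3))
  expect_equal(fit$moderated_t, rep(0, 3))
  expect_equal(fit$p_value, rep(1, 3))
})

test_that("the moderated t equals a hand computation under a fixed prior", {
  set.seed(21)
  counts <- make_counts(matrix(rpois(16, 400), 2, 8))
  info <- tibble::tibble(sample = colnames(counts),
                         fraction = rep(c("Ps", "CB"), each = 4),
                         condition = "control", replicate = rep(1:4, 2))
  d0 <- 3; s02 <- 0.02
  fit <- enrichment_test(counts, info, prior_df = d0, prior_var = s02,
                         normalization = "total")
  x <- log_cpm(counts)
  for (g in 1:2) {
    hand <- hand_moderated_t(x[g, 1:4], x[g, 5:8], d0, s02)
    expect_equal(fit$log2fc[g], hand$log2fc)
    expect_equal(fit$moderated_t[g], hand$t)
    expect_equal(fit$p_value[g], hand$p)
  }
})

test_that("prior limits recover the ordinary t-test and the z-like test", {
  set.seed(31)
  counts <- make_counts(matrix(rnbinom(200 * 8, mu = 200, size = 20), 200, 8))
  info <- tibble::tibble(sample = colnames(counts),
                         fraction = rep(c("Ps", "CB"), each = 4),
                         condition = "control", replicate = rep(1:4, 2))
  x <- log_cpm(counts)

  # prior_df = 0: ordinary equal-variance t-test per gene
  plain <- enrichment_test(counts, info, prior_df = 0, prior_var = 1,
                           normalization = "total")
  for (g in c(1, 57, 200)) {
    tt <- t.test(x[g, 1:4], x[g, 5:8], var.equal = TRUE)
    expect_equal(plain$moderated_t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(plain$p_value[g], tt$p.value, tolerance = 1e-10)
  }

  # prior_df = Inf: all genes share the prior variance; normal reference
  s02 <- 0.05
  zfit <- enrichment_test(counts, info, prior_df = Inf, prior_var = s02,
                          normalization = "total")
  g <- 12
  zstat <- (mean(x[g, 1:4]) - mean(x[g, 5:8])) / sqrt(s02 * (1 / 4 + 1 / 4))
  expect_equal(zfit$moderated_t[g], zstat, tolerance = 1e-10)
  expect_equal(zfit$p_value[g], 2 * pnorm(-abs(zstat)), tolerance = 1e-10)
})

test_that("the moderated test agrees with limma given the same prior", {
  skip_if_not_installed("limma")
  sim <- simulate_ps_cb_counts(n_genes = 400, n_enriched = 40,
                               n_dependent = 0, seed = 14)
  info <- sim$sample_info[sim$sample_info$condition == "control", ]
  counts <- sim$counts[, info$sample]
  x <- log_cpm(counts, lib_size = effective_lib_sizes(counts))
  design <- stats::model.matrix(~ 0 + factor(info$fraction, c("CB", "Ps")))
  colnames(design) <- c("CB", "Ps")
  lf <- limma::lmFit(x, design)
  lf <- limma::contrasts.fit(lf, limma::makeContrasts(Ps - CB, levels = design))
  eb <- limma::eBayes(lf)
  fit <- enrichment_test(counts, info, prior_df = eb$df.prior,
                         prior_var = eb$s2.prior)
  expect_equal(fit$log2fc, unname(eb$coefficients[, 1]), tolerance = 1e-9)
  expect_equal(fit$moderated_t, unname(eb$t[, 1]), tolerance = 1e-9)
  expect_equal(fit$p_value, unname(eb$p.value[, 1]), tolerance = 1e-9)
})

test_that("the fitted variance prior is close to limma's empirical Bayes fit", {
  skip_if_not_installed("limma")
  sim <- simulate_ps_cb_counts(n_genes = 1000, n_enriched = 0,
                               n_dependent = 0, seed = 27)
  info <- sim$sample_info[sim$sample_info$condition == "control", ]
  x <- log_cpm(sim$counts[, info$sample],
               lib_size = effective_lib_sizes(sim$counts[, info$sample]))
  design <- stats::model.matrix(~ factor(info$fraction))
  eb <- limma::eBayes(limma::lmFit(x, design))
  fit <- enrichment_test(sim$counts[, info$sample], info)
  g <- glance(fit)
  expect_equal(g$prior_var, eb$s2.prior, tolerance = 0.05)
  expect_equal(g$prior_df, eb$df.prior, tolerance = 0.1)
})

test_that("enrichment calls respect both cutoffs", {
  res <- tibble::tibble(gene = c("a", "b", "c"),
                        log2fc = log2(c(2.5, 2.5, 1.9)),
                        p_value = c(0.01, 0.20, 0.001))
  cls <- classify_ps_enriched(res)
  expect_equal(cls$localization, c("ps_enriched", "non_localized",
                                   "non_localized"))
})

test_that("diff_fc is exactly zero when both conditions share the data", {
  set.seed(61)
  base <- matrix(rpois(40, 300), 10, 4)
  counts <- make_counts(cbind(base, base), samples = sprintf("s%d", 1:8))
  info <- tibble::tibble(
    sample = colnames(counts),
    fraction = rep(c("Ps", "Ps", "CB", "CB"), 2),
    condition = rep(c("control", "perturbed"), each = 4),
    replicate = rep(1:2, 4)
  )
  dd <- diff_fc(counts, info, prior_df = 4, prior_var = 0.01)
  expect_equal(dd$log2_diff_fc, rep(0, 10))
  expect_equal(dd$p_diff, rep(1, 10))
})

test_that("diff_fc equals the hand-computed interaction of group means", {
  # constructed counts: gene 1 loses a 4-fold enrichment, filler gene fixes
  # all library sizes at 1000 so the log-cpm offsets cancel
  cols <- c("c_Ps_1", "c_Ps_2", "c_CB_1", "c_CB_2",
            "p_Ps_1", "p_Ps_2", "p_CB_1", "p_CB_2")
  counts <- make_counts(rbind(c(400, 400, 100, 100, 100, 100, 100, 100),
                              c(600, 600, 900, 900, 900, 900, 900, 900)),
                        samples = cols)
  info <- tibble::tibble(
    sample = cols,
    fraction = rep(c("Ps", "Ps", "CB", "CB"), 2),
    condition = rep(c("control", "perturbed"), each = 4),
    replicate = rep(1:2, 4)
  )
  dd <- diff_fc(counts, info, prior_df = 4, prior_var = 0.01,
                normalization = "total")
  expect_equal(dd$log2_diff_fc[1], -(log2(400.5) - log2(100.5)))

  x <- log_cpm(counts)
  hand <- (mean(x[1, 5:6]) - mean(x[1, 7:8])) -
    (mean(x[1, 1:2]) - mean(x[1, 3:4]))
  expect_equal(dd$log2_diff_fc[1], hand)

  # and the two-condition enrichment fits give the same interaction
  fc_c <- enrichment_test(counts, info, "control", prior_df = 4,
                          prior_var = 0.01, normalization = "total")$log2fc
  fc_p <- enrichment_test(counts, info, "perturbed", prior_df = 4,
                          prior_var = 0.01, normalization = "total")$log2fc
  expect_equal(dd$log2_diff_fc, fc_p - fc_c)
})

test_that("dependence classification applies the one-sided rule", {
  cls <- tibble::tibble(gene = c("a", "b", "c"),
                        log2fc = c(2, 2, 0.5),
                        p_value = c(0.01, 0.01, 0.5),
                        localization = c("ps_enriched", "ps_enriched",
                                         "non_localized"))
  dd <- tibble::tibble(gene = c("a", "b", "c"),
                       log2_diff_fc = c(-2, 0, -3),
                       p_diff = c(0.001, 0.3, 0.0001))
  out <- classify_dependence(cls, dd)
  expect_equal(out$dependence, c("dependent", "independent", "not_applicable"))
  # increased enrichment is never "dependent", however significant
  dd2 <- dd
  dd2$log2_diff_fc <- c(2, 2, 2)
  expect_true(all(classify_dependence(cls, dd2)$dependence !=
                    "dependent"))
})

test_that("insufficient replication is rejected up front", {
  counts <- make_counts(matrix(rpois(6, 100), 2, 3))
  info <- tibble::tibble(sample = colnames(counts),
                         fraction = c("Ps", "CB", "CB"),
                         condition = "control", replicate = c(1, 1, 2))
  expect_error(enrichment_test(counts, info),
               class = "periloc_invalid_design")
})
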