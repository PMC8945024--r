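design3 <- build_design(3)
meth_ids <- design3$sample_id[design3$assay == "METH"]

test_that("probe filtering applies every exclusion rule", {
  v <- matrix(0.5, 5, length(meth_ids), dimnames = list(NULL, meth_ids))
  annot <- data.frame(
    probe_id = sprintf("p%d", 1:5),
    chrom = c("chr1", "chrX", "chr2", "chr3", "chr4"),
    pos = 1:5 * 100L,
    detection_p = c(0, 0, 0.02, 0, 0),
    snp_at_cg = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    cross_reactive = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  b <- beta_matrix(v, annot)
  suppressMessages(f <- filter_probes(b))
  expect_identical(f$annot$probe_id, "p1")
  expect_equal(unname(attr(f, "removed")),
               c(1L, 1L, 1L, 1L))

  # clean matrix passes unchanged, order preserved
  clean <- annot
  clean$chrom <- "chr5"
  clean$detection_p <- 0
  clean$snp_at_cg <- FALSE
  clean$cross_reactive <- FALSE
  bc <- beta_matrix(v, clean)
  suppressMessages(fc <- filter_probes(bc))
  expect_identical(fc$values, bc$values)
  expect_identical(fc$annot, bc$annot)

  bad <- annot
  bad$detection_p <- 1
  expect_error(suppressMessages(filter_probes(beta_matrix(v, bad))),
               "every probe")
})

test_that("beta/M transform is exact and invertible", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  set.seed(1)
  b <- runif(1000, 0.001, 0.999)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  expect_true(all(diff(beta_to_m(seq(0.01, 0.99, by = 0.01))) > 0))
})

test_that("per-probe fits match per-probe lm() on random data", {
  set.seed(11)
  v <- matrix(runif(100 * 6, 0.2, 0.8), 100, 6)
  colnames(v) <- c(design3$sample_id[design3$assay == "METH" &
                                       design3$treatment == "ZERO_H"],
                   design3$sample_id[design3$assay == "METH" &
                                       design3$treatment == "RPMI"])
  b <- tiny_beta(v)
  fit <- fit_probe_models(b, design3, comparison("RPMI", "ZERO_H", 24))
  group <- c(0, 0, 0, 1, 1, 1)
  donor <- factor(rep(c("D1", "D2", "D3"), 2))
  for (i in sample(100, 25)) {
    y <- beta_to_m(v[i, ])
    lmfit <- lm(y ~ group + donor)
    sm <- summary(lmfit)$coefficients["group", ]
    expect_equal(fit$effect[i], unname(sm["Estimate"]), tolerance = 1e-8)
    expect_equal(fit$t[i], unname(sm["t value"]), tolerance = 1e-8)
    expect_equal(fit$p[i], unname(sm["Pr(>|t|)"]), tolerance = 1e-8)
  }
  # delta-beta is always the difference of group means on the beta scale
  expect_equal(fit$delta_beta, rowMeans(v[, 4:6]) - rowMeans(v[, 1:3]))
})

test_that("paired-design group estimate matches the closed form", {
  # per donor: reference {.1,.2,.3}, target {.2,.3,.4}; estimate 0.1
  v <- rbind(c(0.1, 0.2, 0.3, 0.2, 0.3, 0.4))
  colnames(v) <- c(design3$sample_id[design3$assay == "METH" &
                                       design3$treatment == "ZERO_H"],
                   design3$sample_id[design3$assay == "METH" &
                                       design3$treatment == "RPMI"])
  b <- tiny_beta(v)
  fit <- fit_probe_models(b, design3, comparison("RPMI", "ZERO_H", 24),
                          scale = "beta")
  expect_equal(fit$effect[1], 0.1, tolerance = 1e-12)
})

test_that("identical groups give the null identity and constants give p = 1", {
  v <- rbind(c(0.3, 0.4, 0.5, 0.3, 0.4, 0.5), # same per-donor values
             rep(0.5, 6))                      # constant probe
  colnames(v) <- c(design3$sample_id[design3$assay == "METH" &
                                       design3$treatment == "ZERO_H"],
                   design3$sample_id[design3$assay == "METH" &
                                       design3$treatment == "T3"])
  b <- tiny_beta(v)
  fit <- fit_probe_models(b, design3, comparison("T3", "ZERO_H", 24))
  expect_equal(fit$t[1], 0)
  expect_equal(fit$p[1], 1)
  expect_equal(fit$effect[2], 0)
  expect_equal(fit$p[2], 1)
})

test_that("donor blocking requires at least two donors", {
  d1 <- build_design(1, c(0, 24))
  sim <- simulate_methylation(d1, 10, NULL, seed = 1)
  expect_error(fit_probe_models(sim$beta, d1, comparison("RPMI", "ZERO_H", 24)),
               ">= 2 donors")
})

test_that("null p-values from the per-probe t-tests are uniform", {
  sim <- simulate_methylation(design3, 5000, NULL, seed = 17)
  fit <- fit_probe_models(sim$beta, design3, comparison("RPMI", "ZERO_H", 24))
  ks <- suppressWarnings(ks.test(fit$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("moderation limits behave as the posterior formula dictates", {
  set.seed(4)
  v <- matrix(runif(200 * 6, 0.2, 0.8), 200, 6)
  colnames(v) <- design3$sample_id[design3$assay == "METH" &
                                     design3$treatment %in% c("ZERO_H", "LPS")]
  b <- tiny_beta(v)
  fit <- fit_probe_models(b, design3, comparison("LPS", "ZERO_H", 24))

  # prior_df 0: ordinary t recovered exactly
  m0 <- moderate_variance(fit, prior_df = 0)
  expect_equal(m0$t, fit$t, tolerance = 1e-12)
  expect_equal(m0$p, fit$p, tolerance = 1e-12)

  # d0 -> Inf with given prior variance: posterior collapses to it
  mi <- moderate_variance(fit, prior_df = 1e9, prior_var = 0.02)
  expect_equal(mi$s2_post, rep(0.02, 200), tolerance = 1e-6)

  # identical s2 everywhere: the posterior is that s2 for any d0
  v2 <- v[rep(1, 50), ]
  b2 <- tiny_beta(v2)
  fit2 <- fit_probe_models(b2, design3, comparison("LPS", "ZERO_H", 24))
  m2 <- moderate_variance(fit2, prior_df = 7)
  expect_equal(m2$s2_post, fit2$s2, tolerance = 1e-10)
})

test_that("estimated prior agrees with the limma cross-check", {
  # heterogeneous true variances so the prior df is finite
  set.seed(99)
  n <- 2000
  sds <- sqrt(0.02 * rchisq(n, df = 6) / 6)
  v <- 0.5 + matrix(rnorm(n * 6), n, 6) * sds
  v <- pmin(pmax(v, 0.01), 0.99)
  colnames(v) <- design3$sample_id[design3$assay == "METH" &
                                     design3$treatment %in% c("ZERO_H", "RPMI")]
  fit <- fit_probe_models(tiny_beta(v), design3,
                          comparison("RPMI", "ZERO_H", 24), scale = "beta")
  mod <- moderate_variance(fit)
  sq <- limma::squeezeVar(fit$s2, df = fit$df)
  expect_equal(attr(mod, "prior_df"), sq$df.prior, tolerance = 0.1)
  expect_equal(attr(mod, "prior_var"), sq$var.prior, tolerance = 0.02)
  expect_equal(mod$s2_post, sq$var.post, tolerance = 0.01)
})

test_that("DMP calling applies both thresholds strictly", {
  stats <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    chrom = "chr1", pos = 1:4 * 100L,
    delta_beta = c(0.051, 0.05, 0.20, -0.08),
    p = c(0.04, 0.01, 0.20, 0.049)
  )
  dmp <- call_dmps(stats)
  expect_setequal(dmp$feature_id, c("a", "d"))
  expect_equal(dmp$direction[dmp$feature_id == "a"], "GAIN")
  expect_equal(dmp$direction[dmp$feature_id == "d"], "LOSS")
  # sign consistency of every called DMP
  expect_true(all(sign(dmp$delta_beta) ==
                    ifelse(dmp$direction == "GAIN", 1, -1)))
  expect_error(call_dmps(stats, delta_threshold = 0), "\\(0, 1\\)")
})
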