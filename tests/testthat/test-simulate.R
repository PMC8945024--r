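design3 <- build_design(3)

test_that("methylation simulation is deterministic and bounded", {
  eff <- planted_effects("T3_SPECIFIC", "GAIN", 0.15, n = 10)
  a <- simulate_methylation(design3, 500, eff, seed = 42)
  b <- simulate_methylation(design3, 500, eff, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$beta$values > 0 & a$beta$values < 1))
  expect_equal(nrow(a$truth), 10)
  c2 <- simulate_methylation(design3, 500, eff, seed = 43)
  expect_false(identical(a$beta$values, c2$beta$values))
})

test_that("without planted effects group means stay near baseline", {
  sim <- simulate_methylation(design3, 300, NULL, seed = 9)
  b <- sim$beta$values
  arms24 <- design3[design3$assay == "METH" & design3$timepoint_h == 24, ]
  zero <- design3[design3$assay == "METH" & design3$treatment == "ZERO_H", ]
  for (arm in c("RPMI", "T3", "LPS", "T3_LPS")) {
    ids <- arms24$sample_id[arms24$treatment == arm]
    dbeta <- rowMeans(b[, ids]) - rowMeans(b[, zero$sample_id])
    # per-probe delta-beta: noise + donor wobble only; 3 SE bound on mean
    expect_lt(abs(mean(dbeta)), 3 * sd(dbeta) / sqrt(nrow(b)))
  }
})

test_that("planted delta-beta magnitude is recovered at large donor count", {
  dd <- build_design(200, c(0, 24))
  eff <- planted_effects("DIFFERENTIATION", "GAIN", 0.15, n = 1,
                         feature_id = "cg0000001")
  sim <- simulate_methylation(dd, 5, eff, seed = 2)
  b <- sim$beta$values
  rp <- dd$sample_id[dd$assay == "METH" & dd$treatment == "RPMI"]
  z0 <- dd$sample_id[dd$assay == "METH" & dd$treatment == "ZERO_H"]
  dbeta <- mean(b["cg0000001", rp]) - mean(b["cg0000001", z0])
  expect_equal(dbeta, 0.15, tolerance = 0.01 / 0.15)
})

test_that("magnitudes pushing betas out of range are rejected", {
  eff <- planted_effects("T3_SPECIFIC", "GAIN", 0.9, n = 1)
  expect_error(simulate_methylation(design3, 100, eff, seed = 1),
               "outside \\(0.01, 0.99\\)")
})

test_that("expression simulation: determinism, planted fold change, XIST", {
  eff <- planted_effects("LPS_INDUCED", "GAIN", 2, n = 30, timepoints = "24")
  a <- simulate_expression(design3, 2000, eff, seed = 5)
  b <- simulate_expression(design3, 2000, eff, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$counts$counts >= 0))
  expect_true(all(a$counts$counts == floor(a$counts$counts)))

  cnt <- a$counts$counts
  lps <- design3$sample_id[design3$assay == "RNA" &
                             design3$treatment == "LPS" &
                             design3$timepoint_h == 24]
  rpmi <- design3$sample_id[design3$assay == "RNA" &
                              design3$treatment == "RPMI" &
                              design3$timepoint_h == 24]
  planted <- a$truth$feature_id
  ratio <- rowMeans(cnt[planted, lps, drop = FALSE]) /
    rowMeans(cnt[planted, rpmi, drop = FALSE])
  expect_equal(mean(ratio), 4, tolerance = 0.1)

  # male default: XIST near-silent
  expect_lt(mean(cnt["XIST", ]), 5)
  fem <- simulate_expression(design3, 500, NULL, sex = "female", seed = 5)
  expect_gt(mean(fem$counts$counts["XIST", ]), 1000)
})

test_that("null expression is centered and the Poisson limit holds", {
  sim <- simulate_expression(design3, 2000, NULL, seed = 3)
  cnt <- sim$counts$counts
  rpmi <- design3$sample_id[design3$assay == "RNA" &
                              design3$treatment == "RPMI" &
                              design3$timepoint_h == 24]
  zero <- design3$sample_id[design3$assay == "RNA" &
                              design3$treatment == "ZERO_H"]
  r <- abs(log2(rowMeans(cnt[, rpmi]) / rowMeans(cnt[, zero])))
  expect_lt(median(r[is.finite(r)]), 0.1)

  # dispersion -> 0: variance ~ mean within each donor-free group
  dd <- build_design(60, c(0, 24))
  lowd <- simulate_expression(dd, 50, NULL, dispersion = 1e-8,
                              donor_libsize_sd = 0, seed = 8)
  z0 <- dd$sample_id[dd$assay == "RNA" & dd$treatment == "ZERO_H"]
  m <- rowMeans(lowd$counts$counts[, z0])
  v <- apply(lowd$counts$counts[, z0], 1, var)
  keep <- m > 50
  expect_equal(mean(v[keep] / m[keep]), 1, tolerance = 0.15)

  expect_error(simulate_expression(design3, 100, NULL, dispersion = 0),
               "dispersion")
})

test_that("sequence simulation embeds the motif as requested", {
  annot <- data.frame(probe_id = sprintf("cg%03d", 1:250),
                      chrom = "chr1", pos = 1:250 * 1000,
                      detection_p = 0, snp_at_cg = FALSE,
                      cross_reactive = FALSE)
  targets <- annot$probe_id[1:200]
  s <- simulate_sequences(annot, window_bp = 100, planted_motif = "TGACGTCA",
                          target_ids = targets, target_fraction = 1,
                          background_fraction = 0, seed = 1)
  expect_true(all(nchar(s) == 201))
  has_motif <- grepl("TGACGTCA", s[targets]) | grepl("TGACGTCA", vapply(
    s[targets],
    function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                      collapse = ""), character(1)))
  expect_true(all(has_motif))
  bg <- setdiff(names(s), targets)
  expect_false(any(attr(s, "embedded")[annot$probe_id %in% bg]))

  # half the targets at fraction 0.5, within the binomial 99% interval
  s2 <- simulate_sequences(annot, target_ids = targets, target_fraction = 0.5,
                           background_fraction = 0, seed = 7)
  emb <- sum(attr(s2, "embedded")[annot$probe_id %in% targets])
  expect_gte(emb, qbinom(0.005, 200, 0.5))
  expect_lte(emb, qbinom(0.995, 200, 0.5))

  expect_error(simulate_sequences(annot, target_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulate_sequences(annot, window_bp = 3), "longer than")
})

test_that("the full synthetic study is reproducible with covered truth", {
  a <- simulate_study(n_probes = 1200, n_genes = 400,
                      meth_effects = planted_effects("T3_SPECIFIC", "GAIN",
                                                     0.15, n = 30),
                      expr_effects = planted_effects("LPS_INDUCED", "GAIN",
                                                     1.5, n = 20,
                                                     timepoints = "4,24"),
                      seed = 21)
  b <- simulate_study(n_probes = 1200, n_genes = 400,
                      meth_effects = planted_effects("T3_SPECIFIC", "GAIN",
                                                     0.15, n = 30),
                      expr_effects = planted_effects("LPS_INDUCED", "GAIN",
                                                     1.5, n = 20,
                                                     timepoints = "4,24"),
                      seed = 21)
  expect_identical(a$beta$values, b$beta$values)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$sequences, b$sequences)
  expect_equal(nrow(a$truth), 50)
  expect_true(all(a$truth$feature_id %in%
                    c(a$beta$annot$probe_id, a$counts$annot$gene_id)))
})
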