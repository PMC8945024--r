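design3 <- build_design(3)
rna_ids <- design3$sample_id[design3$assay == "RNA"]

make_counts <- function(cnt, lengths = NULL) {
  n <- nrow(cnt)
  annot <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n)),
    length_bp = lengths %||% rep(1000L, n),
    chrom = "chr1", tss = seq_len(n) * 10000L, strand = "+"
  )
  count_matrix(cnt, annot)
}

test_that("RPKM follows its defining formula", {
  cnt <- matrix(c(10, 9999990), 2, 1,
                dimnames = list(NULL, rna_ids[1]))
  cm <- make_counts(cnt, lengths = c(1000L, 100000L))
  r <- compute_rpkm(cm)
  expect_equal(r["G001", 1], 1.0) # 10 / (1 kb * 10 M)

  # doubling the length halves RPKM
  cm2 <- make_counts(cnt, lengths = c(2000L, 100000L))
  expect_equal(compute_rpkm(cm2)["G001", 1], 0.5)

  # random matrix vs element-wise recomputation
  set.seed(2)
  cnt3 <- matrix(rpois(200, 50), 50, 4, dimnames = list(NULL, rna_ids[1:4]))
  len3 <- sample(500:5000, 50)
  cm3 <- make_counts(cnt3, lengths = len3)
  r3 <- compute_rpkm(cm3)
  for (j in 1:4) {
    expect_equal(r3[, j],
                 setNames(cnt3[, j] / (len3 / 1000) / (sum(cnt3[, j]) / 1e6),
                          rownames(r3)),
                 tolerance = 1e-12)
  }
  zero <- make_counts(matrix(0, 2, 1, dimnames = list(NULL, rna_ids[1])))
  expect_error(compute_rpkm(zero), rna_ids[1])
})

test_that("XIST-based sex assignment uses a strict threshold", {
  mk <- function(xist_rpkm) {
    r <- matrix(xist_rpkm, 1, length(rna_ids),
                dimnames = list("XIST", rna_ids))
    r
  }
  expect_true(all(assign_sex_from_xist(mk(0), design3) == "MALE"))
  expect_true(all(assign_sex_from_xist(mk(50), design3) == "FEMALE"))
  expect_true(all(assign_sex_from_xist(mk(1), design3) == "MALE")) # strict >
  expect_error(assign_sex_from_xist(mk(0), design3, xist_gene_id = "NOPE"),
               "not found")
})

test_that("size factors recover exact scalar multiples and center to 1", {
  set.seed(3)
  ref <- rpois(100, 100) + 1
  cnt <- cbind(ref, 2 * ref, 3 * ref)
  sf <- size_factors(cnt)
  expect_equal(sf / sf[1], c(1, 2, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(prod(sf), 1, tolerance = 1e-8)

  cnt2 <- matrix(rpois(500, 80) + 1, 100, 5)
  expect_equal(prod(size_factors(cnt2)), 1, tolerance = 1e-8)
})

test_that("gene models: null identity, all-zero exclusion, lm agreement", {
  set.seed(6)
  ids <- c(design3$sample_id[design3$assay == "RNA" &
                               design3$treatment == "ZERO_H"],
           design3$sample_id[design3$assay == "RNA" &
                               design3$treatment == "RPMI" &
                               design3$timepoint_h == 24])
  base <- matrix(rpois(50 * 6, 200), 50, 6)
  base[1, ] <- rep(100, 6)  # identical in both arms after normalization
  base[2, ] <- 0            # all-zero gene
  cnt <- matrix(rpois(50 * length(rna_ids), 150), 50, length(rna_ids),
                dimnames = list(NULL, rna_ids))
  cnt[, ids] <- base
  cnt[2, ] <- 0L
  cm <- make_counts(cnt)
  suppressMessages(fit <- fit_gene_models(cm, design3,
                                          comparison("RPMI", "ZERO_H", 24)))
  # gene 1: same normalized value everywhere (size factors are all 1 since
  # each column has the same library size by construction only roughly; so
  # check the all-zero flag and the lm oracle instead, and null identity on
  # a constant matrix)
  expect_true(fit$all_zero[2])
  expect_true(is.na(fit$p[2]))

  cnt_const <- matrix(100L, 10, length(rna_ids), dimnames = list(NULL, rna_ids))
  fit_const <- fit_gene_models(make_counts(cnt_const), design3,
                               comparison("RPMI", "ZERO_H", 24))
  expect_equal(fit_const$log2fc, rep(0, 10))
  expect_equal(fit_const$p, rep(1, 10))

  # lm() oracle on the modeled response
  sf <- size_factors(cnt[, ids])
  y <- log2(sweep(cnt[, ids], 2, sf, "/") + 0.5)
  group <- c(0, 0, 0, 1, 1, 1)
  donor <- factor(rep(c("D1", "D2", "D3"), 2))
  for (i in c(3, 10, 25)) {
    sm <- summary(lm(y[i, ] ~ group + donor))$coefficients["group", ]
    expect_equal(fit$log2fc[i], unname(sm["Estimate"]), tolerance = 1e-8)
    expect_equal(fit$p[i], unname(sm["Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("null gene p-values are uniform", {
  sim <- simulate_expression(design3, 4000, NULL, seed = 23)
  fit <- fit_gene_models(sim$counts, design3, comparison("RPMI", "ZERO_H", 24))
  ks <- suppressWarnings(ks.test(fit$p[!fit$all_zero], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DEG calling enforces all four criteria strictly", {
  stats <- data.frame(
    feature_id = c("a", "b", "c", "d", "e"),
    log2fc = c(0.6, 0.58, 1.0, -0.8, 0.9),
    p = c(0.01, 0.01, 0.01, 0.02, 0.2),
    p_adj = 1,
    mean_rpkm = c(5, 5, 0.9, 6, 6),
    rpkm_log2fc = c(-0.1, 0.5, 0.9, -0.5, 0.8),
    all_zero = FALSE
  )
  class(stats) <- c("de_fit", "data.frame")
  degs <- call_degs(stats)
  # a: sign disagreement; b: log2fc not strictly > 0.58; c: RPKM gate;
  # e: p fails; d passes (DOWN, signs agree)
  expect_identical(degs$feature_id, "d")
  expect_identical(degs$direction, "DOWN")
})

test_that("fold-change-of-means test demands donor concordance", {
  # donor-level RPKM constructed to exact ratios
  a_ids <- design3$sample_id[design3$assay == "RNA" &
                               design3$treatment == "T3_LPS" &
                               design3$timepoint_h == 24]
  b_ids <- design3$sample_id[design3$assay == "RNA" &
                               design3$treatment == "LPS" &
                               design3$timepoint_h == 24]
  r <- matrix(0, 3, length(rna_ids), dimnames = list(
    c("g_conc", "g_disc", "g_fc15"), rna_ids))
  base <- c(10, 10, 10)
  r["g_conc", b_ids] <- base
  r["g_conc", a_ids] <- base * c(2.0, 1.8, 2.2)
  r["g_disc", b_ids] <- base
  r["g_disc", a_ids] <- base * c(3.0, 2.5, 0.8)
  # exact mean FC of 1.5 with pseudocount: mean_a + .1 = 1.5 (mean_b + .1)
  r["g_fc15", b_ids] <- 10
  r["g_fc15", a_ids] <- 15.05 # (15.05 + 0.1) / (10 + 0.1) = 1.5
  res <- fc_mean_test(r, design3, "T3_LPS", "LPS", 24)
  expect_true(res$pass[res$feature_id == "g_conc"])
  expect_identical(res$direction[res$feature_id == "g_conc"], "UP")
  expect_false(res$pass[res$feature_id == "g_disc"])
  expect_false(res$pass[res$feature_id == "g_fc15"]) # strict >
})

test_that("planted expression effects survive the sign-agreement filter", {
  eff <- rbind(planted_effects("LPS_INDUCED", "GAIN", 1.5, n = 40,
                               timepoints = "24"),
               planted_effects("LPS_INDUCED", "LOSS", 1.5, n = 40,
                               timepoints = "24"))
  sim <- simulate_expression(design3, 2000, eff, dispersion = 1e-6, seed = 31)
  fit <- fit_gene_models(sim$counts, design3, comparison("LPS", "RPMI", 24))
  planted <- sim$truth$feature_id
  rows <- fit[match(planted, fit$feature_id), ]
  # with essentially no noise, model and RPKM fold changes share the
  # planted sign for every planted gene
  expect_true(all(sign(rows$log2fc) == sign(rows$rpkm_log2fc)))
  degs <- call_degs(fit)
  expect_true(all(planted %in% degs$feature_id))
})

test_that("DEG calling is invariant to row and sample order", {
  eff <- planted_effects("LPS_INDUCED", "GAIN", 1.5, n = 20, timepoints = "24")
  sim <- simulate_expression(design3, 500, eff, seed = 41)
  cm <- sim$counts
  fit <- fit_gene_models(cm, design3, comparison("LPS", "RPMI", 24))
  deg1 <- call_degs(fit)
  perm <- sample(nrow(cm$counts))
  cm2 <- count_matrix(cm$counts[perm, ], cm$annot[perm, ])
  scramble <- sample(ncol(cm2$counts))
  cm2$counts <- cm2$counts[, scramble]
  fit2 <- fit_gene_models(cm2, design3, comparison("LPS", "RPMI", 24))
  deg2 <- call_degs(fit2)
  expect_setequal(deg1$feature_id, deg2$feature_id)
})
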