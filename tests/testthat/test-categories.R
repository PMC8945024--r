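# Small hand-built comparison tables drive the example-level checks; the
# exhaustive truth-table oracle in helper-oracles.R drives the set-equality
# property.

mk_tbl <- function(rows, timepoint = 24) {
  # rows: list of lists(comparison, effect, p) per feature id
  ids <- names(rows)
  comps <- unique(unlist(lapply(rows, names)))
  stats <- lapply(comps, function(cmp) {
    data.frame(
      feature_id = ids,
      effect = vapply(ids, function(f) rows[[f]][[cmp]][1], numeric(1)),
      p = vapply(ids, function(f) rows[[f]][[cmp]][2], numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  names(stats) <- comps
  comparison_table(stats)
}

test_that("treatment-specific classification needs every reference, one sign", {
  tbl <- mk_tbl(list(
    # both references passed with the same sign -> T3-specific GAIN
    ok = list("T3_vs_RPMI@24h" = c(0.08, 0.01), "T3_vs_ZERO_H@24h" = c(0.07, 0.02)),
    # sign conflict between references -> excluded
    conflict = list("T3_vs_RPMI@24h" = c(0.08, 0.01), "T3_vs_ZERO_H@24h" = c(-0.06, 0.01)),
    # one reference fails the magnitude
    weak = list("T3_vs_RPMI@24h" = c(0.08, 0.01), "T3_vs_ZERO_H@24h" = c(0.03, 0.01))
  ))
  res <- classify_induced(tbl, "T3", c("RPMI", "ZERO_H"), 24,
                          category = "T3_SPECIFIC")
  expect_identical(res$feature_id, "ok")
  expect_identical(res$direction, "GAIN")
  prov <- attr(res, "provenance")
  expect_setequal(prov$comparison_id,
                  c("T3_vs_RPMI@24h", "T3_vs_ZERO_H@24h"))
})

test_that("attenuation demands a significant opposite-sign modifier", {
  tbl <- mk_tbl(list(
    att  = list("RPMI_vs_ZERO_H@24h" = c(0.12, 0.001), "T3_vs_RPMI@24h" = c(-0.06, 0.03)),
    same = list("RPMI_vs_ZERO_H@24h" = c(0.12, 0.001), "T3_vs_RPMI@24h" = c(0.06, 0.01)),
    small = list("RPMI_vs_ZERO_H@24h" = c(0.12, 0.001), "T3_vs_RPMI@24h" = c(-0.04, 0.01))
  ))
  base <- classify_induced(tbl, "RPMI", "ZERO_H", 24,
                           category = "DIFFERENTIATION")
  expect_equal(nrow(base), 3)
  att <- classify_attenuated(base, "T3_vs_RPMI@24h", tbl)
  expect_identical(att$feature_id, "att")
  expect_identical(att$direction, "GAIN") # direction stays the base's
  # empty base gives an empty result, not an error
  empty <- base[0, ]
  attr(empty, "provenance") <- attr(base, "provenance")[0, ]
  expect_equal(nrow(classify_attenuated(empty, "T3_vs_RPMI@24h", tbl)), 0)
})

test_that("the unique co-stimulation signature needs the fourth contrast", {
  tbl <- mk_tbl(list(
    uniq = list("T3_LPS_vs_T3@24h" = c(0.2, 0.001), "T3_LPS_vs_RPMI@24h" = c(0.2, 0.001),
                "T3_LPS_vs_ZERO_H@24h" = c(0.2, 0.001), "T3_LPS_vs_LPS@24h" = c(0.07, 0.02)),
    spec_only = list("T3_LPS_vs_T3@24h" = c(0.2, 0.001), "T3_LPS_vs_RPMI@24h" = c(0.2, 0.001),
                     "T3_LPS_vs_ZERO_H@24h" = c(0.2, 0.001), "T3_LPS_vs_LPS@24h" = c(0.02, 0.2))
  ))
  spec <- classify_induced(tbl, "T3_LPS", c("T3", "RPMI", "ZERO_H"), 24,
                           category = "T3LPS_SPECIFIC")
  expect_setequal(spec$feature_id, c("uniq", "spec_only"))
  uniq <- classify_unique(spec, "T3_LPS_vs_LPS@24h", tbl)
  expect_identical(uniq$feature_id, "uniq")
})

test_that("all categories equal the exhaustive truth-table oracle", {
  for (seed in c(1, 2)) {
    stats <- random_comparison_stats(400, seed = seed)
    tbl <- comparison_table(stats)
    cats <- epistim:::categorize_all(tbl, 24)
    oracle <- oracle_categories(stats)
    for (nm in names(oracle)) {
      expect_identical(sort(cats[[nm]]$feature_id), oracle[[nm]],
                       label = sprintf("category %s (seed %d)", nm, seed))
    }
    # subset relations audited
    expect_true(all(cats$DIFF_ATTENUATED$feature_id %in%
                      cats$DIFFERENTIATION$feature_id))
    expect_true(all(cats$T3LPS_UNIQUE$feature_id %in%
                      cats$T3LPS_SPECIFIC$feature_id))
  }
})

test_that("planted category structure is recovered under low noise", {
  d <- build_design(3)
  eff <- rbind(
    planted_effects("T3_SPECIFIC", "GAIN", 0.2, n = 50),
    planted_effects("LPS_INDUCED", "GAIN", 0.2, n = 30),
    planted_effects("T3LPS_UNIQUE", "GAIN", 0.2, n = 30)
  )
  sim <- simulate_methylation(d, 2000, eff, noise_sd = 0.03, donor_sd = 0.05,
                              baseline_range = c(0.2, 0.75), seed = 13)
  stats <- list()
  for (cmp in list(c("RPMI", "ZERO_H"), c("T3", "RPMI"), c("T3", "ZERO_H"),
                   c("LPS", "RPMI"), c("LPS", "ZERO_H"), c("T3_LPS", "T3"),
                   c("T3_LPS", "RPMI"), c("T3_LPS", "ZERO_H"),
                   c("T3_LPS", "LPS"))) {
    comp <- comparison(cmp[1], cmp[2], 24)
    stats[[comp$id]] <- moderate_variance(
      fit_probe_models(sim$beta, d, comp))
  }
  tbl <- comparison_table(stats)
  cats <- epistim:::categorize_all(tbl, 24)
  planted_t3 <- sim$truth$feature_id[sim$truth$effect_class == "T3_SPECIFIC"]
  planted_uni <- sim$truth$feature_id[sim$truth$effect_class == "T3LPS_UNIQUE"]
  planted_lps <- sim$truth$feature_id[sim$truth$effect_class == "LPS_INDUCED"]
  # all planted T3-specific probes recovered, no nulls admitted
  expect_true(all(planted_t3 %in% cats$T3_SPECIFIC$feature_id))
  nulls <- setdiff(sim$beta$annot$probe_id, sim$truth$feature_id)
  expect_equal(length(intersect(cats$T3_SPECIFIC$feature_id, nulls)), 0)
  # planted unique co-stimulation probes recovered exactly; LPS-induced
  # probes never admitted into the unique set
  expect_true(all(planted_uni %in% cats$T3LPS_UNIQUE$feature_id))
  expect_equal(length(intersect(cats$T3LPS_UNIQUE$feature_id, planted_lps)), 0)
  # engine output equals the oracle on the same stats
  plain <- lapply(stats, function(s) {
    data.frame(feature_id = s$feature_id, effect = s$delta_beta, p = s$p,
               pass = abs(s$delta_beta) > 0.05 & s$p < 0.05,
               stringsAsFactors = FALSE)
  })
  oracle <- oracle_categories(plain)
  expect_identical(sort(cats$T3LPS_UNIQUE$feature_id), oracle$T3LPS_UNIQUE)
  expect_identical(sort(cats$LPS_INDUCED$feature_id), oracle$LPS_INDUCED)
})

test_that("classification is permutation invariant and threshold monotone", {
  stats <- random_comparison_stats(300, seed = 5)
  tbl <- comparison_table(stats)
  res1 <- classify_induced(tbl, "T3", c("RPMI", "ZERO_H"), 24)
  perm_stats <- lapply(stats, function(s) s[sample(nrow(s)), ])
  res2 <- classify_induced(comparison_table(perm_stats), "T3",
                           c("RPMI", "ZERO_H"), 24)
  expect_setequal(res1$feature_id, res2$feature_id)

  # loosening p never shrinks the induced set
  loose <- lapply(stats, function(s) {
    s$pass <- abs(s$effect) > 0.05 & s$p < 0.2
    s
  })
  res3 <- classify_induced(comparison_table(loose), "T3",
                           c("RPMI", "ZERO_H"), 24)
  expect_true(all(res1$feature_id %in% res3$feature_id))
})

test_that("missing comparisons are reported by name", {
  stats <- random_comparison_stats(50, seed = 3)
  stats[["T3_vs_ZERO_H@24h"]] <- NULL
  tbl <- comparison_table(stats)
  expect_error(classify_induced(tbl, "T3", c("RPMI", "ZERO_H"), 24),
               "T3_vs_ZERO_H@24h")
})

test_that("tertile partition follows the stated remainder and tie rules", {
  r9 <- setNames(9:1, paste0("g", 1:9))
  t9 <- tertile_partition(r9)
  expect_equal(as.integer(table(t9$tertile)[c("ENHANCED", "NO_EFFECT", "ABROGATED")]),
               c(3L, 3L, 3L))
  expect_identical(t9$tertile[t9$feature_id == "g1"], "ENHANCED")
  expect_identical(t9$tertile[t9$feature_id == "g9"], "ABROGATED")

  set.seed(8)
  r143 <- setNames(runif(143), sprintf("g%03d", 1:143))
  t143 <- tertile_partition(r143)
  sizes <- as.integer(table(factor(t143$tertile,
                                   c("ENHANCED", "NO_EFFECT", "ABROGATED"))))
  expect_equal(sizes, c(48L, 48L, 47L))

  # equal ratios: ordering is lexicographic by gene id, sizes balanced
  req <- setNames(rep(1, 7), c("b", "a", "d", "c", "f", "e", "g"))
  teq <- tertile_partition(req)
  expect_identical(teq$feature_id, sort(names(req)))
  expect_equal(as.integer(table(factor(teq$tertile,
                                       c("ENHANCED", "NO_EFFECT", "ABROGATED")))),
               c(3L, 2L, 2L))
  expect_warning(tertile_partition(setNames(1:2, c("a", "b"))), "fallback")
})

test_that("count reporting matches the x/y (z%) convention", {
  expect_identical(category_fraction(312, 7210), "312/7210 (4.3%)")
  expect_identical(category_fraction(315, 11927), "315/11927 (2.6%)")
  expect_identical(category_fraction(136, 575), "136/575 (23.7%)")
  expect_identical(category_fraction(0, 10), "0/10 (0%)")
})
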