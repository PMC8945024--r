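#' Default planted-effect plan for the methylation assay
#'
#' The desk-scale study conditions: 20,000 probes of which 2,300 carry
#' effects (leaving >= 10,000 true nulls for calibration), with every
#' category-engine class represented in both directions at delta-beta 0.15.
#' Twelve 4-probe runs of consecutive probes carry a shared T3-specific gain
#' so that the DMR caller has genuine regions to find.
#'
#' @param n_probes number of probes the matrix will have; planted counts
#'   scale proportionally to the 20,000-probe reference plan.
#' @param magnitude planted delta-beta, default 0.15.
#' @return planted-effects data frame for [simulate_methylation()].
#' @export
default_meth_effects <- function(n_probes = 20000, magnitude = 0.15) {
  k <- function(base) max(1L, round(base * n_probes / 20000))
  plan <- rbind(
    planted_effects("DIFFERENTIATION", "GAIN", magnitude, n = k(500)),
    planted_effects("DIFFERENTIATION", "LOSS", magnitude, n = k(500)),
    planted_effects("DIFF_ATTENUATED_BY_T3", "GAIN", magnitude, n = k(150)),
    planted_effects("DIFF_ATTENUATED_BY_T3", "LOSS", magnitude, n = k(150)),
    planted_effects("T3_SPECIFIC", "GAIN", magnitude, n = k(150)),
    planted_effects("T3_SPECIFIC", "LOSS", magnitude, n = k(150)),
    planted_effects("LPS_INDUCED", "GAIN", magnitude, n = k(200)),
    planted_effects("LPS_INDUCED", "LOSS", magnitude, n = k(200)),
    planted_effects("LPS_ATTENUATED_BY_T3LPS", "GAIN", magnitude, n = k(75)),
    planted_effects("LPS_ATTENUATED_BY_T3LPS", "LOSS", magnitude, n = k(75)),
    planted_effects("T3LPS_UNIQUE", "GAIN", magnitude, n = k(75)),
    planted_effects("T3LPS_UNIQUE", "LOSS", magnitude, n = k(75))
  )
  # clustered probes for DMR calling: runs of 4 consecutive probes
  # (probe ids are sequential along the genome, so consecutive ids are
  # neighbours 300-1500 bp apart)
  n_clusters <- max(1L, min(k(12), n_probes %/% 50))
  starts <- as.integer(seq(51, n_probes - 10, length.out = n_clusters))
  cluster_ids <- unique(sprintf("cg%07d", as.vector(outer(0:3, starts, "+"))))
  clusters <- planted_effects("T3_SPECIFIC", "GAIN", magnitude,
                              n = length(cluster_ids),
                              feature_id = cluster_ids)
  out <- rbind(plan, clusters)
  rownames(out) <- NULL
  out
}

#' Default planted-effect plan for the expression assay
#'
#' 870 of 5,000 genes carry log2 fold-change 1.5 effects across the same
#' classes as the methylation plan, at both the 4 h and 24 h timepoints;
#' planted counts scale proportionally for other gene-universe sizes.
#'
#' @param n_genes number of genes the matrix will have.
#' @param magnitude planted log2 fold change, default 1.5.
#' @return planted-effects data frame for [simulate_expression()].
#' @export
default_expr_effects <- function(n_genes = 5000, magnitude = 1.5) {
  k <- function(base) max(1L, round(base * n_genes / 5000))
  plan <- rbind(
    planted_effects("DIFFERENTIATION", "GAIN", magnitude, n = k(200), timepoints = "4,24"),
    planted_effects("DIFFERENTIATION", "LOSS", magnitude, n = k(200), timepoints = "4,24"),
    planted_effects("DIFF_ATTENUATED_BY_T3", "GAIN", magnitude, n = k(30), timepoints = "4,24"),
    planted_effects("DIFF_ATTENUATED_BY_T3", "LOSS", magnitude, n = k(30), timepoints = "4,24"),
    planted_effects("T3_SPECIFIC", "GAIN", magnitude, n = k(20), timepoints = "4,24"),
    planted_effects("T3_SPECIFIC", "LOSS", magnitude, n = k(20), timepoints = "4,24"),
    planted_effects("LPS_INDUCED", "GAIN", magnitude, n = k(125), timepoints = "4,24"),
    planted_effects("LPS_INDUCED", "LOSS", magnitude, n = k(125), timepoints = "4,24"),
    planted_effects("LPS_ATTENUATED_BY_T3LPS", "GAIN", magnitude, n = k(40), timepoints = "4,24"),
    planted_effects("LPS_ATTENUATED_BY_T3LPS", "LOSS", magnitude, n = k(40), timepoints = "4,24"),
    planted_effects("T3LPS_UNIQUE", "GAIN", magnitude, n = k(20), timepoints = "4,24"),
    planted_effects("T3LPS_UNIQUE", "LOSS", magnitude, n = k(20), timepoints = "4,24")
  )
  rownames(plan) <- NULL
  plan
}

#' Simulate a complete synthetic study
#'
#' Builds the design, the beta matrix, the count matrix, probe-window
#' sequences (motif planted in the T3-specific probe windows) and a combined
#' ground-truth table. Identical seed and parameters give bit-identical
#' output.
#'
#' @param n_donors donors, default 3.
#' @param n_probes probes, default 20,000.
#' @param n_genes genes, default 5,000.
#' @param meth_effects,expr_effects planted-effect plans; defaults from
#'   [default_meth_effects()] / [default_expr_effects()].
#' @param sex \code{"male"} or \code{"female"} (drives the XIST gene).
#' @param seed integer master seed; assay-level seeds are derived from it.
#' @param with_sequences also simulate probe-window sequences (default TRUE).
#' @param ... passed through to the assay simulators.
#' @return object of class \code{synthetic_study}: list(design, beta, counts,
#'   sequences, truth, seed).
#' @export
simulate_study <- function(n_donors = 3, n_probes = 20000, n_genes = 5000,
                           meth_effects = default_meth_effects(n_probes),
                           expr_effects = default_expr_effects(n_genes),
                           sex = "male", seed = 1L,
                           with_sequences = TRUE, ...) {
  seed <- as.integer(seed)
  design <- build_design(n_donors)
  meth <- simulate_methylation(design, n_probes, meth_effects,
                               seed = seed, ...)
  expr <- simulate_expression(design, n_genes, expr_effects,
                              sex = sex, seed = seed + 1L)
  seqs <- NULL
  if (with_sequences) {
    t3_targets <- meth$truth$feature_id[meth$truth$effect_class == "T3_SPECIFIC"]
    seqs <- simulate_sequences(meth$beta$annot, target_ids = t3_targets,
                               target_fraction = 0.6,
                               background_fraction = 0.05,
                               seed = seed + 2L)
  }
  structure(
    list(design = design, beta = meth$beta, counts = expr$counts,
         sequences = seqs, truth = rbind(meth$truth, expr$truth),
         seed = seed),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study (seed", x$seed, "):\n")
  print(x$design)
  cat(nrow(x$beta$values), "probes,", nrow(x$counts$counts), "genes,",
      nrow(x$truth), "planted effects\n")
  invisible(x)
}
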