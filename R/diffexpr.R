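#' Compute RPKM from a count matrix
#'
#' RPKM = count / (gene length in kb x library size in millions), with the
#' library size taken as the per-sample column sum of counts.
#'
#' @param counts a [count_matrix()].
#' @return numeric matrix of RPKM values (genes x samples) with the library
#'   sizes attached as attribute \code{libsize}.
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- colSums(counts$counts)
  zero <- lib == 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts$counts)[zero], collapse = ", "))
  }
  len_kb <- counts$annot$length_bp / 1000
  rpkm <- sweep(counts$counts / len_kb, 2, lib / 1e6, "/")
  attr(rpkm, "libsize") <- lib
  rpkm
}

#' Assign donor sex from XIST expression
#'
#' A donor is labeled \code{FEMALE} when the mean XIST RPKM across that
#' donor's samples strictly exceeds the threshold, else \code{MALE}.
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param design a \code{study_design} (maps samples to donors).
#' @param xist_gene_id row name of the XIST gene, default \code{"XIST"}.
#' @param threshold_rpkm decision threshold, default 1.
#' @return named character vector, one label per donor.
#' @export
assign_sex_from_xist <- function(rpkm, design, xist_gene_id = "XIST",
                                 threshold_rpkm = 1) {
  if (!xist_gene_id %in% rownames(rpkm)) {
    stop("gene '", xist_gene_id, "' not found in the RPKM matrix")
  }
  x <- rpkm[xist_gene_id, ]
  donors <- sort(unique(design$donor_id))
  vapply(donors, function(d) {
    ids <- intersect(design$sample_id[design$donor_id == d], names(x))
    if (!length(ids)) return(NA_character_)
    if (mean(x[ids]) > threshold_rpkm) "FEMALE" else "MALE"
  }, character(1))
}

#' Median-of-ratios size factors
#'
#' Per sample, the median across genes of the ratio of the count to the
#' gene's geometric mean across samples; genes with a zero count in any
#' sample are excluded from the reference.
#'
#' @param counts integer matrix, genes x samples.
#' @return numeric vector of size factors (geometric mean ~ 1).
#' @export
size_factors <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) stop("no gene is expressed in every sample; cannot normalize")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
    exp(median(log(cnt) - logg[use]))
  })
  # explicit geometric-mean centering so the factors multiply to 1
  sf / exp(mean(log(sf)))
}

#' Fit per-gene linear models for one comparison
#'
#' Counts are normalized by median-of-ratios size factors, shifted by a 0.5
#' pseudocount and log2-transformed, then modeled as
#' \code{log2(count/sf + 0.5) ~ group + donor} by least squares. The
#' reported effect is the group coefficient (log2 fold change on the count
#' scale); group-mean RPKM values and the RPKM-based log2 fold change used
#' by the sign-agreement noise filter are attached.
#'
#' @param counts a [count_matrix()].
#' @param design a \code{study_design}.
#' @param comp a [comparison()].
#' @param block_donor include donor blocking (default TRUE).
#' @return data frame of class \code{de_fit}: \code{feature_id},
#'   \code{log2fc}, \code{s2}, \code{df}, \code{t}, \code{p}, \code{p_adj},
#'   \code{mean_rpkm_target}, \code{mean_rpkm_reference}, \code{mean_rpkm}
#'   (mean over the two compared groups' samples), \code{rpkm_log2fc},
#'   \code{all_zero}. All-zero genes are excluded from testing (NA
#'   statistics, \code{all_zero = TRUE}).
#' @export
fit_gene_models <- function(counts, design, comp, block_donor = TRUE) {
  stopifnot(inherits(counts, "count_matrix"), inherits(comp, "comparison"))
  tgt <- design_samples(design, "RNA", comp$target, comp$timepoint_h)
  ref <- design_samples(design, "RNA", comp$reference, comp$timepoint_h)
  if (nrow(tgt) == 0 || nrow(ref) == 0) {
    stop("comparison ", comp$id, ": arm has no RNA samples in the design")
  }
  samp <- rbind(ref, tgt)
  missing_cols <- setdiff(samp$sample_id, colnames(counts$counts))
  if (length(missing_cols)) {
    stop("count matrix lacks samples: ", paste(missing_cols, collapse = ", "))
  }
  cnt <- counts$counts[, samp$sample_id, drop = FALSE]
  group <- as.integer(samp$sample_id %in% tgt$sample_id)

  all_zero <- rowSums(cnt) == 0
  sf <- size_factors(cnt)
  Y <- log2(sweep(cnt, 2, sf, "/") + 0.5)
  fit <- fit_feature_lm(Y, group, samp$donor_id, block_donor)

  rpkm_all <- compute_rpkm(counts)
  rpkm <- rpkm_all[, samp$sample_id, drop = FALSE]
  mt <- rowMeans(rpkm[, group == 1, drop = FALSE])
  mr <- rowMeans(rpkm[, group == 0, drop = FALSE])
  out <- data.frame(
    feature_id = counts$annot$gene_id,
    log2fc = fit$effect, s2 = fit$s2, df = fit$df,
    t = fit$t, p = fit$p, p_adj = p.adjust(fit$p, "BH"),
    mean_rpkm_target = mt, mean_rpkm_reference = mr,
    mean_rpkm = rowMeans(rpkm),
    rpkm_log2fc = log2((mt + 0.1) / (mr + 0.1)),
    all_zero = all_zero,
    stringsAsFactors = FALSE
  )
  out$log2fc[all_zero] <- NA_real_
  out$t[all_zero] <- NA_real_
  out$p[all_zero] <- NA_real_
  if (any(all_zero)) {
    message("fit_gene_models: ", sum(all_zero),
            " all-zero gene(s) excluded from testing")
  }
  class(out) <- c("de_fit", "data.frame")
  attr(out, "comparison") <- comp$id
  attr(out, "coef_var_unit") <- fit$coef_var_unit
  attr(out, "moderated") <- FALSE
  out
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff all four criteria hold, strictly: model
#' \code{|log2fc| > lfc_threshold}; unadjusted \code{p < p_threshold}; mean
#' RPKM over the samples of the two compared groups \code{> rpkm_min}; and
#' the model log2 fold change agrees in sign with the RPKM-based log2 fold
#' change (noise filter). Genes are labeled UP/DOWN by the model sign.
#'
#' @param stats a \code{de_fit}.
#' @param lfc_threshold minimum absolute model log2FC, default 0.58
#'   (2^0.58 is a linear fold change of ~1.5).
#' @param p_threshold maximum unadjusted p, default 0.05.
#' @param rpkm_min minimum mean RPKM, default 1.
#' @param use_adjusted_p gate on BH-adjusted p instead (default FALSE).
#' @return data frame of class \code{deg_result} with a \code{direction}
#'   column.
#' @export
call_degs <- function(stats, lfc_threshold = 0.58, p_threshold = 0.05,
                      rpkm_min = 1, use_adjusted_p = FALSE) {
  pv <- if (use_adjusted_p) stats$p_adj else stats$p
  keep <- !is.na(stats$log2fc) &
    abs(stats$log2fc) > lfc_threshold &
    pv < p_threshold &
    stats$mean_rpkm > rpkm_min &
    sign(stats$log2fc) == sign(stats$rpkm_log2fc)
  out <- stats[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "UP", "DOWN")
  rownames(out) <- NULL
  class(out) <- c("deg_result", "data.frame")
  attr(out, "comparison") <- attr(stats, "comparison")
  attr(out, "thresholds") <- c(lfc = lfc_threshold, p = p_threshold,
                               rpkm = rpkm_min)
  out
}

#' Fold-change-of-means test with donor concordance
#'
#' The criterion used for the co-stimulation vs LPS expression contrast: a
#' gene passes iff the linear fold change of group-mean RPKM exceeds the
#' threshold (strictly, in either direction) and every donor's individual
#' ratio changes in the same direction. Zero means are handled with a 0.1
#' RPKM pseudocount.
#'
#' @param rpkm RPKM matrix.
#' @param design a \code{study_design}.
#' @param group_a,group_b treatment arms compared (a over b).
#' @param timepoint_h timepoint of both arms.
#' @param fc_threshold linear fold-change threshold, default 1.5.
#' @return data frame: \code{feature_id}, \code{fc_mean} (ratio of group
#'   means), \code{pass}, \code{direction} (UP/DOWN for passing genes,
#'   NA otherwise).
#' @export
fc_mean_test <- function(rpkm, design, group_a, group_b, timepoint_h = 24,
                         fc_threshold = 1.5) {
  a <- design_samples(design, "RNA", group_a, timepoint_h)
  b <- design_samples(design, "RNA", group_b, timepoint_h)
  if (nrow(a) == 0 || nrow(b) == 0) stop("arm without RNA samples")
  donors <- intersect(a$donor_id, b$donor_id)
  if (!length(donors)) stop("no paired donors across the two groups")
  A <- rpkm[, a$sample_id[match(donors, a$donor_id)], drop = FALSE]
  B <- rpkm[, b$sample_id[match(donors, b$donor_id)], drop = FALSE]
  pseudo <- 0.1
  fc <- (rowMeans(A) + pseudo) / (rowMeans(B) + pseudo)
  per_donor_sign <- sign(log((A + pseudo) / (B + pseudo)))
  concordant <- apply(per_donor_sign, 1, function(s) {
    all(s > 0) || all(s < 0)
  })
  pass <- (fc > fc_threshold | fc < 1 / fc_threshold) & concordant
  data.frame(
    feature_id = rownames(rpkm),
    fc_mean = fc,
    pass = pass,
    direction = ifelse(pass, ifelse(fc > 1, "UP", "DOWN"), NA_character_),
    stringsAsFactors = FALSE
  )
}
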