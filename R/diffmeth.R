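#' Define a two-group comparison
#'
#' @param target treatment arm whose effect is estimated (e.g. \code{"T3"}).
#' @param reference reference arm (e.g. \code{"RPMI"} or \code{"ZERO_H"}).
#' @param timepoint_h timepoint of the target arm in hours; \code{ZERO_H}
#'   samples are always taken at 0 h regardless.
#' @return object of class \code{comparison} with an \code{id} like
#'   \code{"T3_vs_RPMI@24h"}.
#' @export
comparison <- function(target, reference, timepoint_h = 24) {
  target <- match.arg(target, TREATMENTS)
  reference <- match.arg(reference, TREATMENTS)
  if (target == reference) stop("target and reference arms must differ")
  structure(
    list(target = target, reference = reference,
         timepoint_h = as.numeric(timepoint_h),
         id = sprintf("%s_vs_%s@%sh", target, reference, timepoint_h)),
    class = "comparison"
  )
}

#' @export
print.comparison <- function(x, ...) {
  cat("comparison:", x$id, "\n")
  invisible(x)
}

#' Filter probes on quality and location
#'
#' Removes probes with a detection p-value above the threshold, probes with a
#' SNP at the CG site, cross-reactive probes, and (by default) probes on the
#' X and Y chromosomes. Removal counts per reason are attached as the
#' \code{removed} attribute and reported via \code{message()}.
#'
#' @param beta a [beta_matrix()].
#' @param detection_p_max maximum allowed detection p-value, default 0.01.
#' @param drop_sex_chromosomes drop chrX / chrY probes, default TRUE.
#' @return filtered \code{beta_matrix}, probe order preserved.
#' @export
filter_probes <- function(beta, detection_p_max = 0.01,
                          drop_sex_chromosomes = TRUE) {
  stopifnot(inherits(beta, "beta_matrix"))
  an <- beta$annot
  bad_det <- an$detection_p > detection_p_max
  bad_snp <- an$snp_at_cg
  bad_cross <- an$cross_reactive
  bad_sex <- if (drop_sex_chromosomes) {
    an$chrom %in% c("chrX", "chrY", "X", "Y")
  } else rep(FALSE, nrow(an))
  keep <- !(bad_det | bad_snp | bad_cross | bad_sex)
  removed <- c(detection_p = sum(bad_det), snp_at_cg = sum(bad_snp),
               cross_reactive = sum(bad_cross), sex_chromosome = sum(bad_sex))
  if (!any(keep)) stop("probe filtering removed every probe")
  message(sprintf(
    "filter_probes: kept %d/%d (removed: detection_p %d, SNP %d, cross-reactive %d, sex-chrom %d)",
    sum(keep), nrow(an), removed[1], removed[2], removed[3], removed[4]))
  out <- beta_matrix(beta$values[keep, , drop = FALSE], an[keep, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Fit per-probe linear models for one comparison
#'
#' For every probe, fits \code{response ~ group + donor} by least squares on
#' the requested scale (M-values by default) over the samples of the target
#' and reference arms, and reports the group-difference estimate with its
#' ordinary t-test. The beta-scale effect size (delta-beta, difference of
#' group mean betas) is reported alongside regardless of the modeling scale.
#'
#' @param beta a [beta_matrix()] (filtered).
#' @param design a \code{study_design}.
#' @param comp a [comparison()].
#' @param block_donor include donor as a blocking covariate (default TRUE;
#'   requires >= 2 donors).
#' @param scale modeling scale, \code{"M"} (default) or \code{"beta"}.
#' @param eps clipping epsilon for the M transform.
#' @return data frame of class \code{dm_fit}: \code{feature_id},
#'   \code{chrom}, \code{pos}, \code{delta_beta}, \code{effect} (model
#'   scale), \code{s2}, \code{df}, \code{t}, \code{p}, \code{p_adj} (BH,
#'   informational only), \code{mean_target}, \code{mean_reference}.
#'   Attributes: \code{comparison}, \code{scale}, \code{coef_var_unit},
#'   \code{moderated}.
#' @export
fit_probe_models <- function(beta, design, comp, block_donor = TRUE,
                             scale = c("M", "beta"), eps = 1e-6) {
  stopifnot(inherits(beta, "beta_matrix"), inherits(comp, "comparison"))
  scale <- match.arg(scale)
  tgt <- design_samples(design, "METH", comp$target, comp$timepoint_h)
  ref <- design_samples(design, "METH", comp$reference, comp$timepoint_h)
  if (nrow(tgt) == 0 || nrow(ref) == 0) {
    stop("comparison ", comp$id, ": arm has no METH samples in the design")
  }
  samp <- rbind(ref, tgt)
  missing_cols <- setdiff(samp$sample_id, colnames(beta$values))
  if (length(missing_cols)) {
    stop("beta matrix lacks samples: ", paste(missing_cols, collapse = ", "))
  }
  B <- beta$values[, samp$sample_id, drop = FALSE]
  Y <- if (scale == "M") beta_to_m(B, eps) else B
  group <- as.integer(samp$sample_id %in% tgt$sample_id)
  fit <- fit_feature_lm(Y, group, samp$donor_id, block_donor)

  nt <- rowMeans(B[, group == 1, drop = FALSE])
  nr <- rowMeans(B[, group == 0, drop = FALSE])
  out <- data.frame(
    feature_id = beta$annot$probe_id,
    chrom = beta$annot$chrom, pos = beta$annot$pos,
    delta_beta = nt - nr,
    effect = fit$effect, s2 = fit$s2, df = fit$df,
    t = fit$t, p = fit$p, p_adj = p.adjust(fit$p, "BH"),
    mean_target = nt, mean_reference = nr,
    stringsAsFactors = FALSE
  )
  # constant probes: no evidence either way
  const <- fit$constant
  out$delta_beta[const] <- 0
  class(out) <- c("dm_fit", "data.frame")
  attr(out, "comparison") <- comp$id
  attr(out, "scale") <- scale
  attr(out, "coef_var_unit") <- fit$coef_var_unit
  attr(out, "moderated") <- FALSE
  out
}

## Shared least-squares engine: one design matrix, matrix response over all
## features at once. Returns the group-difference estimate, residual
## variance, residual df and ordinary t-test per feature.
fit_feature_lm <- function(Y, group, donor, block_donor = TRUE) {
  n <- ncol(Y)
  donors <- unique(donor)
  if (block_donor && length(donors) < 2) {
    stop("donor blocking requires >= 2 donors (rank-deficient design)")
  }
  X <- if (block_donor) {
    stats::model.matrix(~ group + factor(donor))
  } else {
    stats::model.matrix(~ group)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  df <- n - qx$rank
  if (df < 1) stop("no residual degrees of freedom; need more samples")
  coefs <- qr.coef(qx, t(Y))
  res <- t(Y) - X %*% coefs
  s2 <- colSums(res^2) / df
  cvu <- chol2inv(qr.R(qx))[2, 2] # var(group coef) / sigma^2
  effect <- coefs["group", ]
  se <- sqrt(s2 * cvu)
  tstat <- effect / se
  p <- 2 * pt(-abs(tstat), df)
  # degenerate rows: constant response, or a numerically perfect fit with a
  # null effect (residual variance at rounding level) carry no evidence
  constant <- apply(Y, 1, function(r) all(r == r[1]))
  scale2 <- rowMeans(Y^2) + 1e-300
  null_fit <- constant | (s2 / scale2 < 1e-20 & abs(effect) / sqrt(scale2) < 1e-10)
  effect[null_fit] <- 0
  tstat[null_fit] <- 0
  p[null_fit] <- 1
  s2[null_fit] <- 0
  list(effect = unname(effect), s2 = unname(s2), df = df,
       t = unname(tstat), p = unname(p), coef_var_unit = cvu,
       constant = null_fit)
}

#' Call differentially methylated probes
#'
#' A probe is a DMP iff \code{|delta_beta| > delta_threshold} and
#' \code{p < p_threshold}, both strict, on unadjusted p-values. DMPs are
#' labeled \code{GAIN} (positive delta-beta) or \code{LOSS}.
#'
#' @param stats a \code{dm_fit} (moderated or not).
#' @param delta_threshold minimum absolute delta-beta, default 0.05.
#' @param p_threshold maximum p-value, default 0.05.
#' @return data frame of class \code{dmp_result}: the passing rows of
#'   \code{stats} plus a \code{direction} column.
#' @export
call_dmps <- function(stats, delta_threshold = 0.05, p_threshold = 0.05) {
  if (delta_threshold <= 0 || delta_threshold >= 1 ||
      p_threshold <= 0 || p_threshold >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  keep <- abs(stats$delta_beta) > delta_threshold & stats$p < p_threshold
  out <- stats[keep, , drop = FALSE]
  out$direction <- ifelse(out$delta_beta > 0, "GAIN", "LOSS")
  rownames(out) <- NULL
  class(out) <- c("dmp_result", "data.frame")
  attr(out, "comparison") <- attr(stats, "comparison")
  attr(out, "thresholds") <- c(delta = delta_threshold, p = p_threshold)
  out
}

#' @export
summary.dm_fit <- function(object, ...) {
  cat("dm_fit for", attr(object, "comparison") %||% "?", "on",
      attr(object, "scale") %||% "?", "scale;",
      nrow(object), "probes;",
      if (isTRUE(attr(object, "moderated"))) "moderated" else "unmoderated",
      "\n")
  cat(sprintf("  p < 0.05: %d; |delta-beta| > 0.05: %d\n",
              sum(object$p < 0.05), sum(abs(object$delta_beta) > 0.05)))
  invisible(object)
}
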