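#' Construct a beta-value matrix container
#'
#' Bundles a probes x samples matrix of methylation fractions with its probe
#' annotation (coordinates, detection p-value, SNP/cross-reactive flags).
#'
#' @param values numeric matrix, probes x samples, values in \code{[0, 1]},
#'   rownames = probe ids, colnames = sample ids.
#' @param annot data frame with columns \code{probe_id}, \code{chrom},
#'   \code{pos} (0-based), \code{detection_p}, \code{snp_at_cg},
#'   \code{cross_reactive}; one row per probe, same order as \code{values}.
#' @return An object of class \code{beta_matrix}.
#' @export
beta_matrix <- function(values, annot) {
  stopifnot(is.matrix(values), nrow(values) == nrow(annot))
  need <- c("probe_id", "chrom", "pos", "detection_p", "snp_at_cg", "cross_reactive")
  miss <- setdiff(need, names(annot))
  if (length(miss)) stop("probe annotation lacks: ", paste(miss, collapse = ", "))
  if (anyDuplicated(annot$probe_id)) stop("probe_ids must be unique")
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  rownames(values) <- annot$probe_id
  structure(list(values = values, annot = annot), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "probes x", ncol(x$values), "samples\n")
  invisible(x)
}

#' Describe planted effects for the synthetic generator
#'
#' One row per feature to plant. Effect classes mirror the category engine:
#' \code{DIFFERENTIATION} (culture effect shared by all stimulated arms),
#' \code{DIFF_ATTENUATED_BY_T3} (culture effect damped in T3-containing arms),
#' \code{T3_SPECIFIC}, \code{LPS_INDUCED} (LPS and T3+LPS arms),
#' \code{LPS_ATTENUATED_BY_T3LPS} (LPS effect damped under co-stimulation) and
#' \code{T3LPS_UNIQUE} (co-stimulation arm only).
#'
#' @param effect_class one of the planted effect classes (see Details).
#' @param direction \code{"GAIN"} or \code{"LOSS"}.
#' @param magnitude positive effect size: delta-beta for methylation,
#'   log2 fold change for expression.
#' @param n number of features planted with this configuration.
#' @param timepoints character, comma-separated affected timepoints, e.g.
#'   \code{"24"} or \code{"4,24"}.
#' @param feature_id optional explicit feature ids (length \code{n}); when
#'   \code{NA} the simulator assigns random distinct features.
#' @return data frame of planted-effect rows, rbind-able.
#' @export
planted_effects <- function(effect_class, direction = "GAIN", magnitude = 0.15,
                            n = 1L, timepoints = "24", feature_id = NA_character_) {
  effect_class <- match.arg(effect_class, setdiff(EFFECT_CLASSES, "NULL"))
  direction <- match.arg(direction, c("GAIN", "LOSS"))
  if (magnitude <= 0) stop("planted magnitude must be > 0")
  n <- as.integer(n)
  if (length(feature_id) == 1L) feature_id <- rep(feature_id, n)
  if (length(feature_id) != n) stop("feature_id must have length n")
  data.frame(
    effect_class = effect_class, direction = direction,
    magnitude = magnitude, timepoints = timepoints,
    feature_id = feature_id, stringsAsFactors = FALSE
  )
}

## Fraction of the planted magnitude each arm receives, per effect class.
## 'atten_frac' is the proportion of the base effect removed in the
## attenuated arm(s).
effect_arm_fractions <- function(effect_class, atten_frac) {
  z <- c(RPMI = 0, T3 = 0, LPS = 0, T3_LPS = 0)
  switch(effect_class,
    "DIFFERENTIATION" = c(RPMI = 1, T3 = 1, LPS = 1, T3_LPS = 1),
    "DIFF_ATTENUATED_BY_T3" = c(RPMI = 1, T3 = 1 - atten_frac,
                                LPS = 1, T3_LPS = 1 - atten_frac),
    "T3_SPECIFIC" = c(RPMI = 0, T3 = 1, LPS = 0, T3_LPS = 1),
    "LPS_INDUCED" = c(RPMI = 0, T3 = 0, LPS = 1, T3_LPS = 1),
    "LPS_ATTENUATED_BY_T3LPS" = c(RPMI = 0, T3 = 0, LPS = 1,
                                  T3_LPS = 1 - atten_frac),
    "T3LPS_UNIQUE" = c(RPMI = 0, T3 = 0, LPS = 0, T3_LPS = 1),
    z
  )
}

parse_timepoints <- function(x) as.numeric(strsplit(x, ",")[[1]])

## Random probe annotation across the 22 autosomes; deterministic under the
## caller's RNG state. Positions are sorted within chromosome with gaps of
## 300-1500 bp so probes resemble array spacing.
random_probe_annot <- function(n_probes, prefix = "cg") {
  chrom <- sort(sample(sprintf("chr%d", 1:22), n_probes, replace = TRUE))
  pos <- integer(n_probes)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(sample(300:1500, length(idx), replace = TRUE)) + 10000L
  }
  data.frame(
    probe_id = sprintf("%s%07d", prefix, seq_len(n_probes)),
    chrom = chrom, pos = pos,
    detection_p = 0, snp_at_cg = FALSE, cross_reactive = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Simulate a methylation beta-value matrix with planted effects
#'
#' Betas are generated on the M-value (log2-odds) scale: per-probe baseline +
#' donor random intercept (shared across arms within a donor) + planted group
#' offset + Gaussian noise, then inverse-transformed. Planted offsets are
#' computed so that the expected beta-scale difference equals the requested
#' delta-beta magnitude.
#'
#' @param design a \code{study_design}; only METH samples are used.
#' @param n_probes number of probes simulated (>= number of planted effects).
#' @param effects data frame from [planted_effects()] (or \code{NULL} for a
#'   pure null matrix).
#' @param noise_sd residual SD on the M scale, default 0.12.
#' @param donor_sd donor random-intercept SD on the M scale, default 0.25.
#' @param baseline_range range the per-probe baseline betas are drawn from.
#' @param atten_frac fraction of the base effect removed in attenuated arms,
#'   default 2/3 (so a 0.15 base delta-beta is attenuated by 0.10).
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return list with elements \code{beta} (a [beta_matrix()]) and
#'   \code{truth} (data frame: feature_id, assay, effect_class, direction,
#'   magnitude, timepoints).
#' @export
simulate_methylation <- function(design, n_probes, effects = NULL,
                                 noise_sd = 0.12, donor_sd = 0.25,
                                 baseline_range = c(0.2, 0.8),
                                 atten_frac = 2 / 3, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  meth <- design[design$assay == "METH", , drop = FALSE]
  if (nrow(meth) == 0) stop("design contains no METH samples")
  n_eff <- if (is.null(effects)) 0L else nrow(effects)
  if (n_probes < n_eff) stop("n_probes must be >= number of planted effects")
  if (noise_sd <= 0 || donor_sd < 0) stop("dispersion parameters must be positive")

  set.seed(as.integer(seed))
  annot <- random_probe_annot(n_probes)
  baseline <- runif(n_probes, baseline_range[1], baseline_range[2])

  # assign planted features to probes
  if (n_eff > 0) {
    free <- which(is.na(effects$feature_id))
    taken <- match(effects$feature_id[!is.na(effects$feature_id)], annot$probe_id)
    if (anyNA(taken)) stop("unknown feature_id in effects table")
    if (length(free)) {
      pool <- setdiff(seq_len(n_probes), taken)
      pick <- sample(pool, length(free))
      effects$feature_id[free] <- annot$probe_id[pick]
    }
    eff_idx <- match(effects$feature_id, annot$probe_id)
    # expected betas must stay inside (0.01, 0.99)
    sgn <- ifelse(effects$direction == "GAIN", 1, -1)
    target <- baseline[eff_idx] + sgn * effects$magnitude
    if (any(target <= 0.01 | target >= 0.99)) {
      stop("planted magnitude pushes expected beta outside (0.01, 0.99); ",
           "reduce magnitude or narrow baseline_range")
    }
  }

  donors <- sort(unique(meth$donor_id))
  donor_int <- matrix(rnorm(n_probes * length(donors), sd = donor_sd),
                      n_probes, length(donors), dimnames = list(NULL, donors))

  base_m <- beta_to_m(baseline)
  mu <- matrix(base_m, n_probes, nrow(meth))
  colnames(mu) <- meth$sample_id
  mu <- mu + donor_int[, meth$donor_id, drop = FALSE]

  if (n_eff > 0) {
    sgn <- ifelse(effects$direction == "GAIN", 1, -1)
    for (k in seq_len(n_eff)) {
      i <- match(effects$feature_id[k], annot$probe_id)
      tps <- parse_timepoints(effects$timepoints[k])
      frac <- effect_arm_fractions(effects$effect_class[k], atten_frac)
      for (arm in names(frac)) {
        if (frac[[arm]] == 0) next
        cols <- which(meth$treatment == arm & meth$timepoint_h %in% tps)
        if (!length(cols)) next
        tgt <- baseline[i] + sgn[k] * effects$magnitude[k] * frac[[arm]]
        mu[i, cols] <- mu[i, cols] + (beta_to_m(tgt) - base_m[i])
      }
    }
  }

  beta <- m_to_beta(mu + matrix(rnorm(length(mu), sd = noise_sd), nrow(mu)))
  truth <- if (n_eff > 0) {
    data.frame(feature_id = effects$feature_id, assay = "METH",
               effect_class = effects$effect_class,
               direction = effects$direction,
               magnitude = effects$magnitude,
               timepoints = effects$timepoints, stringsAsFactors = FALSE)
  } else {
    data.frame(feature_id = character(), assay = character(),
               effect_class = character(), direction = character(),
               magnitude = numeric(), timepoints = character(),
               stringsAsFactors = FALSE)
  }
  list(beta = beta_matrix(beta, annot), truth = truth)
}
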