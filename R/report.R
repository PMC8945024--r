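#' Row-standardize a features x samples matrix
#'
#' Each feature (row) is centered and scaled to unit SD. Constant rows are
#' set to all zeros and flagged in the \code{constant} attribute.
#'
#' @param values numeric matrix, features x samples, >= 2 samples.
#' @return z-scored matrix with logical attribute \code{constant}.
#' @export
zscore_matrix <- function(values) {
  if (is.null(dim(values)) || ncol(values) < 2) {
    stop("z-scoring needs a matrix with >= 2 samples")
  }
  mu <- rowMeans(values)
  s <- apply(values, 1, sd)
  const <- s == 0
  z <- (values - mu) / ifelse(const, 1, s)
  z[const, ] <- 0
  attr(z, "constant") <- const
  z
}

#' Project samples onto principal components of a feature matrix
#'
#' Samples are projected onto the eigenvectors of the feature-centered
#' covariance; components are ordered by decreasing eigenvalue. The sign of
#' each component is fixed so its largest-magnitude loading is positive.
#'
#' @param values numeric matrix, features x samples (e.g. the beta values of
#'   a DMP set); >= 2 samples, >= 1 feature.
#' @param n_components number of components returned (clipped with a
#'   warning when above \code{min(dim)}).
#' @param zscore standardize rows first (default FALSE: raw values).
#' @return list of class \code{pca_projection}: \code{coordinates} (samples
#'   x components), \code{explained_variance} (fractions, non-increasing),
#'   \code{loadings}, \code{input_scale} (\code{"raw"} or
#'   \code{"z-scored"}).
#' @export
pca_project <- function(values, n_components = 3, zscore = FALSE) {
  if (ncol(values) < 2) stop("PCA needs >= 2 samples")
  if (nrow(values) < 1) stop("PCA needs >= 1 feature")
  if (zscore) values <- zscore_matrix(values)
  max_comp <- min(nrow(values), ncol(values) - 1L)
  if (n_components > max_comp) {
    warning("n_components clipped to ", max_comp)
    n_components <- max_comp
  }
  pc <- prcomp(t(values), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  coords <- pc$x[, k, drop = FALSE]
  load <- pc$rotation[, k, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in k) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  ev <- pc$sdev^2
  structure(
    list(coordinates = coords,
         explained_variance = (ev / sum(ev))[k],
         loadings = load,
         input_scale = if (zscore) "z-scored" else "raw"),
    class = "pca_projection"
  )
}

#' @export
print.pca_projection <- function(x, ...) {
  cat("PCA on", x$input_scale, "values:",
      paste0(sprintf("PC%d %.1f%%", seq_along(x$explained_variance),
                     100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Median trajectory of a feature set across treatment arms
#'
#' Expression mode: per feature, the group-mean RPKM per arm; then the
#' median over features; reported as log2 of the ratio of that median to
#' the reference arm's median (a zero reference median gets a 0.1
#' pseudocount, with a message). Methylation mode: the median over all
#' member beta values per arm, reported as the change versus the reference
#' median. The alternative order of operations (median per sample, then
#' mean) is available via \code{order_of_ops = "median_then_mean"}.
#'
#' @param values matrix features x samples (RPKM or beta).
#' @param design a \code{study_design}.
#' @param feature_set feature ids (rows) summarized.
#' @param arms treatment arms summarized.
#' @param timepoint_h timepoint of the arms, default 24.
#' @param assay \code{"RNA"} (fold-change mode) or \code{"METH"} (delta
#'   mode).
#' @param reference reference arm, default \code{"ZERO_H"}.
#' @param order_of_ops \code{"mean_then_median"} (default) or
#'   \code{"median_then_mean"}.
#' @return data frame: \code{arm}, \code{summary_value} (median RPKM or
#'   median beta), \code{trajectory} (log2 FC of medians, or median beta
#'   change).
#' @export
trajectory_summary <- function(values, design, feature_set, arms,
                               timepoint_h = 24,
                               assay = c("RNA", "METH"),
                               reference = "ZERO_H",
                               order_of_ops = c("mean_then_median",
                                                "median_then_mean")) {
  assay <- match.arg(assay)
  order_of_ops <- match.arg(order_of_ops)
  feature_set <- intersect(feature_set, rownames(values))
  if (!length(feature_set)) stop("feature_set has no rows in the matrix")
  all_arms <- unique(c(reference, arms))
  summarize_arm <- function(arm) {
    ids <- design_samples(design, assay, arm, timepoint_h)$sample_id
    ids <- intersect(ids, colnames(values))
    if (!length(ids)) stop("arm ", arm, " has no samples in the matrix")
    sub <- values[feature_set, ids, drop = FALSE]
    if (assay == "METH") {
      median(sub) # median over all member beta values
    } else if (order_of_ops == "mean_then_median") {
      median(rowMeans(sub)) # per-feature group mean, then median
    } else {
      mean(apply(sub, 2, median)) # per-sample median, then mean
    }
  }
  med <- vapply(all_arms, summarize_arm, numeric(1))
  ref_val <- med[[reference]]
  if (assay == "RNA") {
    if (ref_val == 0) {
      message("trajectory_summary: zero reference median, 0.1 pseudocount applied")
      ref_val <- 0.1
      med[med == 0] <- 0.1
    }
    traj <- log2(med / ref_val)
  } else {
    traj <- med - ref_val
  }
  data.frame(arm = all_arms, summary_value = unname(med),
             trajectory = unname(traj), stringsAsFactors = FALSE)
}

#' Rank features by an effect-size key
#'
#' Descending by absolute key; ties broken by feature id; top-n returned.
#'
#' @param stats data frame with \code{feature_id}.
#' @param key numeric vector aligned with \code{stats} (e.g. the mean
#'   delta-beta of the modifier comparison).
#' @param n number of features returned (full set when larger).
#' @param annotation optional [nearest_gene()] output merged in by position
#'   (matched on feature order is the caller's responsibility; a
#'   \code{gene_id} column is attached when row counts align).
#' @return ranked data frame with \code{rank} and \code{key} columns.
#' @export
rank_top_features <- function(stats, key, n = 10, annotation = NULL) {
  if (length(key) != nrow(stats)) stop("key must align with stats rows")
  if (any(!is.finite(key))) stop("key must be computable (finite) for all features")
  ord <- order(-abs(key), stats$feature_id)
  out <- stats[ord, , drop = FALSE]
  out$key <- key[ord]
  if (!is.null(annotation) && nrow(annotation) == nrow(stats)) {
    out$gene_id <- annotation$gene_id[ord]
    out$distance_bp <- annotation$distance_bp[ord]
  }
  out <- utils::head(out, n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
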