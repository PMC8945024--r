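#' Construct a count-matrix container
#'
#' Bundles a genes x samples matrix of non-negative integer counts with gene
#' annotation (length, TSS coordinates, strand) used for RPKM computation and
#' nearest-gene assignment.
#'
#' @param counts integer matrix, genes x samples, rownames = gene ids.
#' @param annot data frame with columns \code{gene_id}, \code{length_bp},
#'   \code{chrom}, \code{tss}, \code{strand}; one row per gene, same order.
#' @return object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, annot) {
  stopifnot(is.matrix(counts), nrow(counts) == nrow(annot))
  need <- c("gene_id", "length_bp", "chrom", "tss", "strand")
  miss <- setdiff(need, names(annot))
  if (length(miss)) stop("gene annotation lacks: ", paste(miss, collapse = ", "))
  if (anyDuplicated(annot$gene_id)) stop("gene_ids must be unique")
  if (any(annot$length_bp <= 0)) stop("gene lengths must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  rownames(counts) <- annot$gene_id
  structure(list(counts = counts, annot = annot), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Simulate an RNA-seq count matrix with planted effects
#'
#' Counts are negative binomial around a per-gene baseline mean scaled by a
#' donor-specific library-size factor, with planted log2 group offsets. An
#' \code{XIST} gene is always included; under the default male simulation its
#' mean is near zero, under \code{sex = "female"} it is highly expressed, so
#' the XIST-based sex-assignment step has signal to work with.
#'
#' @param design a \code{study_design}; only RNA samples are used.
#' @param n_genes number of genes simulated (including XIST).
#' @param effects data frame from [planted_effects()]; magnitudes are log2
#'   fold changes. \code{NULL} plants nothing.
#' @param dispersion NB overdispersion (DESeq parameterisation,
#'   \code{var = mu + dispersion * mu^2}); must be > 0. Default 0.01.
#' @param mean_log,sd_log lognormal parameters of baseline means.
#' @param donor_libsize_sd lognormal sdlog of donor library-size factors.
#' @param sex \code{"male"} (XIST silent) or \code{"female"} (XIST high).
#' @param atten_frac as in [simulate_methylation()].
#' @param seed integer seed.
#' @return list with \code{counts} (a [count_matrix()]) and \code{truth}.
#' @export
simulate_expression <- function(design, n_genes, effects = NULL,
                                dispersion = 0.01,
                                mean_log = log(800), sd_log = 1.2,
                                donor_libsize_sd = 0.1,
                                sex = c("male", "female"),
                                atten_frac = 2 / 3, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  sex <- match.arg(sex)
  rna <- design[design$assay == "RNA", , drop = FALSE]
  if (nrow(rna) == 0) stop("design contains no RNA samples")
  if (dispersion <= 0) stop("dispersion must be > 0")
  n_eff <- if (is.null(effects)) 0L else nrow(effects)
  if (n_genes < n_eff + 1L) stop("n_genes must exceed number of planted effects")

  set.seed(as.integer(seed))
  ids <- sprintf("GENE%05d", seq_len(n_genes - 1L))
  chrom <- sample(sprintf("chr%d", 1:22), n_genes - 1L, replace = TRUE)
  annot <- data.frame(
    gene_id = c(ids, "XIST"),
    length_bp = c(sample(500:5000, n_genes - 1L, replace = TRUE), 19280L),
    chrom = c(chrom, "chrX"),
    tss = sample.int(2e8, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  baseline <- c(exp(rnorm(n_genes - 1L, mean_log, sd_log)),
                if (sex == "male") 0.5 else 5000)

  if (n_eff > 0) {
    free <- which(is.na(effects$feature_id))
    pool <- setdiff(ids, effects$feature_id) # never plant on XIST
    if (length(free)) effects$feature_id[free] <- sample(pool, length(free))
    if (anyNA(match(effects$feature_id, ids))) {
      stop("unknown or XIST feature_id in effects table")
    }
  }

  donors <- sort(unique(rna$donor_id))
  donor_fac <- setNames(exp(rnorm(length(donors), 0, donor_libsize_sd)), donors)

  log2mu <- matrix(log2(baseline), n_genes, nrow(rna))
  colnames(log2mu) <- rna$sample_id
  if (n_eff > 0) {
    sgn <- ifelse(effects$direction == "GAIN", 1, -1)
    for (k in seq_len(n_eff)) {
      i <- match(effects$feature_id[k], annot$gene_id)
      tps <- parse_timepoints(effects$timepoints[k])
      frac <- effect_arm_fractions(effects$effect_class[k], atten_frac)
      for (arm in names(frac)) {
        if (frac[[arm]] == 0) next
        cols <- which(rna$treatment == arm & rna$timepoint_h %in% tps)
        if (length(cols)) {
          log2mu[i, cols] <- log2mu[i, cols] + sgn[k] * effects$magnitude[k] * frac[[arm]]
        }
      }
    }
  }

  mu <- 2^log2mu * rep(donor_fac[rna$donor_id], each = n_genes)
  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
    n_genes, nrow(rna), dimnames = list(annot$gene_id, rna$sample_id)
  )

  truth <- if (n_eff > 0) {
    data.frame(feature_id = effects$feature_id, assay = "RNA",
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
  list(counts = count_matrix(counts, annot), truth = truth)
}
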