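#' Default pipeline configuration
#'
#' All thresholds default to the canonical cut-offs: delta-beta 0.05,
#' unadjusted p 0.05, log2 fold change 0.58 (linear 1.5), mean RPKM gate 1,
#' fold change of mean RPKM 1.5; DMR chaining gap 1000 bp with minimum 3
#' CpGs; enrichment composite filter p 0.05 / fold 1.5 / 5 percentage
#' points / 2 targets.
#'
#' @param seed master seed.
#' @param outdir output directory (\code{NULL}: keep results in memory
#'   only).
#' @return a validated \code{pipeline_config}.
#' @export
default_config <- function(seed = 1L, outdir = NULL) {
  validate_config(list(seed = seed, outdir = outdir))
}

config_template <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    synthetic = list(n_donors = 3L, n_probes = 20000L, n_genes = 5000L,
                     sex = "male", with_sequences = TRUE),
    input_prefix = NULL,
    thresholds = list(
      delta_beta = 0.05, p = 0.05, log2fc = 0.58, rpkm_min = 1,
      fc_mean = 1.5,
      dmr_max_gap_bp = 1000, dmr_min_cpgs = 3,
      enrich_p = 0.05, enrich_fold = 1.5, enrich_diff_pp = 5,
      enrich_min_targets = 2, enrich_min_genes = 2
    ),
    comparisons = list(meth_timepoint = 24, rna_timepoints = c(4, 24)),
    annotation = list(max_distance_bp = 1e6, promoter_max_bp = 5000),
    moderation = TRUE,
    block_donor = TRUE,
    meth_scale = "M",
    background_size = 2000L,
    plots = FALSE
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a (possibly partial) named list or the path of a YAML file.
#' Unknown keys are rejected by name; type and positivity violations are
#' enumerated together rather than failing one at a time. Defaults are
#' filled in and the completed configuration is returned with a provenance
#' hash attached.
#'
#' @param raw named list or YAML file path.
#' @return validated list of class \code{pipeline_config} with attribute
#'   \code{hash}.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1L) {
    raw <- yaml::read_yaml(raw)
    if (is.null(raw)) raw <- list()
  }
  if (!is.list(raw)) stop("configuration must be a named list or YAML path")
  tpl <- config_template()
  errors <- character()

  merge_level <- function(tpl, raw, prefix = "") {
    unknown <- setdiff(names(raw), names(tpl))
    if (length(unknown)) {
      errors <<- c(errors, sprintf("unknown key '%s%s'", prefix, unknown))
    }
    for (k in intersect(names(raw), names(tpl))) {
      if (is.list(tpl[[k]]) && !is.null(names(tpl[[k]]))) {
        if (!is.list(raw[[k]])) {
          errors <<- c(errors, sprintf("key '%s%s' must be a list", prefix, k))
        } else {
          tpl[[k]] <- merge_level(tpl[[k]], raw[[k]], paste0(prefix, k, "."))
        }
      } else if (!is.null(raw[[k]])) {
        tpl[[k]] <- raw[[k]]
      }
    }
    tpl
  }
  cfg <- merge_level(tpl, raw)

  check_num <- function(x, name, positive = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      errors <<- c(errors, sprintf("'%s' must be a finite number", name))
    } else if (positive && x <= 0) {
      errors <<- c(errors, sprintf("'%s' must be positive", name))
    }
  }
  for (nm in c("delta_beta", "p", "log2fc", "rpkm_min", "fc_mean",
               "dmr_max_gap_bp", "dmr_min_cpgs", "enrich_p", "enrich_fold",
               "enrich_diff_pp", "enrich_min_targets", "enrich_min_genes")) {
    check_num(cfg$thresholds[[nm]], paste0("thresholds.", nm))
  }
  check_num(cfg$seed, "seed", positive = FALSE)
  check_num(cfg$synthetic$n_donors, "synthetic.n_donors")
  check_num(cfg$synthetic$n_probes, "synthetic.n_probes")
  check_num(cfg$synthetic$n_genes, "synthetic.n_genes")
  if (is.numeric(cfg$thresholds$p) && length(cfg$thresholds$p) == 1L &&
      (cfg$thresholds$p >= 1 || cfg$thresholds$p <= 0)) {
    errors <- c(errors, "'thresholds.p' must lie in (0, 1)")
  }
  if (!is.numeric(cfg$comparisons$rna_timepoints) ||
      length(cfg$comparisons$rna_timepoints) < 1) {
    errors <- c(errors, "'comparisons.rna_timepoints' must be a non-empty numeric vector")
  }
  if (!cfg$meth_scale %in% c("M", "beta")) {
    errors <- c(errors, "'meth_scale' must be \"M\" or \"beta\"")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Provenance hash of a configuration
#'
#' Covers every analysis-relevant parameter; the output directory is
#' excluded so that identical analyses written to different locations carry
#' the same stamp.
#'
#' @param cfg a \code{pipeline_config} (or plain list).
#' @return 16-hex-character hash of the canonical serialization.
#' @export
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      paste0("{", paste(names(x), vapply(x, canon, character(1)),
                        sep = ":", collapse = ","), "}")
    } else {
      paste(format(x, digits = 15), collapse = ",")
    }
  }
  fnv1a_hash(canon(cfg))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config (hash", attr(x, "hash"), ")\n")
  cat("  seed:", x$seed, " outdir:", x$outdir %||% "<memory>", "\n")
  cat("  thresholds: delta-beta", x$thresholds$delta_beta,
      "p", x$thresholds$p, "log2FC", x$thresholds$log2fc,
      "RPKM", x$thresholds$rpkm_min, "FC(mean)", x$thresholds$fc_mean, "\n")
  invisible(x)
}
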