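#' Motif enrichment with the composite filter
#'
#' For each motif, compares the fraction of target sequences containing the
#' motif with the fraction of background sequences containing it (targets
#' are excluded from the background by construction of the two inputs). The
#' p-value is the one-sided hypergeometric tail: drawing \code{n_target}
#' sequences from the pooled universe, the probability of at least the
#' observed number of hit sequences. A motif passes the composite filter iff
#' p < \code{p_max}, fold change (pct target / pct background) >
#' \code{fold_min}, difference > \code{diff_min_pp} percentage points, at
#' least \code{min_targets} target sequences contain it, and its TF shows
#' meaningful expression (log2 mean RPKM >= 0 in at least one treatment
#' arm, when an expression table is supplied).
#'
#' @param target_hits named list (motif_id -> logical vector over target
#'   sequences) or the output of [scan_pwm()] per motif.
#' @param background_hits same structure over background sequences.
#' @param pwms optional list of [pwm()] objects (provides TF gene ids).
#' @param tf_expression optional matrix of log2 mean RPKM, TF genes x arms
#'   (see [tf_expression_table()]).
#' @param p_max,fold_min,diff_min_pp,min_targets filter thresholds
#'   (defaults 0.05, 1.5, 5, 2).
#' @return data frame of class \code{enrichment_result}: counts,
#'   \code{pct_target}, \code{pct_background}, \code{fold},
#'   \code{difference_pp}, \code{p}, \code{passes_filter},
#'   \code{excluded_reason}.
#' @export
motif_enrichment <- function(target_hits, background_hits, pwms = NULL,
                             tf_expression = NULL, p_max = 0.05,
                             fold_min = 1.5, diff_min_pp = 5,
                             min_targets = 2) {
  as_flags <- function(x) {
    lapply(x, function(h) if (is.data.frame(h)) h$hit else as.logical(h))
  }
  tg <- as_flags(target_hits)
  bg <- as_flags(background_hits)
  motifs <- intersect(names(tg), names(bg))
  if (!length(motifs)) stop("no shared motif ids between target and background")
  rows <- lapply(motifs, function(m) {
    n_t <- length(tg[[m]])
    n_b <- length(bg[[m]])
    if (n_b == 0) stop("empty background for motif ", m)
    n_tw <- sum(tg[[m]])
    n_bw <- sum(bg[[m]])
    pct_t <- 100 * n_tw / n_t
    pct_b <- 100 * n_bw / n_b
    p <- phyper(n_tw - 1, n_tw + n_bw, n_t + n_b - n_tw - n_bw, n_t,
                lower.tail = FALSE)
    tf <- if (!is.null(pwms) && m %in% names(pwms)) pwms[[m]]$tf_gene_id else m
    excluded <- NA_character_
    if (!is.null(tf_expression)) {
      if (tf %in% rownames(tf_expression)) {
        if (all(tf_expression[tf, ] < 0)) excluded <- "TF_NOT_EXPRESSED"
      } else {
        excluded <- "TF_EXPRESSION_UNKNOWN"
      }
    }
    fold <- if (pct_b > 0) pct_t / pct_b else Inf
    data.frame(
      motif_id = m, tf_gene_id = tf,
      n_target_with = n_tw, n_target = n_t,
      n_background_with = n_bw, n_background = n_b,
      pct_target = pct_t, pct_background = pct_b,
      fold = fold, difference_pp = pct_t - pct_b, p = p,
      passes_filter = is.na(excluded) & p < p_max & fold > fold_min &
        (pct_t - pct_b) > diff_min_pp & n_tw >= min_targets,
      excluded_reason = excluded,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Per-arm log2 mean RPKM table for TF-expression filtering
#'
#' @param rpkm RPKM matrix.
#' @param design a \code{study_design}.
#' @param gene_ids genes to tabulate (default all).
#' @return matrix genes x treatment arms of log2 mean RPKM (0.01 RPKM
#'   pseudocount).
#' @export
tf_expression_table <- function(rpkm, design, gene_ids = rownames(rpkm)) {
  rna <- design[design$assay == "RNA", , drop = FALSE]
  arms <- intersect(TREATMENTS, unique(rna$treatment))
  out <- vapply(arms, function(a) {
    ids <- intersect(rna$sample_id[rna$treatment == a], colnames(rpkm))
    log2(rowMeans(rpkm[gene_ids, ids, drop = FALSE]) + 0.01)
  }, numeric(length(gene_ids)))
  rownames(out) <- gene_ids
  out
}

#' Term (ontology / pathway) enrichment
#'
#' One-sided hypergeometric test per term against the supplied universe. A
#' term passes iff p < \code{p_max} and the overlap has at least
#' \code{min_genes} genes. Terms with no universe genes are skipped with a
#' message.
#'
#' @param gene_set character vector, must be a subset of \code{universe}.
#' @param universe character vector of all testable genes.
#' @param term_db named list: term id -> character vector of member genes.
#' @param p_max,min_genes filter thresholds (defaults 0.05, 2).
#' @return data frame of class \code{enrichment_result}: \code{term_id},
#'   counts, \code{fold}, \code{p}, \code{passes_filter}.
#' @export
term_enrichment <- function(gene_set, universe, term_db, p_max = 0.05,
                            min_genes = 2) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe)) {
    stop("gene_set must be a subset of the universe")
  }
  n_set <- length(gene_set)
  N <- length(universe)
  skipped <- 0L
  rows <- lapply(names(term_db), function(tid) {
    members <- intersect(term_db[[tid]], universe)
    K <- length(members)
    if (K == 0) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    m <- length(intersect(gene_set, members))
    p <- phyper(m - 1, K, N - K, n_set, lower.tail = FALSE)
    expected <- n_set * K / N
    data.frame(
      term_id = tid, n_overlap = m, n_term = K,
      n_set = n_set, n_universe = N,
      fold = if (expected > 0) m / expected else NA_real_,
      p = p,
      passes_filter = p < p_max & m >= min_genes,
      stringsAsFactors = FALSE
    )
  })
  if (skipped > 0) {
    message("term_enrichment: ", skipped, " term(s) with no universe genes skipped")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(), n_overlap = integer(),
                      n_term = integer(), n_set = integer(),
                      n_universe = integer(), fold = numeric(), p = numeric(),
                      passes_filter = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Read a GMT file into a term database
#'
#' Standard GMT: one term per line, tab-separated: term id, description,
#' member genes.
#'
#' @param path GMT file.
#' @return named list term id -> gene ids, with descriptions in attribute
#'   \code{description}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  out <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(out) <- vapply(parts, `[`, character(1), 1)
  attr(out, "description") <- vapply(parts, `[`, character(1), 2)
  out
}
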