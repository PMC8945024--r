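# Independent brute-force oracles shared across test files. These are kept
# deliberately naive (per-feature loops, quadratic scans, direct logical
# definitions) so they stay independent of the package implementations they
# check.

# Truth-table evaluation of every category over a comparison-table-like
# named list of data.frames (feature_id, effect, p, pass). Thresholds are
# applied feature by feature, following the pattern definitions directly.
oracle_categories <- function(stats, timepoint = 24) {
  cid <- function(a, b) sprintf("%s_vs_%s@%sh", a, b, timepoint)
  universe <- sort(stats[[1]]$feature_id)
  get <- function(id, f) {
    d <- stats[[id]]
    d[d$feature_id == f, , drop = FALSE]
  }
  passes <- function(id, f) get(id, f)$pass
  sgn <- function(id, f) sign(get(id, f)$effect)

  res <- list(DIFFERENTIATION = character(), DIFF_ATTENUATED = character(),
              T3_SPECIFIC = character(), LPS_INDUCED = character(),
              LPS_BASE = character(), LPS_ATTENUATED = character(),
              T3LPS_SPECIFIC = character(), T3LPS_UNIQUE = character())
  dirs <- list()
  for (f in universe) {
    # differentiation: RPMI vs 0 h
    if (passes(cid("RPMI", "ZERO_H"), f)) {
      res$DIFFERENTIATION <- c(res$DIFFERENTIATION, f)
      d <- sgn(cid("RPMI", "ZERO_H"), f)
      dirs[["DIFFERENTIATION"]][[f]] <- d
      # attenuated: T3 vs RPMI significant, opposite sign
      if (passes(cid("T3", "RPMI"), f) && sgn(cid("T3", "RPMI"), f) == -d) {
        res$DIFF_ATTENUATED <- c(res$DIFF_ATTENUATED, f)
      }
    }
    # T3-specific: T3 vs RPMI and T3 vs 0 h, same sign
    if (passes(cid("T3", "RPMI"), f) && passes(cid("T3", "ZERO_H"), f) &&
        sgn(cid("T3", "RPMI"), f) == sgn(cid("T3", "ZERO_H"), f) &&
        sgn(cid("T3", "RPMI"), f) != 0) {
      res$T3_SPECIFIC <- c(res$T3_SPECIFIC, f)
    }
    # LPS-induced, route A: LPS vs RPMI and 0 h
    route_a <- passes(cid("LPS", "RPMI"), f) && passes(cid("LPS", "ZERO_H"), f) &&
      sgn(cid("LPS", "RPMI"), f) == sgn(cid("LPS", "ZERO_H"), f) &&
      sgn(cid("LPS", "RPMI"), f) != 0
    # route B: T3+LPS vs T3 and 0 h
    route_b <- passes(cid("T3_LPS", "T3"), f) && passes(cid("T3_LPS", "ZERO_H"), f) &&
      sgn(cid("T3_LPS", "T3"), f) == sgn(cid("T3_LPS", "ZERO_H"), f) &&
      sgn(cid("T3_LPS", "T3"), f) != 0
    dir_a <- if (route_a) sgn(cid("LPS", "RPMI"), f) else NULL
    dir_b <- if (route_b) sgn(cid("T3_LPS", "T3"), f) else NULL
    if (route_a || route_b) {
      if (route_a && route_b && dir_a != dir_b) {
        # conflicting direction between routes: dropped
      } else {
        res$LPS_INDUCED <- c(res$LPS_INDUCED, f)
      }
    }
    if (route_a) {
      res$LPS_BASE <- c(res$LPS_BASE, f)
      if (passes(cid("T3_LPS", "LPS"), f) &&
          sgn(cid("T3_LPS", "LPS"), f) == -dir_a) {
        res$LPS_ATTENUATED <- c(res$LPS_ATTENUATED, f)
      }
    }
    # T3+LPS-specific: vs T3, RPMI and 0 h, one sign
    refs <- c(cid("T3_LPS", "T3"), cid("T3_LPS", "RPMI"), cid("T3_LPS", "ZERO_H"))
    if (all(vapply(refs, passes, logical(1), f = f))) {
      ss <- vapply(refs, sgn, numeric(1), f = f)
      if (length(unique(ss)) == 1 && ss[1] != 0) {
        res$T3LPS_SPECIFIC <- c(res$T3LPS_SPECIFIC, f)
        if (passes(cid("T3_LPS", "LPS"), f) &&
            sgn(cid("T3_LPS", "LPS"), f) == ss[1]) {
          res$T3LPS_UNIQUE <- c(res$T3LPS_UNIQUE, f)
        }
      }
    }
  }
  lapply(res, sort)
}

# Random comparison-table inputs over a feature universe: effects and
# p-values drawn so that a workable share of features pass per comparison.
random_comparison_stats <- function(n_features, timepoint = 24, seed = 1) {
  set.seed(seed)
  ids <- sprintf("f%04d", seq_len(n_features))
  defs <- list(c("RPMI", "ZERO_H"), c("T3", "RPMI"), c("T3", "ZERO_H"),
               c("LPS", "RPMI"), c("LPS", "ZERO_H"), c("T3_LPS", "T3"),
               c("T3_LPS", "RPMI"), c("T3_LPS", "ZERO_H"), c("T3_LPS", "LPS"))
  out <- list()
  for (d in defs) {
    id <- sprintf("%s_vs_%s@%sh", d[1], d[2], timepoint)
    eff <- runif(n_features, -0.2, 0.2)
    p <- runif(n_features)^2 # skewed so many pass
    out[[id]] <- data.frame(feature_id = ids, effect = eff, p = p,
                            pass = abs(eff) > 0.05 & p < 0.05,
                            stringsAsFactors = FALSE)
  }
  out
}

# Naive maximal-window scan for DMRs: enumerate all contiguous candidate
# windows, keep valid + maximal ones.
oracle_dmrs <- function(stats, max_gap_bp = 1000, min_cpgs = 3,
                        p_threshold = 0.05, delta_threshold = 0.05) {
  x <- as.data.frame(stats)
  x <- x[order(x$chrom, x$pos), ]
  out <- list()
  for (ch in unique(x$chrom)) {
    cc <- x[x$chrom == ch & x$p < p_threshold & x$delta_beta != 0, ]
    n <- nrow(cc)
    if (n == 0) next
    valid <- function(i, j) {
      idx <- i:j
      s <- sign(cc$delta_beta[idx])
      all(s == s[1]) && (j == i || all(diff(cc$pos[idx]) <= max_gap_bp))
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!valid(i, j)) next
        maximal <- (i == 1 || !valid(i - 1, j)) && (j == n || !valid(i, j + 1))
        if (!maximal) next
        if (j - i + 1 < min_cpgs) next
        if (!any(abs(cc$delta_beta[i:j]) > delta_threshold)) next
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = cc$pos[i], end = cc$pos[j] + 1L,
          n_cpgs = j - i + 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Quadratic all-pairs interval intersection (0-based half-open).
oracle_intersect <- function(regions, intervals) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(intervals))) {
      if (regions$chrom[i] != intervals$chrom[j]) next
      ov <- min(regions$end[i], intervals$end[j]) -
        max(regions$start[i], intervals$start[j])
      if (ov >= 1) {
        out[[length(out) + 1]] <- data.frame(region_idx = i, interval_idx = j,
                                             overlap_bp = ov)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(region_idx = integer(), interval_idx = integer(),
                      overlap_bp = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$region_idx, res$interval_idx), , drop = FALSE]
}

# All-pairs nearest-TSS minimization with lexicographic tie-break.
oracle_nearest <- function(chrom, pos, genes, max_distance_bp = 1e6) {
  n <- length(pos)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- genes[genes$chrom == chrom[i], ]
    if (nrow(cand) == 0) next
    dd <- abs(pos[i] - cand$tss)
    dmin <- min(dd)
    if (dmin > max_distance_bp) next
    best <- cand[dd == dmin, ]
    best <- best[order(best$gene_id), ][1, ]
    gene[i] <- best$gene_id
    delta <- pos[i] - best$tss
    dist[i] <- if (best$strand == "-") -delta else delta
  }
  data.frame(gene_id = gene, distance_bp = dist, stringsAsFactors = FALSE)
}

# Exact hypergeometric upper tail by direct combinatorial enumeration.
oracle_hyper_tail <- function(k, K, N, n) {
  # P(X >= k) with X ~ Hypergeom(N, K, n)
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x) / total
  }, numeric(1)))
}

# Character-level PWM scan over all offsets and strands.
oracle_scan <- function(seqs, mat, background = rep(0.25, 4), threshold) {
  bases <- c("A", "C", "G", "T")
  L <- nrow(mat)
  revcomp <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  score_at <- function(chars, o) {
    sc <- 0
    for (i in seq_len(L)) {
      b <- match(chars[o + i - 1], bases)
      if (!is.na(b)) sc <- sc + log2(max(mat[i, b], 1e-10) / background[b])
    }
    sc
  }
  best_of <- function(s) {
    chars <- strsplit(s, "")[[1]]
    if (length(chars) < L) return(-Inf)
    max(vapply(seq_len(length(chars) - L + 1), function(o) score_at(chars, o),
               numeric(1)))
  }
  best <- pmax(vapply(seqs, best_of, numeric(1)),
               vapply(vapply(seqs, revcomp, character(1)), best_of, numeric(1)))
  data.frame(best_score = unname(best), hit = unname(best >= threshold))
}

# Tiny deterministic beta matrix around given per-sample values.
tiny_beta <- function(values, chrom = NULL, pos = NULL) {
  n <- nrow(values)
  annot <- data.frame(
    probe_id = sprintf("p%03d", seq_len(n)),
    chrom = chrom %||% rep("chr1", n),
    pos = pos %||% (seq_len(n) * 1000L),
    detection_p = 0, snp_at_cg = FALSE, cross_reactive = FALSE,
    stringsAsFactors = FALSE
  )
  beta_matrix(values, annot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
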