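#' Call differentially methylated regions by gap chaining
#'
#' Candidate probes (p below threshold) are chained along each chromosome:
#' a chain extends while the next candidate has the same effect sign and
#' lies within \code{max_gap_bp} of the previous one. Non-candidate probes
#' between candidates are ignored. A chain is reported as a DMR iff it has
#' at least \code{min_cpgs} members and at least one member with
#' \code{|delta_beta| > delta_threshold}. The region p-value is the
#' Stouffer combination of member p-values (two-sided, sign-aligned), and
#' coordinates are 0-based half-open spanning the member CpGs.
#'
#' @param stats a \code{dm_fit} (needs \code{chrom}, \code{pos},
#'   \code{delta_beta}, \code{p}).
#' @param max_gap_bp maximum gap between consecutive member CpGs, default
#'   1000.
#' @param min_cpgs minimum members per region, default 3.
#' @param p_threshold candidate probe p cut-off, default 0.05.
#' @param delta_threshold delta-beta a region must reach in at least one
#'   member, default 0.05.
#' @return data frame of class \code{dmr_result}: \code{chrom},
#'   \code{start}, \code{end}, \code{n_cpgs}, \code{region_p},
#'   \code{max_abs_delta}, \code{direction}, \code{probe_ids}
#'   (comma-separated, position order).
#' @export
call_dmrs <- function(stats, max_gap_bp = 1000, min_cpgs = 3,
                      p_threshold = 0.05, delta_threshold = 0.05) {
  need <- c("feature_id", "chrom", "pos", "delta_beta", "p")
  miss <- setdiff(need, names(stats))
  if (length(miss)) stop("stats lack columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(stats)[, need]
  ord <- order(x$chrom, x$pos)
  if (!identical(ord, seq_len(nrow(x)))) {
    warning("probes were not position-sorted; sorting internally")
    x <- x[ord, ]
  }
  cand <- x[x$p < p_threshold & x$delta_beta != 0, , drop = FALSE]
  regions <- list()
  for (ch in unique(cand$chrom)) {
    cc <- cand[cand$chrom == ch, , drop = FALSE]
    if (nrow(cc) == 0) next
    sgn <- sign(cc$delta_beta)
    new_chain <- c(TRUE, diff(cc$pos) > max_gap_bp | diff(sgn) != 0)
    chain_id <- cumsum(new_chain)
    for (g in split(seq_len(nrow(cc)), chain_id)) {
      if (length(g) < min_cpgs) next
      mem <- cc[g, , drop = FALSE]
      if (!any(abs(mem$delta_beta) > delta_threshold)) next
      z <- qnorm(1 - mem$p / 2)
      zc <- sum(z) / sqrt(nrow(mem))
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = min(mem$pos), end = max(mem$pos) + 1L,
        n_cpgs = nrow(mem),
        region_p = 2 * pnorm(-zc),
        max_abs_delta = max(abs(mem$delta_beta)),
        direction = if (sign(mem$delta_beta[1]) > 0) "GAIN" else "LOSS",
        probe_ids = paste(mem$feature_id, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpgs = integer(), region_p = numeric(),
               max_abs_delta = numeric(), direction = character(),
               probe_ids = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("dmr_result", "data.frame")
  attr(out, "parameters") <- c(max_gap_bp = max_gap_bp, min_cpgs = min_cpgs,
                               p = p_threshold, delta = delta_threshold)
  out
}

#' Intersect regions with intervals
#'
#' Reports every (region, interval) pair overlapping by at least 1 bp, with
#' the overlap width. Both inputs use 0-based half-open coordinates, so
#' abutting features ([100,200) vs [200,300)) do not overlap.
#'
#' @param regions data frame with \code{chrom}, \code{start}, \code{end}
#'   (e.g. a \code{dmr_result}).
#' @param intervals data frame with \code{chrom}, \code{start}, \code{end}
#'   and optionally \code{name}.
#' @return data frame: \code{region_idx}, \code{interval_idx} (row indices
#'   into the inputs), \code{chrom}, \code{overlap_bp}.
#' @export
intersect_regions <- function(regions, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(regions$end <= regions$start) || any(intervals$end <= intervals$start)) {
    stop("intervals must satisfy start < end (0-based half-open)")
  }
  hits <- list()
  for (ch in intersect(unique(regions$chrom), unique(intervals$chrom))) {
    ri <- which(regions$chrom == ch)
    ii <- which(intervals$chrom == ch)
    # IRanges is 1-based closed; [start, end) maps to start+1 .. end
    r <- IRanges::IRanges(start = regions$start[ri] + 1L, end = regions$end[ri])
    q <- IRanges::IRanges(start = intervals$start[ii] + 1L, end = intervals$end[ii])
    ov <- IRanges::findOverlaps(r, q, minoverlap = 1L)
    if (length(ov) == 0) next
    rr <- ri[S4Vectors::queryHits(ov)]
    qq <- ii[S4Vectors::subjectHits(ov)]
    hits[[length(hits) + 1L]] <- data.frame(
      region_idx = rr, interval_idx = qq, chrom = ch,
      overlap_bp = pmin(regions$end[rr], intervals$end[qq]) -
        pmax(regions$start[rr], intervals$start[qq]),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(hits)) do.call(rbind, hits) else {
    data.frame(region_idx = integer(), interval_idx = integer(),
               chrom = character(), overlap_bp = integer(),
               stringsAsFactors = FALSE)
  }
  stopifnot(all(out$overlap_bp >= 1))
  out[order(out$region_idx, out$interval_idx), , drop = FALSE]
}
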