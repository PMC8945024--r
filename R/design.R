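#' Build the study design for a stimulation time course
#'
#' Constructs the full sample sheet for the two-assay design: untreated cells
#' collected at attachment (the 0 h control, treatment \code{ZERO_H}) plus
#' four arms (\code{RPMI}, \code{T3}, \code{LPS}, \code{T3_LPS}) profiled at
#' the later timepoints. RNA samples exist at 0, 4 and 24 h; methylation
#' samples only at 0 and 24 h, matching an array design where the early
#' timepoint is not assayed.
#'
#' @param n_donors number of donors (biological replicates), >= 1.
#' @param timepoints set of hours profiled; subset of \code{c(0, 4, 24)}.
#' @return A data frame of class \code{study_design} with columns
#'   \code{sample_id}, \code{donor_id}, \code{treatment}, \code{timepoint_h},
#'   \code{assay}, in deterministic order (assay, timepoint, treatment, donor).
#' @examples
#' d <- build_design(3)
#' table(d$assay) # 15 METH, 27 RNA
#' @export
build_design <- function(n_donors, timepoints = c(0, 4, 24)) {
  if (length(timepoints) == 0) {
    stop("invalid design: 'timepoints' must be non-empty", call. = FALSE)
  }
  if (!is.numeric(n_donors) || n_donors < 1) {
    stop("invalid design: 'n_donors' must be >= 1", call. = FALSE)
  }
  n_donors <- as.integer(n_donors)
  timepoints <- sort(unique(as.numeric(timepoints)))
  if (!all(timepoints %in% c(0, 4, 24))) {
    stop("invalid design: timepoints must be a subset of {0, 4, 24}",
         call. = FALSE)
  }
  assay_tp <- list(METH = c(0, 24), RNA = c(0, 4, 24))
  rows <- list()
  donors <- sprintf("D%d", seq_len(n_donors))
  for (assay in names(assay_tp)) {
    tps <- intersect(timepoints, assay_tp[[assay]])
    for (tp in tps) {
      arms <- if (tp == 0) "ZERO_H" else STIM_ARMS
      for (arm in arms) {
        rows[[length(rows) + 1L]] <- data.frame(
          donor_id = donors,
          treatment = arm,
          timepoint_h = tp,
          assay = assay,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  design <- do.call(rbind, rows)
  design$sample_id <- sprintf(
    "%s_%s_%sh_%s", design$donor_id, design$treatment,
    design$timepoint_h, design$assay
  )
  design <- design[, c("sample_id", "donor_id", "treatment", "timepoint_h", "assay")]
  rownames(design) <- NULL
  stopifnot(!anyDuplicated(design$sample_id))
  class(design) <- c("study_design", "data.frame")
  design
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(unique(x$donor_id)), "donors,",
      nrow(x), "samples\n")
  tab <- table(x$assay, paste0(x$treatment, "@", x$timepoint_h, "h"))
  print(tab)
  invisible(x)
}

## Subset helper: samples of one assay at one (arm, timepoint) cell.
## ZERO_H is pinned to timepoint 0 whatever timepoint the comparison uses.
design_samples <- function(design, assay, treatment, timepoint_h) {
  tp <- if (treatment == "ZERO_H") 0 else timepoint_h
  d <- design[design$assay == assay & design$treatment == treatment &
                design$timepoint_h == tp, , drop = FALSE]
  d[order(d$donor_id), , drop = FALSE]
}
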