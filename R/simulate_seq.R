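#' Simulate probe-centered sequence windows with an embedded motif
#'
#' Generates one random sequence of length \code{2 * window_bp + 1} per probe
#' (the window from -window_bp to +window_bp around the CpG). The motif
#' consensus is embedded at a random offset, on a random strand, in a stated
#' fraction of target probes and of background probes, so motif-enrichment
#' recovery can be tested against a known planted enrichment.
#'
#' @param probe_annot probe annotation data frame (needs \code{probe_id}).
#' @param window_bp half-window size in bp; default 100 (201 bp sequences).
#' @param planted_motif consensus string over A/C/G/T embedded in sequences.
#' @param target_ids character vector of probe_ids forming the target set.
#' @param target_fraction fraction of target probes receiving the motif.
#' @param background_fraction fraction of non-target probes receiving it.
#' @param seed integer seed.
#' @return named character vector of sequences (names = probe_ids), with
#'   attribute \code{embedded}: logical, whether the motif was planted.
#' @export
simulate_sequences <- function(probe_annot, window_bp = 100,
                               planted_motif = "TGACGTCA",
                               target_ids = character(),
                               target_fraction = 0.5,
                               background_fraction = 0.05,
                               seed = 1L) {
  if (target_fraction < 0 || target_fraction > 1 ||
      background_fraction < 0 || background_fraction > 1) {
    stop("motif fractions must lie in [0, 1]")
  }
  motif <- toupper(planted_motif)
  if (!grepl("^[ACGT]+$", motif)) stop("planted_motif must be over A/C/G/T")
  len <- 2L * as.integer(window_bp) + 1L
  if (len <= nchar(motif)) stop("window must be longer than the motif")

  set.seed(as.integer(seed))
  n <- nrow(probe_annot)
  is_target <- probe_annot$probe_id %in% target_ids
  embed <- ifelse(is_target,
                  runif(n) < target_fraction,
                  runif(n) < background_fraction)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(bases, len, replace = TRUE)
    if (embed[i]) {
      m <- strsplit(motif, "")[[1]]
      if (runif(1) < 0.5) m <- rev(chartr("ACGT", "TGCA", m))
      off <- sample.int(len - length(m) + 1L, 1L)
      s[off:(off + length(m) - 1L)] <- m
    }
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- probe_annot$probe_id
  attr(seqs, "embedded") <- embed
  seqs
}
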