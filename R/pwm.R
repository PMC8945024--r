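#' Construct a position weight matrix
#'
#' @param mat numeric matrix, positions x 4, columns A, C, G, T; each row
#'   sums to 1 (within 1e-6). At least 4 positions.
#' @param motif_id motif identifier.
#' @param tf_gene_id gene id of the transcription factor the motif belongs
#'   to (used by the expression-based exclusion filter).
#' @param background base frequencies, default uniform.
#' @param threshold absolute log-odds hit threshold; when \code{NULL} it is
#'   set to \code{threshold_frac} of the maximum attainable score.
#' @param threshold_frac fraction of the maximum score used when
#'   \code{threshold} is NULL, default 0.8.
#' @return object of class \code{pwm}.
#' @export
pwm <- function(mat, motif_id, tf_gene_id = motif_id,
                background = rep(0.25, 4), threshold = NULL,
                threshold_frac = 0.8) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(mat) < 4) stop("PWM must have at least 4 positions")
  if (any(abs(rowSums(mat) - 1) > 1e-6)) stop("PWM rows must sum to 1")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 base frequencies summing to 1")
  }
  colnames(mat) <- c("A", "C", "G", "T")
  lo <- log2(pmax(mat, 1e-10) / rep(background, each = nrow(mat)))
  max_score <- sum(apply(lo, 1, max))
  if (is.null(threshold)) threshold <- threshold_frac * max_score
  structure(
    list(motif_id = motif_id, tf_gene_id = tf_gene_id, mat = mat,
         background = background, threshold = threshold,
         max_score = max_score, logodds = lo),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (TF %s): %d positions, threshold %.2f (max %.2f)\n",
              x$motif_id, x$tf_gene_id, nrow(x$mat), x$threshold, x$max_score))
  invisible(x)
}

#' Build a PWM from a consensus sequence
#'
#' @param consensus string over A/C/G/T.
#' @param p probability mass on the consensus base per position (rest spread
#'   evenly), default 0.85.
#' @param ... passed to [pwm()].
#' @return a \code{pwm}.
#' @export
consensus_to_pwm <- function(consensus, p = 0.85, ...) {
  b <- strsplit(toupper(consensus), "")[[1]]
  if (!all(b %in% c("A", "C", "G", "T"))) stop("consensus must be over A/C/G/T")
  mat <- matrix((1 - p) / 3, length(b), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  mat[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- p
  pwm(mat, ...)
}

encode_seq <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L # N and anything else scores as background
  v
}

#' Scan sequences with a PWM
#'
#' Scores every offset on both strands with log-odds scoring (positions with
#' N contribute 0, i.e. background). A sequence is a hit iff its best score
#' is at least the PWM threshold. Sequences shorter than the motif are not
#' hits and are counted in a message.
#'
#' @param sequences named character vector of A/C/G/T/N sequences.
#' @param x a [pwm()].
#' @return data frame: \code{seq_id}, \code{best_score}, \code{hit}.
#' @export
scan_pwm <- function(sequences, x) {
  stopifnot(inherits(x, "pwm"))
  L <- nrow(x$mat)
  lo5 <- cbind(x$logodds, 0)
  comp <- c(4L, 3L, 2L, 1L, 5L)
  pos_idx <- seq_len(L)
  short <- 0L
  best <- vapply(sequences, function(s) {
    enc <- encode_seq(s)
    n <- length(enc)
    if (n < L) {
      short <<- short + 1L
      return(-Inf)
    }
    rc <- rev(comp[enc])
    score_strand <- function(e) {
      max(vapply(0:(n - L), function(o) {
        sum(lo5[cbind(pos_idx, e[o + pos_idx])])
      }, numeric(1)))
    }
    max(score_strand(enc), score_strand(rc))
  }, numeric(1))
  if (short > 0) {
    message("scan_pwm: ", short, " sequence(s) shorter than the motif")
  }
  data.frame(
    seq_id = names(sequences) %||% as.character(seq_along(sequences)),
    best_score = unname(best),
    hit = unname(best >= x$threshold),
    stringsAsFactors = FALSE
  )
}

#' Write PWMs in a HOMER-style text format
#'
#' One record per motif: a header line
#' \code{">consensus<TAB>motif_id/tf_gene_id<TAB>threshold"} followed by one
#' line of 4 tab-separated base probabilities per position.
#'
#' @param pwms list of [pwm()] objects.
#' @param path output file.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (x in pwms) {
    cons <- paste(c("A", "C", "G", "T")[apply(x$mat, 1, which.max)],
                  collapse = "")
    writeLines(sprintf(">%s\t%s/%s\t%.6g", cons, x$motif_id, x$tf_gene_id,
                       x$threshold), con)
    utils::write.table(format(x$mat, digits = 6), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read PWMs from the HOMER-style text format written by [write_pwms()]
#'
#' @param path motif file.
#' @return list of [pwm()] objects keyed by motif_id.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif records in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[k]]), "\t")[[1]]
    name <- strsplit(hdr[2], "/", fixed = TRUE)[[1]]
    body <- lines[(starts[k] + 1L):ends[k]]
    body <- body[nzchar(body)]
    mat <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
    mat <- mat / rowSums(mat) # guard rounding in the text representation
    out[[name[1]]] <- pwm(mat, motif_id = name[1],
                          tf_gene_id = if (length(name) > 1) name[2] else name[1],
                          threshold = as.numeric(hdr[3]))
  }
  out
}
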