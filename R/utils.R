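#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rnbinom rbinom median sd var prcomp qnorm
#'   pnorm pt phyper p.adjust ks.test complete.cases setNames quantile
#' @importFrom utils write.table read.table
NULL

TREATMENTS <- c("ZERO_H", "RPMI", "T3", "LPS", "T3_LPS")
STIM_ARMS <- c("RPMI", "T3", "LPS", "T3_LPS")

EFFECT_CLASSES <- c(
  "NULL", "DIFFERENTIATION", "DIFF_ATTENUATED_BY_T3", "T3_SPECIFIC",
  "LPS_INDUCED", "LPS_ATTENUATED_BY_T3LPS", "T3LPS_UNIQUE"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a beta value to an M-value
#'
#' The M-value is the log2-odds of methylation, \code{log2(beta/(1 - beta))}.
#' Betas are clipped into \code{[eps, 1 - eps]} first so the transform is
#' defined at simulated extremes.
#'
#' @param beta numeric vector/matrix of methylation fractions in \code{[0, 1]}.
#' @param eps clipping epsilon applied before the logit, default \code{1e-6}.
#' @return numeric of the same shape as \code{beta}.
#' @examples
#' beta_to_m(0.5) # 0
#' beta_to_m(0.8) # 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert an M-value back to a beta value
#'
#' Algebraic inverse of [beta_to_m()].
#'
#' @param m numeric vector/matrix of M-values (log2-odds).
#' @return methylation fractions in \code{(0, 1)}.
#' @export
m_to_beta <- function(m) {
  x <- 2^m
  x / (1 + x)
}

## FNV-1a 64-bit-ish hash over a character scalar, returned as hex.
## Used to stamp a provenance hash of the configuration into outputs;
## implemented here because no hashing dependency is required elsewhere.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  # 32-bit modular multiply split into 16-bit halves (doubles stay < 2^53)
  mulmod <- function(a, b) {
    lo <- a %% 65536
    hi <- a %/% 65536
    ((lo * b) %% 4294967296 + ((hi * b) %% 65536) * 65536) %% 4294967296
  }
  # xor with a byte touches only the low 8 bits
  xor8 <- function(h, b) h - (h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
  h1 <- 2166136261
  h2 <- 1566083941
  for (b in bytes) {
    h1 <- mulmod(xor8(h1, b), 16777619)
    h2 <- mulmod(xor8(h2, b), 33554467)
  }
  tohex8 <- function(v) {
    paste(format.hexmode(as.integer((v %/% 16^(7:0)) %% 16)), collapse = "")
  }
  paste0(tohex8(h1), tohex8(h2))
}

## Deterministic "x/y (z%)" formatter mirroring in-text count reporting.
## One decimal place; round() gives round-half-even behaviour.
format_fraction <- function(x, y, digits = 1L) {
  pct <- if (y > 0) round(100 * x / y, digits) else 0
  sprintf("%d/%d (%s%%)", as.integer(x), as.integer(y), format(pct))
}

## Shared checked accessor: named list element must exist.
must_have <- function(lst, name, what) {
  if (!name %in% names(lst)) {
    stop(what, " is missing required element '", name, "'", call. = FALSE)
  }
  lst[[name]]
}

## Inverse trigamma by Newton iteration on log-scale (monotone, convex).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}
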