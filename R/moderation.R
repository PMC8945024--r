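#' Empirical-Bayes moderation of per-feature variances
#'
#' Shrinks each feature's residual variance toward a common prior using the
#' standard posterior formula
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}
#' and recomputes the t-statistic with \eqn{d_0 + d} degrees of freedom.
#' The prior \eqn{(d_0, s_0^2)} is estimated from the marginal distribution
#' of the residual variances by moment matching on \eqn{\log s^2} (under the
#' scaled-F marginal, the variance of \eqn{\log s^2} in excess of
#' \eqn{\psi'(d/2)} identifies \eqn{d_0} through the trigamma function, and
#' the mean identifies \eqn{s_0^2}). When the excess variance is
#' non-positive the prior df is infinite and every posterior variance
#' collapses to \eqn{s_0^2}.
#'
#' @param fit a \code{dm_fit} / \code{de_fit} from the per-feature model
#'   fitters.
#' @param prior_df optional fixed \eqn{d_0} (0 = no shrinkage; \code{Inf} =
#'   complete pooling); \code{NULL} (default) estimates it.
#' @param prior_var optional fixed \eqn{s_0^2}; \code{NULL} estimates it.
#' @return the fit with moderated \code{t}, \code{p} (and \code{p_adj}),
#'   extra columns \code{s2_post} and \code{df_total}, and attributes
#'   \code{prior_df} and \code{prior_var}.
#' @export
moderate_variance <- function(fit, prior_df = NULL, prior_var = NULL) {
  s2 <- fit$s2
  d <- fit$df
  cvu <- attr(fit, "coef_var_unit")
  if (is.null(cvu)) stop("fit lacks the coef_var_unit attribute")
  usable <- is.finite(s2) & s2 > 0
  if (!any(usable)) {
    warning("all residual variances are zero; moderation skipped")
    return(fit)
  }
  if (is.null(prior_df) || is.null(prior_var)) {
    est <- fit_f_dist(s2[usable], d)
    if (is.null(prior_df)) prior_df <- est$df
    if (is.null(prior_var)) prior_var <- est$var
  }
  d0 <- prior_df
  s0 <- prior_var
  s2_post <- if (is.infinite(d0)) {
    rep(s0, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0 + d * s2) / (d0 + d)
  }
  df_total <- d + d0
  tstat <- fit$effect / sqrt(s2_post * cvu)
  p <- ifelse(is.infinite(df_total),
              2 * pnorm(-abs(tstat)),
              2 * pt(-abs(tstat), pmin(df_total, 1e300)))
  # constant features keep their null identity
  const <- s2 == 0 & fit$effect == 0
  tstat[const] <- 0
  p[const] <- 1
  fit$t <- unname(tstat)
  fit$p <- unname(p)
  fit$p_adj <- p.adjust(fit$p, "BH")
  fit$s2_post <- unname(s2_post)
  fit$df_total <- df_total
  attr(fit, "moderated") <- TRUE
  attr(fit, "prior_df") <- d0
  attr(fit, "prior_var") <- s0
  fit
}

## Moment matching of a scaled F marginal for s^2 on the log scale.
## Closed-form fallback (infinite prior df) when the observed log-variance
## spread does not exceed what the residual df alone implies.
fit_f_dist <- function(s2, df) {
  z <- log(s2)
  # degenerate spread: every variance identical; the only consistent prior
  # is that common value with infinite df
  if (var(z) < 1e-12) return(list(df = Inf, var = exp(mean(z))))
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(z) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    if (!is.finite(d0) || !is.finite(s0)) {
      d0 <- Inf
      s0 <- exp(mean(e))
    }
  } else {
    d0 <- Inf
    s0 <- exp(mean(e))
  }
  list(df = d0, var = s0)
}
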