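#' Moderated t-statistics for one-vs-rest differential methylation
#'
#' Computes, for every locus, the mean beta difference between one subgroup
#' and all remaining samples, together with an empirical Bayes moderated
#' t-statistic. Per-locus pooled sample variances \eqn{s_g^2} (with
#' \eqn{d = n_1 + n_2 - 2} degrees of freedom) are shrunk towards a common
#' prior: under the scaled-inverse-chi-squared model
#' \eqn{s_g^2 | \sigma_g^2 \sim \sigma_g^2 \chi^2_d / d},
#' \eqn{1/\sigma_g^2 \sim \chi^2_{d_0} / (d_0 s_0^2)}, the posterior
#' variance is \deqn{\tilde s_g^2 = (d_0 s_0^2 + d s_g^2) / (d_0 + d)}
#' and the moderated statistic
#' \eqn{\tilde t_g = \Delta\beta_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})}
#' is referred to a t distribution on \eqn{d + d_0} degrees of freedom.
#' The hyperparameters \eqn{(d_0, s_0^2)} are fitted by moment-matching
#' the marginal distribution of \eqn{\log s_g^2} across loci. Two-sided
#' p-values are Benjamini-Hochberg adjusted.
#'
#' @param beta a [beta_matrix()] (no missing values at tested loci).
#' @param labels subgroup label per sample.
#' @param subgroup the subgroup forming the "one" side of the contrast.
#' @param prior_df optional override for \eqn{d_0}: `0` gives the ordinary
#'   two-sample t; `Inf` gives complete shrinkage to \eqn{s_0^2}.
#' @param prior_var optional override for \eqn{s_0^2} (only used together
#'   with a `prior_df` override).
#' @return a data.frame of class `locus_stats` with columns `locus_id`,
#'   `subgroup`, `mean_difference`, `ordinary_s2`, `moderated_s2`,
#'   `prior_df`, `prior_var`, `moderated_t`, `p_value`, `adjusted_p`,
#'   sorted by `|moderated_t|` descending (ties by locus id).
#' @export
moderated_t_stats <- function(beta, labels, subgroup,
                              prior_df = NULL, prior_var = NULL) {
  labels <- as.character(labels)
  if (length(labels) != nrow(beta))
    stop("one label per sample required")
  if (!subgroup %in% labels) stop(sprintf("subgroup '%s' not present", subgroup))
  in_g <- labels == subgroup
  n1 <- sum(in_g); n2 <- sum(!in_g)
  if (n1 < 2L || n2 < 2L)
    stop("need at least two samples in the subgroup and in the rest")
  x <- unclass_beta(beta)
  if (anyNA(x)) stop("missing values present; impute or filter loci first")

  m1 <- colMeans(x[in_g, , drop = FALSE])
  m2 <- colMeans(x[!in_g, , drop = FALSE])
  v1 <- apply(x[in_g, , drop = FALSE], 2L, var)
  v2 <- apply(x[!in_g, , drop = FALSE], 2L, var)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d

  if (is.null(prior_df)) {
    if (all(s2 <= 0))
      stop("degenerate fit: all per-locus variances are zero")
    fit <- fit_s2_prior(s2, d)
    d0 <- fit$prior_df; s02 <- fit$prior_var
  } else {
    d0 <- prior_df
    s02 <- if (!is.null(prior_var)) prior_var
           else if (is.finite(d0) && d0 == 0) 0
           else fit_s2_prior(s2, d)$prior_var
  }

  s2_mod <- if (is.infinite(d0)) rep(s02, length(s2))
            else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  df_total <- d + d0
  pval <- 2 * pt(-abs(tstat), df = df_total)

  out <- data.frame(locus_id = colnames(beta),
                    subgroup = subgroup,
                    mean_difference = m1 - m2,
                    ordinary_s2 = s2,
                    moderated_s2 = s2_mod,
                    prior_df = d0,
                    prior_var = s02,
                    moderated_t = tstat,
                    p_value = pval,
                    adjusted_p = p.adjust(pval, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$moderated_t), out$locus_id), ]
  rownames(out) <- NULL
  class(out) <- c("locus_stats", "data.frame")
  out
}

## Moment-match the scaled-inverse-chi-squared variance prior on the log
## scale: with z_g = log s_g^2 and e_g = z_g - digamma(d/2) + log(d/2),
## E e = log s0^2 + digamma(d0/2) - log(d0/2) and
## Var e = trigamma(d/2) + trigamma(d0/2).
fit_s2_prior <- function(s2, d) {
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(prior_df = d0, prior_var = s02)
}

## Newton solve trigamma(x) = y on x > 0.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}
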