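#' @keywords internal
#' Invert the trigamma function by Newton iteration on 1/psi'(y).
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 50L) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < tol * y) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-probe residual variances toward a prior using the scaled-F
#' model: s2 ~ s0^2(A) * F(d, d0) marginally, with hyperparameters estimated
#' by moment matching on the log scale (digamma/trigamma corrections). With
#' `trend = TRUE` the prior variance is an intensity-dependent curve fitted by
#' lowess of the corrected log variances on average log2 level A,
#' accommodating the intensity-dependent variance typical of RPPA. With
#' `robust = TRUE` the log-variance residuals are winsorised before moment
#' matching and probes beyond the upper winsorisation limit receive a reduced
#' per-probe prior df so that genuinely hypervariable probes are not
#' over-shrunk.
#'
#' If all residual variances are identical the prior df is infinite and every
#' posterior variance equals the prior curve; total df is then capped at a
#' large sentinel (1e6) for t quantiles.
#'
#' @param fit An `rppa_fit` (or any list with `sigma2`, `df_residual`,
#'   `amean`).
#' @param trend Fit an intensity-dependent prior-variance curve.
#' @param robust Winsorised, outlier-protecting hyperparameter estimation.
#' @param span Lowess span for the trend curve.
#' @param winsor Lower/upper winsorisation quantiles used when `robust`.
#' @param prior_df Optional fixed prior df overriding estimation (0 gives the
#'   unmoderated classical fit; `Inf` gives full shrinkage to the prior).
#' @return The fit augmented to class `rppa_modfit` with `prior_df` (scalar
#'   estimate), `prior_df_probe` (per-probe, reduced for robust outliers),
#'   `prior_var` (s0^2 evaluated per probe), `post_var` (posterior variances)
#'   and `df_total`.
#' @export
ebayes_moderate <- function(fit, trend = TRUE, robust = TRUE, span = 0.4,
                            winsor = c(0.05, 0.95), prior_df = NULL) {
  s2 <- fit$sigma2
  df <- fit$df_residual
  A <- fit$amean
  ok <- is.finite(s2) & df > 0
  if (sum(ok) < 10 && is.null(prior_df))
    stop("need >= 10 probes with residual df > 0 to estimate the prior")
  s2f <- pmax(s2, 1e-10)
  z <- log(s2f)
  e <- z - digamma(df / 2) + log(df / 2)
  # prior-variance location: constant or intensity-dependent curve
  if (trend) {
    lo <- stats::lowess(A[ok], e[ok], f = span)
    cA <- stats::approx(lo$x, lo$y, xout = A, rule = 2, ties = mean)$y
  } else {
    cA <- rep(mean(e[ok]), length(e))
  }
  resid <- e - cA
  used <- resid[ok]
  if (robust) {
    lim <- stats::quantile(used, winsor, names = FALSE)
    used_w <- pmin(pmax(used, lim[1]), lim[2])
  } else {
    used_w <- used
  }
  loc <- mean(used_w)
  evar <- stats::var(used_w) - mean(trigamma(df[ok] / 2))
  if (!is.null(prior_df)) {
    d0 <- prior_df
  } else if (is.finite(evar) && evar > 1e-10) {
    d0 <- 2 * trigamma_inverse(evar)
  } else {
    d0 <- Inf
  }
  corr <- if (is.finite(d0) && d0 > 0) digamma(d0 / 2) - log(d0 / 2) else 0
  prior_var <- exp(cA + loc + corr)
  d0_probe <- rep(d0, length(s2))
  if (robust && is.finite(d0) && d0 > 0) {
    lim_hi <- stats::quantile(used, winsor[2], names = FALSE)
    exceed <- pmax(resid - loc - (lim_hi - loc), 0)
    vartot <- max(stats::var(used_w), 1e-8)
    out <- ok & exceed > 0
    # hypervariable probes keep more of their own variance
    d0_probe[out] <- pmax(d0 / (1 + exceed[out]^2 / vartot), 0.5)
  }
  if (!is.null(prior_df)) d0_probe <- rep(prior_df, length(s2))
  post_var <- ifelse(is.finite(d0_probe),
                     (d0_probe * prior_var + df * s2) / (d0_probe + df),
                     prior_var)
  if (any(i <- d0_probe == 0)) post_var[i] <- s2[i]
  df_total <- pmin(df + d0_probe, 1e6)
  fit$prior_df <- d0
  fit$prior_df_probe <- d0_probe
  fit$prior_var <- prior_var
  fit$post_var <- post_var
  fit$df_total <- df_total
  fit$trend <- trend
  fit$robust <- robust
  class(fit) <- c("rppa_modfit", class(fit))
  fit
}

#' Apply a contrast to a moderated fit
#'
#' Computes the log2 fold-change c' mu, its moderated standard error,
#' moderated t-statistic, two-sided p on the total (residual + prior) degrees
#' of freedom, per-contrast Benjamini-Hochberg FDR, and a confidence interval
#' from the moderated standard errors. Second-order "shift" contrasts such as
#' (perturbed+stimulus - perturbed) - (stimulus - untreated) are expressed
#' through the same coefficient vector.
#'
#' @param modfit An `rppa_modfit` from [ebayes_moderate()].
#' @param contrast Named numeric vector of coefficients over (a subset of) the
#'   fitted groups; difference contrasts sum to 0.
#' @param contrast_id Label stored with the result.
#' @param alpha Two-sided CI level is `1 - alpha` (default 95%).
#' @return Data.frame of class `rppa_contrast` with columns `probe_id, lfc,
#'   se, t, p, fdr, ci_low, ci_high, avg_expr, df_total`.
#' @export
apply_contrast <- function(modfit, contrast, contrast_id = NULL, alpha = 0.05) {
  if (!inherits(modfit, "rppa_modfit"))
    stop("run ebayes_moderate() before apply_contrast()")
  groups <- colnames(modfit$group_means)
  if (is.null(names(contrast))) {
    if (length(contrast) != length(groups))
      stop("unnamed contrast must cover all ", length(groups), " groups")
    names(contrast) <- groups
  }
  bad <- setdiff(names(contrast), groups)
  if (length(bad))
    stop("contrast references unfitted group(s): ", paste(bad, collapse = ", "))
  cvec <- stats::setNames(rep(0, length(groups)), groups)
  cvec[names(contrast)] <- contrast
  lfc <- drop(modfit$group_means %*% cvec)
  # unscaled variance of the contrast: sum c_g^2 / (effective group weight)
  u2 <- drop((1 / modfit$group_wsum) %*% cvec^2)
  se <- sqrt(modfit$post_var * u2)
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df = modfit$df_total)
  fdr <- adjust_bh(p)
  q <- stats::qt(1 - alpha / 2, df = modfit$df_total)
  out <- data.frame(
    probe_id = rownames(modfit$group_means),
    lfc = lfc, se = se, t = tstat, p = p, fdr = fdr,
    ci_low = lfc - q * se, ci_high = lfc + q * se,
    avg_expr = modfit$amean, df_total = modfit$df_total,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "contrast_id") <- if (is.null(contrast_id))
    paste(names(contrast)[contrast != 0], collapse = "/") else contrast_id
  attr(out, "coefficients") <- cvec
  class(out) <- c("rppa_contrast", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment applied per contrast. Missing p-values are
#' propagated as `NA` and excluded from the number of tests.
#'
#' @param p Vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted values, monotone and capped at 1.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Count differentially expressed probes by direction
#'
#' @param result An `rppa_contrast`.
#' @param threshold FDR cutoff (strict `<`), default 0.05.
#' @return Named integer vector `c(n_up, n_down, n_total)`; probes with lfc
#'   exactly 0 count as neither direction.
#' @export
count_de <- function(result, threshold = 0.05) {
  sig <- !is.na(result$fdr) & result$fdr < threshold
  n_up <- sum(sig & result$lfc > 0)
  n_down <- sum(sig & result$lfc < 0)
  c(n_up = n_up, n_down = n_down, n_total = n_up + n_down)
}

#' Directional overlap of two differential-expression results
#'
#' Partitions the union of the two DE sets by sign agreement, the tabular twin
#' of a two-set directional Venn diagram.
#'
#' @param resA,resB `rppa_contrast` results over the same probe universe.
#' @param threshold FDR cutoff defining DE (strict `<`).
#' @return Named integer vector
#'   `c(up_up, down_down, opposite, onlyA, onlyB)`.
#' @export
directional_overlap <- function(resA, resB, threshold = 0.05) {
  if (!setequal(resA$probe_id, resB$probe_id))
    stop("results are over different probe universes")
  b <- resB[match(resA$probe_id, resB$probe_id), ]
  deA <- !is.na(resA$fdr) & resA$fdr < threshold & resA$lfc != 0
  deB <- !is.na(b$fdr) & b$fdr < threshold & b$lfc != 0
  both <- deA & deB
  sA <- sign(resA$lfc); sB <- sign(b$lfc)
  c(up_up = sum(both & sA > 0 & sB > 0),
    down_down = sum(both & sA < 0 & sB < 0),
    opposite = sum(both & sA * sB < 0),
    onlyA = sum(deA & !deB),
    onlyB = sum(deB & !deA))
}
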