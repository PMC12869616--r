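#' Cell-means design specification
#'
#' Builds the samples x groups 0/1 incidence matrix for a cell-means
#' parameterisation (one coefficient per treatment group, no intercept), with
#' optional per-sample precision weights. Every fitted group must have at
#' least two samples.
#'
#' @param group Character/factor vector of group labels, one per sample.
#' @param sample_ids Sample identifiers (default names of `group` or s1..sn).
#' @param weights Positive per-sample precision weights (default 1).
#' @return List of class `rppa_design`: `groups`, `incidence`, `weights`.
#' @export
design_spec <- function(group, sample_ids = NULL, weights = NULL) {
  group <- as.character(group)
  n <- length(group)
  if (is.null(sample_ids)) sample_ids <- names(group)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  lev <- unique(group)
  tab <- table(factor(group, levels = lev))
  if (any(tab < 2)) stop("every fitted group needs >= 2 samples: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive finite, one per sample")
  inc <- outer(group, lev, "==") + 0
  dimnames(inc) <- list(sample_ids, lev)
  structure(list(groups = lev, incidence = inc,
                 weights = stats::setNames(weights, sample_ids)),
            class = "rppa_design")
}

#' Fit per-probe cell-means linear models
#'
#' Weighted least squares of each probe's log2 level on the treatment groups
#' (cell-means coding), the first stage of the moderated analysis. Probes with
#' missing values lose those samples for that probe only; the residual degrees
#' of freedom are tracked per probe.
#'
#' @param x `rppa_expression` object or log2 matrix with sample columns
#'   matching the design.
#' @param design An `rppa_design` from [design_spec()].
#' @return List of class `rppa_fit`: `group_means` (probes x groups), `sigma2`
#'   (residual variance), `df_residual`, `amean` (weighted average log2 level),
#'   `group_wsum` (probes x groups effective weight totals, for contrast
#'   standard errors), `n_dropped` (samples dropped per probe), plus the
#'   design.
#' @export
fit_cellmeans <- function(x, design) {
  v <- expr_values(x)
  sid <- rownames(design$incidence)
  if (!all(sid %in% colnames(v)))
    stop("design samples missing from expression matrix: ",
         paste(setdiff(sid, colnames(v)), collapse = ", "))
  v <- v[, sid, drop = FALSE]
  w <- design$weights
  inc <- design$incidence
  g <- ncol(inc)
  obs <- !is.na(v)                       # probes x samples
  wobs <- sweep(obs + 0, 2L, w, "*")     # observed weight per cell
  v0 <- v; v0[!obs] <- 0
  group_wsum <- wobs %*% inc                       # probes x groups
  if (any(group_wsum == 0))
    stop("some probe has a group with no observed samples; drop such probes first")
  group_means <- (sweep(v0, 2L, w, "*") %*% inc) / group_wsum
  fitted <- group_means %*% t(inc)
  r <- v - fitted
  r[!obs] <- 0
  wrss <- rowSums(sweep(r^2, 2L, w, "*"))
  n_obs <- rowSums(obs)
  df <- n_obs - g
  if (all(df <= 0)) stop("no residual degrees of freedom (n - groups <= 0)")
  sigma2 <- ifelse(df > 0, wrss / df, NA_real_)
  amean <- rowSums(sweep(v0, 2L, w, "*")) / rowSums(wobs)
  structure(list(group_means = group_means, sigma2 = sigma2,
                 df_residual = df, amean = amean, group_wsum = group_wsum,
                 n_dropped = ncol(v) - n_obs, design = design),
            class = "rppa_fit")
}

#' @export
print.rppa_fit <- function(x, ...) {
  cat(sprintf("rppa_fit: %d probes, %d groups, median residual df %.0f\n",
              nrow(x$group_means), ncol(x$group_means),
              stats::median(x$df_residual)))
  invisible(x)
}

#' Estimate per-sample precision weights
#'
#' Fits a heteroscedastic variance-factor model in which sample j's residual
#' variance is sigma2_probe / w_j, estimated by iterating between per-probe
#' weighted fits and leverage-corrected moment updates of the sample factors
#' (the same model targeted by array-weight procedures in microarray
#' analysis). Weights are normalised to geometric mean 1 and clamped to
#' \[0.05, 20\].
#'
#' @param x Expression object or log2 matrix.
#' @param group Group label per sample (in expression column order for the
#'   selected samples).
#' @param sample_ids Samples to use (default all columns).
#' @param max_iter,tol Iteration control; non-convergence returns the last
#'   iterate with attribute `converged = FALSE` and a warning.
#' @return Named positive weights, geometric mean 1.
#' @export
estimate_sample_weights <- function(x, group, sample_ids = NULL,
                                    max_iter = 100L, tol = 1e-3) {
  v <- expr_values(x)
  if (is.null(sample_ids)) sample_ids <- colnames(v)
  v <- v[, sample_ids, drop = FALSE]
  v <- v[stats::complete.cases(v), , drop = FALSE]
  if (nrow(v) < 50)
    warning("fewer than 50 complete probes; precision weights will be unstable")
  group <- as.character(group)
  n <- ncol(v)
  lev <- unique(group)
  g <- length(lev)
  if (n - g <= 0) stop("no residual degrees of freedom for weight estimation")
  inc <- outer(group, lev, "==") + 0
  w <- rep(1, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gw <- drop(crossprod(inc, w))                       # group weight totals
    means <- sweep(v, 2L, w, "*") %*% inc / rep(gw, each = nrow(v))
    r <- v - means %*% t(inc)
    s2 <- rowSums(sweep(r^2, 2L, w, "*")) / (n - g)
    ok <- s2 > 1e-12
    if (!any(ok)) stop("all probes have zero residual variance")
    z <- colMeans(r[ok, , drop = FALSE]^2 / s2[ok])     # E = (1 - h_j)/w_j
    h <- w / gw[match(group, lev)]                      # leverage per sample
    wnew <- pmax(1e-8, (1 - h) / pmax(z, 1e-12))
    wnew <- sqrt(w * wnew)                              # damped (geometric) step
    wnew <- wnew / exp(mean(log(wnew)))
    if (max(abs(log(wnew) - log(w))) < tol) { w <- wnew; converged <- TRUE; break }
    w <- wnew
  }
  if (!converged) warning("precision-weight estimation did not converge; returning last iterate")
  w <- pmin(pmax(w, 0.05), 20)
  w <- w / exp(mean(log(w)))
  structure(stats::setNames(w, sample_ids), converged = converged)
}
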