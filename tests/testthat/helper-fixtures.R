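# shared fixture builders and independent oracles

rand_expr <- function(p = 20, n = 6, seed = 1, prefix = "p") {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  expression_matrix(m)
}

simple_annotation <- function(probe_ids, phospho = rep(FALSE, length(probe_ids)),
                              excluded = rep(FALSE, length(probe_ids)),
                              tags = NULL) {
  ann <- data.frame(probe_id = probe_ids,
                    target = probe_ids,
                    phospho_site = ifelse(phospho, "site", ""),
                    validated = TRUE, excluded = excluded,
                    stringsAsFactors = FALSE)
  ann$is_phospho <- phospho
  ann$context_tags <- if (is.null(tags))
    replicate(length(probe_ids), character(0), simplify = FALSE) else tags
  ann
}

# independent silhouette oracle: literal formula, scalar loops
brute_silhouette <- function(scores, labels) {
  n <- nrow(scores)
  d <- function(i, j) sqrt(sum((scores[i, ] - scores[j, ])^2))
  out <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    oth <- which(labels != labels[i])
    if (!length(own)) { out[i] <- 0; next }
    a <- mean(vapply(own, d, numeric(1), i = i))
    b <- mean(vapply(oth, d, numeric(1), i = i))
    out[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  out
}

# independent exact Wilcoxon oracle: full 2^n enumeration over sign vectors
brute_wilcoxon <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  if (n == 0) return(1)
  r <- rank(abs(diffs))
  wobs <- sum(r[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wall <- signs %*% r
  p_le <- mean(wall <= wobs + 1e-9)
  p_ge <- mean(wall >= wobs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# classical per-probe contrast t-test via lm(), the unmoderated oracle
classical_contrast <- function(v, group, cvec) {
  t(apply(v, 1L, function(y) {
    f <- stats::lm(y ~ 0 + factor(group, levels = names(cvec)))
    co <- stats::coef(f)
    s2 <- sum(stats::resid(f)^2) / f$df.residual
    ngr <- table(factor(group, levels = names(cvec)))
    lfc <- sum(cvec * co)
    se <- sqrt(s2 * sum(cvec^2 / ngr))
    tt <- lfc / se
    c(lfc = lfc, t = tt, p = 2 * stats::pt(-abs(tt), f$df.residual))
  }))
}

# fit the four-group quartet for the ab40 arm on a (possibly uncentered) matrix
quartet_from_data <- function(expr, samples, iso = "ab40",
                              trend = TRUE, robust = TRUE) {
  g4 <- c("untreated", "insulin", iso, paste0(iso, "_insulin"))
  sub <- samples[samples$group %in% g4, ]
  des <- design_spec(sub$group, sample_ids = sub$sample_id)
  mod <- ebayes_moderate(fit_cellmeans(expr, des), trend = trend, robust = robust)
  ins <- paste0(iso, "_insulin")
  ci <- function(co) apply_contrast(mod, co)
  contrast_quartet(
    I = ci(c(insulin = 1, untreated = -1)),
    Ia = ci(stats::setNames(c(1, -1), c(ins, iso))),
    L = ci(stats::setNames(c(1, -1), c(ins, "insulin"))),
    S = ci(stats::setNames(c(1, -1, -1, 1), c(ins, iso, "insulin", "untreated")))
  )
}

null_sim_config <- function(seed, n_probes = 500, sd = NULL,
                            batch_offsets = c(batch1 = 0, batch2 = 0,
                                              batch3 = 0, batch4 = 0), ...) {
  tp <- if (is.null(sd)) list(intercept = log(0.0225), slope = -0.3) else
    list(intercept = log(sd^2), slope = 0)
  sim_config(n_probes = n_probes, n_phospho = 0L, seed = seed,
             trend_params = tp, prior_df = if (is.null(sd)) 4 else Inf,
             scenario_counts = c(insulin_up = 0L),
             batch_offsets = batch_offsets, ...)
}

two_group_result <- function(expr, samples, groups, trend = TRUE, robust = TRUE,
                             weights = NULL) {
  sub <- samples[samples$group %in% groups, ]
  des <- design_spec(sub$group, sample_ids = sub$sample_id, weights = weights)
  mod <- ebayes_moderate(fit_cellmeans(expr, des), trend = trend, robust = robust)
  apply_contrast(mod, stats::setNames(c(1, -1), groups))
}

# synthetic contrast-result table with prescribed CIs, for invariant-set tests
fake_contrast <- function(probe_id, lfc, ci_low, ci_high) {
  data.frame(probe_id = probe_id, lfc = lfc, se = NA_real_, t = NA_real_,
             p = NA_real_, fdr = NA_real_, ci_low = ci_low, ci_high = ci_high,
             stringsAsFactors = FALSE)
}
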