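test_that("cell-means fits reproduce weighted group averages", {
  m <- matrix(c(1, 1, 1, 3, 3, 3), 1, 6,
              dimnames = list("p1", paste0("s", 1:6)))
  des <- design_spec(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  fit <- fit_cellmeans(expression_matrix(m), des)
  expect_equal(unname(fit$group_means["p1", ]), c(1, 3))
  expect_equal(unname(fit$sigma2), 0)
  expect_equal(unname(fit$df_residual), 4)

  # WLS means are invariant to a common rescaling of the weights
  x <- rand_expr(10, 6, seed = 3)
  d1 <- design_spec(rep(c("a", "b"), each = 3), x$sample_ids)
  d2 <- design_spec(rep(c("a", "b"), each = 3), x$sample_ids, weights = rep(2, 6))
  expect_equal(fit_cellmeans(x, d1)$group_means, fit_cellmeans(x, d2)$group_means)

  # independent weighted-average oracle on a random 30-probe fixture
  set.seed(7)
  x <- rand_expr(30, 9, seed = 7)
  grp <- rep(c("a", "b", "c"), each = 3)
  w <- runif(9, 0.5, 2)
  fit <- fit_cellmeans(x, design_spec(grp, x$sample_ids, weights = w))
  for (g in c("a", "b", "c")) {
    j <- which(grp == g)
    oracle <- (x$values[, j] %*% w[j]) / sum(w[j])
    expect_equal(unname(fit$group_means[, g]), unname(drop(oracle)),
                 tolerance = 1e-12)
  }
})

test_that("missing values drop samples per probe and track degrees of freedom", {
  x <- rand_expr(5, 6, seed = 13)
  x$values[1, 1] <- NA
  fit <- fit_cellmeans(x, design_spec(rep(c("a", "b"), each = 3), x$sample_ids))
  expect_equal(unname(fit$df_residual), c(3, 4, 4, 4, 4))
  expect_equal(unname(fit$group_means[1, "a"]), mean(x$values[1, 2:3]))
})

test_that("precision weights recover engineered sample-quality differences", {
  d <- generate_dataset(null_sim_config(seed = 3, sample_quality = c(s07 = 1 / 9)))
  sub <- d$samples[d$samples$group %in% c("insulin", "untreated"), ]
  w <- estimate_sample_weights(d$expr, sub$group, sample_ids = sub$sample_id)
  expect_lt(w[["s07"]], 0.5)
  expect_equal(exp(mean(log(w))), 1, tolerance = 1e-6)

  # homoscedastic data: all weights near 1
  d0 <- generate_dataset(null_sim_config(seed = 4))
  sub0 <- d0$samples[d0$samples$group %in% c("insulin", "untreated"), ]
  w0 <- estimate_sample_weights(d0$expr, sub0$group, sample_ids = sub0$sample_id)
  expect_true(all(w0 >= 0.8 & w0 <= 1.25))
})

test_that("precision weights agree directionally with limma arrayWeights", {
  skip_if_not_installed("limma")
  d <- generate_dataset(null_sim_config(seed = 3, sample_quality = c(s07 = 1 / 9)))
  sub <- d$samples[d$samples$group %in% c("insulin", "untreated"), ]
  v <- expr_values(d$expr)[, sub$sample_id]
  w <- estimate_sample_weights(d$expr, sub$group, sample_ids = sub$sample_id)
  design <- stats::model.matrix(~0 + factor(sub$group))
  aw <- limma::arrayWeights(v, design)
  expect_identical(unname(which.min(w)), unname(which.min(aw)))
  expect_gt(cor(log(as.numeric(w)), log(aw)), 0.8)
})

test_that("moderation obeys its limiting cases and the shrinkage formula", {
  x <- rand_expr(60, 6, seed = 5)
  des <- design_spec(rep(c("a", "b"), each = 3), x$sample_ids)
  fit <- fit_cellmeans(x, des)

  # d0 = 0: moderated equals classical
  m0 <- ebayes_moderate(fit, trend = FALSE, robust = FALSE, prior_df = 0)
  expect_equal(m0$post_var, fit$sigma2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(m0$df_total), fit$df_residual, ignore_attr = TRUE)

  # d0 = Inf: posterior variance collapses onto the prior
  mI <- ebayes_moderate(fit, trend = FALSE, robust = FALSE, prior_df = Inf)
  expect_equal(mI$post_var, mI$prior_var, tolerance = 1e-12)
  expect_equal(unname(mI$df_total), rep(1e6, 60))

  # estimated case: posterior is a convex combination lying between s2 and s0^2
  xh <- x
  set.seed(55)
  xh$values <- x$values * rep(sqrt(0.05 * 4 / rchisq(60, 4)), 6)
  fith <- fit_cellmeans(xh, des)
  m <- ebayes_moderate(fith, trend = TRUE, robust = FALSE)
  expect_true(is.finite(m$prior_df))
  lo <- pmin(m$prior_var, fith$sigma2)
  hi <- pmax(m$prior_var, fith$sigma2)
  expect_true(all(m$post_var >= lo - 1e-12 & m$post_var <= hi + 1e-12))
  expect_equal(unname(m$post_var),
               unname((m$prior_df_probe * m$prior_var +
                         fith$df_residual * fith$sigma2) /
                        (m$prior_df_probe + fith$df_residual)),
               tolerance = 1e-12)

  # identical variances: infinite prior df convention
  xx <- x
  xx$values <- matrix(rep(c(0, 1, -1, 0, 1, -1), each = 60), 60, 6,
                      dimnames = dimnames(x$values))
  fconst <- fit_cellmeans(expression_matrix(xx$values), des)
  mc <- ebayes_moderate(fconst, trend = FALSE, robust = FALSE)
  expect_identical(mc$prior_df, Inf)
})

test_that("hyperparameter estimates match limma on shared data", {
  skip_if_not_installed("limma")
  set.seed(31)
  x <- rand_expr(200, 6, seed = 31)
  x$values <- x$values * rep(sqrt(0.02 * 4 / rchisq(200, 4)), 6)
  grp <- rep(c("a", "b"), each = 3)
  fit <- fit_cellmeans(x, design_spec(grp, x$sample_ids))
  m <- ebayes_moderate(fit, trend = FALSE, robust = FALSE)
  lf <- limma::lmFit(x$values, stats::model.matrix(~0 + factor(grp)))
  lb <- limma::eBayes(lf, trend = FALSE, robust = FALSE)
  expect_equal(m$prior_df, lb$df.prior, tolerance = 1e-6)
  expect_equal(mean(m$prior_var), mean(lb$s2.prior), tolerance = 1e-6)
  expect_equal(m$post_var, lb$s2.post, tolerance = 1e-8, ignore_attr = TRUE)
  # and the moderated t for the group difference matches
  res <- apply_contrast(m, c(a = 1, b = -1))
  ct <- limma::contrasts.fit(lf, c(1, -1))
  cb <- limma::eBayes(ct, trend = FALSE, robust = FALSE)
  expect_equal(res$t, drop(cb$t), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$p, drop(cb$p.value), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("trended moderation tracks limma's trended prior closely", {
  skip_if_not_installed("limma")
  set.seed(41)
  p <- 300
  A <- runif(p, -2, 2)
  sd_p <- sqrt(exp(log(0.04) - 0.5 * A))
  v <- matrix(rnorm(p * 6, 0, rep(sd_p, 6)), p, 6) + A
  dimnames(v) <- list(sprintf("p%03d", 1:p), sprintf("s%02d", 1:6))
  grp <- rep(c("a", "b"), each = 3)
  fit <- fit_cellmeans(expression_matrix(v), design_spec(grp, colnames(v)))
  m <- ebayes_moderate(fit, trend = TRUE, robust = FALSE)
  lb <- limma::eBayes(limma::lmFit(v, stats::model.matrix(~0 + factor(grp))),
                      trend = TRUE, robust = FALSE)
  expect_gt(cor(log(m$prior_var), log(lb$s2.prior)), 0.95)
  expect_gt(cor(m$post_var, lb$s2.post), 0.97)
})

test_that("contrasts implement second-order arithmetic and closed-form errors", {
  # known group means: shift contrast arithmetic
  v <- rbind(p1 = c(0, 0, 0, 2, 2, 2, 0, 0, 0, 1, 1, 1))
  colnames(v) <- sprintf("s%02d", 1:12)
  grp <- rep(c("unt", "ins", "ab", "ab_ins"), each = 3)
  fit <- fit_cellmeans(expression_matrix(v + 0), design_spec(grp, colnames(v)))
  m <- ebayes_moderate(fit, trend = FALSE, robust = FALSE, prior_df = 0)
  S <- apply_contrast(m, c(ab_ins = 1, ab = -1, ins = -1, unt = 1))
  expect_equal(S$lfc, -1)
  expect_equal(sum(attr(S, "coefficients")), 0)

  # balanced design: se = sigma_tilde * sqrt(sum c^2 / n)
  x <- rand_expr(40, 12, seed = 6)
  fit <- fit_cellmeans(x, design_spec(grp, x$sample_ids))
  m <- ebayes_moderate(fit, trend = FALSE, robust = FALSE)
  cvec <- c(ab_ins = 1, ab = -1, ins = -1, unt = 1)
  res <- apply_contrast(m, cvec)
  expect_equal(res$se, sqrt(m$post_var * sum(cvec^2) / 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(apply_contrast(m, c(nope = 1, unt = -1)), "unfitted")
  # CI brackets the estimate and fdr dominates p
  expect_true(all(res$ci_low <= res$lfc & res$lfc <= res$ci_high))
  expect_true(all(res$fdr >= res$p - 1e-12))
})

test_that("BH adjustment follows the step-up procedure and its invariances", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.3, NA, 0.01)
  out <- adjust_bh(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], stats::p.adjust(c(0.3, 0.01), "BH"))
  # pointwise dominance and permutation invariance
  set.seed(12); q <- runif(50)
  expect_true(all(adjust_bh(q) >= q))
  perm <- sample(50)
  expect_equal(adjust_bh(q)[perm], adjust_bh(q[perm]))
})

test_that("DE counting and directional overlap partition probes correctly", {
  d <- generate_dataset(null_sim_config(seed = 8))
  res <- two_group_result(median_center(d$expr), d$samples, c("insulin", "untreated"))
  cnt <- count_de(res)
  expect_identical(unname(cnt["n_total"]), unname(cnt["n_up"] + cnt["n_down"]))

  # 10 strong true effects among 200 nulls are all and only what is found
  set.seed(15)
  p <- 210
  v <- matrix(rnorm(p * 6, 0, 0.1), p, 6,
              dimnames = list(sprintf("p%03d", 1:p), sprintf("s%02d", 1:6)))
  v[1:10, 4:6] <- v[1:10, 4:6] + 1.0
  res2 <- two_group_result(expression_matrix(v),
                           data.frame(sample_id = colnames(v),
                                      group = rep(c("a", "b"), each = 3)),
                           c("b", "a"))
  cnt2 <- count_de(res2)
  expect_true(abs(cnt2[["n_up"]] - 10) <= 1)

  expect_identical(unname(directional_overlap(res2, res2)[["opposite"]]), 0L)
  neg <- res2; neg$lfc <- -neg$lfc
  ov <- directional_overlap(res2, neg)
  expect_identical(unname(ov[["opposite"]]), unname(cnt2[["n_total"]]))
  expect_identical(unname(ov[["up_up"]]) + unname(ov[["down_down"]]), 0L)

  # brute-force set-arithmetic oracle on random significance patterns
  set.seed(16)
  mk <- function() data.frame(probe_id = sprintf("p%02d", 1:40),
                              lfc = rnorm(40), fdr = runif(40))
  a <- mk(); b <- mk()
  ov2 <- directional_overlap(a, b, threshold = 0.3)
  Aup <- a$probe_id[a$fdr < 0.3 & a$lfc > 0]; Adn <- a$probe_id[a$fdr < 0.3 & a$lfc < 0]
  Bup <- b$probe_id[b$fdr < 0.3 & b$lfc > 0]; Bdn <- b$probe_id[b$fdr < 0.3 & b$lfc < 0]
  expect_identical(unname(ov2[["up_up"]]), length(intersect(Aup, Bup)))
  expect_identical(unname(ov2[["down_down"]]), length(intersect(Adn, Bdn)))
  expect_identical(unname(ov2[["opposite"]]),
                   length(intersect(Aup, Bdn)) + length(intersect(Adn, Bup)))
})
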