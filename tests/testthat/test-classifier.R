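quartet_row <- function(I, Ia, L, S, Av = c(NA, NA), Au = c(NA, NA), id = "p1") {
  data.frame(probe_id = id,
             I_lfc = I[1], I_fdr = I[2], Ia_lfc = Ia[1], Ia_fdr = Ia[2],
             L_lfc = L[1], L_fdr = L[2], S_lfc = S[1], S_fdr = S[2],
             Av_lfc = Av[1], Av_fdr = Av[2], Au_lfc = Au[1], Au_fdr = Au[2],
             stringsAsFactors = FALSE)
}

test_that("the canonical response patterns yield their expected calls", {
  # strong stimulation robustly attenuated: both L and S beyond the robust tier
  robust <- quartet_row(I = c(1.4, 1e-5), Ia = c(0.4, 0.02),
                        L = c(-1.0, 5e-4), S = c(-1.0, 5e-4))
  expect_identical(classify_response(robust)$category, "robust_attenuation")

  # stimulus inhibition converted to stimulation (AMPK-type pattern)
  rev <- quartet_row(I = c(-0.8, 1e-3), Ia = c(0.7, 4e-3),
                     L = c(0.9, 2e-3), S = c(1.5, 1e-4))
  expect_identical(classify_response(rev)$category, "reversal")

  # responsive probe whose shift is null
  noef <- quartet_row(I = c(1.0, 1e-3), Ia = c(0.95, 2e-3),
                      L = c(-0.05, 0.9), S = c(-0.05, 0.6))
  expect_identical(classify_response(noef)$category, "no_effect")

  # plain attenuation below the robust tier
  att <- quartet_row(I = c(1.0, 1e-4), Ia = c(0.45, 0.01),
                     L = c(-0.55, 0.02), S = c(-0.55, 0.03))
  expect_identical(classify_response(att)$category, "attenuation")

  # same-direction shift
  aug <- quartet_row(I = c(0.8, 1e-3), Ia = c(1.6, 1e-4),
                     L = c(0.8, 5e-3), S = c(0.8, 0.01))
  expect_identical(classify_response(aug)$category, "augmentation")
})

test_that("non-responsive probes are rejected toward the basal pathway", {
  q <- quartet_row(I = c(0.2, 0.4), Ia = c(0.1, 0.5), L = c(0, 1), S = c(0, 1))
  expect_error(classify_response(q), "classify_basal")
})

test_that("saturation is co-annotated on attenuation with an elevated baseline", {
  sat <- quartet_row(I = c(1.0, 1e-4), Ia = c(0.05, 0.8),
                     L = c(-0.02, 0.9), S = c(-0.95, 1e-3),
                     Av = c(0.9, 1e-3), Au = c(1.0, 5e-4))
  call <- classify_response(sat)
  expect_identical(call$category, "attenuation")
  expect_true(call$saturation_possible)
  expect_match(call$rationale, "saturation")
  # the same pattern without baseline elevation is plain attenuation
  nosat <- quartet_row(I = c(1.0, 1e-4), Ia = c(0.05, 0.8),
                       L = c(-0.02, 0.9), S = c(-0.95, 1e-3),
                       Av = c(0.05, 0.9), Au = c(0.02, 0.9))
  expect_false(classify_response(nosat)$saturation_possible)
})

test_that("calls are deterministic and symmetric under global sign flips", {
  set.seed(44)
  rows <- do.call(rbind, lapply(1:50, function(i) {
    I <- c(sample(c(-1, 1), 1) * runif(1, 0.5, 2), 10^runif(1, -6, -1.4))
    Ia <- c(rnorm(1), runif(1))
    S <- c(Ia[1] - I[1], 10^runif(1, -6, 0))
    L <- c(rnorm(1, S[1], 0.1), 10^runif(1, -6, 0))
    quartet_row(I, Ia, L, S, id = sprintf("p%02d", i))
  }))
  c1 <- classify_response(rows)
  c2 <- classify_response(rows)
  expect_identical(c1, c2)
  flipped <- rows
  for (nm in grep("_lfc$", names(rows), value = TRUE)) flipped[[nm]] <- -rows[[nm]]
  c3 <- classify_response(flipped)
  expect_identical(c1$category, c3$category)
  expect_true(all(nzchar(c1$rationale)))          # every call traces to a rule
})

test_that("basal classification needs concordant significant contrasts", {
  expect_identical(classify_basal(0.6, 0.01, 0.5, 0.02), "concordant_up")
  expect_identical(classify_basal(-0.6, 0.01, -0.5, 0.02), "concordant_down")
  expect_identical(classify_basal(0.6, 0.01, 0.5, 0.30), "none")
  expect_identical(classify_basal(0.6, 0.01, -0.5, 0.02), "discordant")
})

test_that("call grids line up probes against isoforms", {
  calls <- data.frame(
    probe_id = c("p1", "p2", "p1", "p2"),
    isoform = c("ab40", "ab40", "ab42", "ab42"),
    category = c("attenuation", "reversal", "no_effect", "no_effect"),
    saturation_possible = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  grid <- summarize_calls(calls)
  expect_identical(nrow(grid), 2L)
  expect_identical(grid$ab40, c("attenuation*", "reversal"))
  expect_identical(grid$ab42, c("no_effect", "no_effect"))
  expect_identical(nrow(summarize_calls(calls[0, ])), 0L)
})

test_that("scenario truth is recovered from simulated quartets", {
  cfg <- sim_config(n_probes = 200, n_phospho = 200, seed = 5,
                    trend_params = list(intercept = log(0.0225), slope = 0),
                    prior_df = Inf,
                    scenario_counts = c(attenuated = 70L, reversed = 70L,
                                        insulin_up = 30L, insulin_down = 30L),
                    batch_offsets = c(batch1 = 0, batch2 = 0, batch3 = 0, batch4 = 0))
  d <- generate_dataset(cfg)
  q <- quartet_from_data(d$expr, d$samples)
  resp <- q[q$I_fdr < 0.05, ]
  calls <- classify_response(resp)
  tr <- merge(calls, d$truth[, c("probe_id", "scenario")])
  acc <- function(scen, ok) mean(tr$category[tr$scenario == scen] %in% ok)
  expect_gte(acc("attenuated", c("attenuation", "robust_attenuation")), 0.9)
  expect_gte(acc("reversed", "reversal"), 0.9)
  expect_gte(acc("insulin_up", "no_effect"), 0.9)
  expect_gte(acc("insulin_down", "no_effect"), 0.9)
  # a modulated isoform coexists with an intact one on the same probes
  q42 <- quartet_from_data(d$expr, d$samples, iso = "ab42")
  calls42 <- classify_response(q42[q42$I_fdr < 0.05, ])
  tr42 <- merge(calls42, d$truth[, c("probe_id", "scenario")])
  expect_gte(mean(tr42$category[tr42$scenario == "attenuated"] == "no_effect"), 0.9)
})
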