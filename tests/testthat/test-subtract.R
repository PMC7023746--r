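# Background fitting and bootstrap subtraction.

test_that("channel bootstrap matches exact binomial quantiles on two channels", {
  # (50, 50): channel 1 of each redraw is Binomial(100, 0.5)
  bs <- bootstrap_channel_distribution(c(a = 50, b = 50), n_boot = 10000, seed = 3)
  expect_lte(abs(bs$lower[["a"]] - qbinom(0.005, 100, 0.5)), 1)
  expect_lte(abs(bs$upper[["a"]] - qbinom(0.995, 100, 0.5)), 1)

  # all mutations in one channel: degenerate CIs
  one <- bootstrap_channel_distribution(c(a = 40, b = 0), n_boot = 1000, seed = 1)
  expect_equal(unname(one$lower), c(40, 0))
  expect_equal(unname(one$upper), c(40, 0))

  # reproducibility and preconditions
  again <- bootstrap_channel_distribution(c(a = 50, b = 50), n_boot = 10000, seed = 3)
  expect_identical(bs$lower, again$lower)
  expect_identical(bs$upper, again$upper)
  expect_error(bootstrap_channel_distribution(c(0, 0), seed = 1), "Empty sample")
  expect_error(bootstrap_channel_distribution(c(5, 5), n_boot = 10, seed = 1),
               "at least 1000")
})

test_that("background model averages control profiles and burdens", {
  sch <- mutsigexp:::new_channel_scheme("toy", c("A", "B"), "SBS")
  m <- matrix(c(100L, 0L, 0L, 100L), nrow = 2,
              dimnames = list(c("A", "B"), c("c1", "c2")))
  bg <- fit_background(catalog_from_counts(m, sch))
  expect_equal(as.numeric(bg$profile), c(0.5, 0.5))
  expect_equal(bg$burden, 100)

  ident <- matrix(c(60L, 40L, 120L, 80L), nrow = 2,
                  dimnames = list(c("A", "B"), c("c1", "c2")))
  bg2 <- fit_background(catalog_from_counts(ident, sch))
  expect_equal(as.numeric(bg2$profile), c(0.6, 0.4))
  expect_equal(bg2$burden, 150)

  expect_error(fit_background(catalog_from_counts(m[, 1, drop = FALSE], sch)),
               "at least 2 control")
})

test_that("a zero background leaves the centroid as the signature", {
  sig <- peaked_signature(seed = 6)
  counts <- draw_counts(list(sig), 400, 3, seed = 15)
  ct <- catalog_from_counts(counts)
  bg0 <- background_model_from(signature_profile(rep(0, 96), sbs96_scheme(),
                                                 normalize = FALSE), 0)
  res <- subtract_background(ct, bg0, n_boot = 1000, seed = 2)
  expect_equal(res$background_scale, 1)
  expect_equal(res$attributed_burden, mean(colSums(counts)))
  expect_equal(as.numeric(res$signature),
               unname(rowMeans(sweep(counts, 2, colSums(counts), "/"))))
})

test_that("subclones drawn purely from background leave almost nothing", {
  bg_sig <- example_background_signature()
  bg <- background_model_from(bg_sig, 300)
  counts <- draw_counts(list(bg_sig), 300, 4, seed = 41)
  res <- subtract_background(catalog_from_counts(counts), bg,
                             n_boot = 1000, seed = 41)
  # null simulation: residual mass is resampling noise only
  expect_lt(res$attributed_burden, 0.15 * 300)
  # every zeroed channel's negative residual lies within its noise tolerance
  zeroed <- names(res$centroid) %in% res$zeroed_channels
  expect_true(all(res$residual[zeroed] >= -res$channel_tolerance[zeroed] - 1e-9))
  expect_true(all(as.numeric(res$signature) >= 0))
})

test_that("subtraction recovers a planted signature mixed over background", {
  bg_sig <- example_background_signature()
  planted <- peaked_signature(seed = 17)
  counts <- draw_counts(list(bg_sig, planted), c(200, 600), 4, seed = 18)
  bg <- background_model_from(bg_sig, 200)
  res <- subtract_background(catalog_from_counts(counts), bg,
                             n_boot = 1000, seed = 18)
  expect_gte(cosine_similarity(res$signature, planted), 0.95)
  expect_lt(abs(res$attributed_burden - 600) / 600, 0.15)
  expect_lte(res$attributed_burden, res$mean_experimental_burden)
  expect_equal(sum(res$signature), 1)
  # determinism given (seed, n_boot)
  res2 <- subtract_background(catalog_from_counts(counts), bg,
                              n_boot = 1000, seed = 18)
  expect_identical(glance(res), glance(res2))
})

test_that("recovered cosine does not degrade as the planted burden grows", {
  bg_sig <- example_background_signature()
  planted <- peaked_signature(seed = 23)
  bg <- background_model_from(bg_sig, 200)
  cosines <- vapply(c(100, 300, 900), function(tb) {
    counts <- draw_counts(list(bg_sig, planted), c(200, tb), 4, seed = 29)
    res <- subtract_background(catalog_from_counts(counts), bg,
                               n_boot = 1000, seed = 29)
    cosine_similarity(res$signature, planted)
  }, numeric(1))
  # non-decreasing up to a small resampling-noise allowance
  expect_true(all(diff(cosines) > -0.005))
})

test_that("a background that saturates the signal is a degenerate subtraction", {
  bg_sig <- signature_profile(c(1, rep(0, 95)), sbs96_scheme())
  # experimental mass sits entirely on a channel the background dominates
  counts <- matrix(0L, 96, 2, dimnames = list(sbs96_scheme()$labels, c("e1", "e2")))
  counts[1, ] <- 10L
  bg <- background_model_from(bg_sig, 1e8)
  expect_error(subtract_background(catalog_from_counts(counts), bg,
                                   n_boot = 1000, seed = 1),
               "Degenerate subtraction")
})
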