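# Burden testing, profile statistics, SNR, cosine similarity and stability.

test_that("burden test behaves at the centre and the extreme of the null", {
  # experimental mean equal to the control mean: p near 0.5, not significant
  bt <- burden_test(c(190, 200, 210, 200), c(195, 200, 205),
                    n_boot = 2000, seed = 5, method = "bootstrap")
  expect_gt(bt$p_value, 0.3)
  expect_lt(bt$p_value, 0.7)
  expect_false(bt$significant)

  # experimental mean above every bootstrap mean: minimal achievable p
  bt2 <- burden_test(c(100, 102, 98, 101), c(1000, 1005),
                     n_boot = 2000, seed = 5, method = "bootstrap")
  expect_equal(bt2$p_value, 1 / 2001)
  expect_true(bt2$significant)

  # permutation method reaches the significance cutoff once the group sizes
  # allow it (choose(12, 6) = 924 distinct splits)
  bt3 <- burden_test(c(100, 102, 98, 101, 99, 103),
                     c(1000, 1005, 990, 1010, 995, 1002),
                     n_boot = 2000, seed = 5)
  expect_lte(bt3$p_value, 0.01)

  expect_error(burden_test(c(100), c(200, 300)), "Insufficient controls")
  expect_error(burden_test(c(100, 110), c(200), n_boot = 10), "at least 1000")
})

test_that("burden test is reproducible and invariant to control order", {
  a <- burden_test(c(180, 220, 200, 190), c(260, 240), n_boot = 2000, seed = 77)
  b <- burden_test(c(180, 220, 200, 190), c(260, 240), n_boot = 2000, seed = 77)
  expect_identical(glance(a), glance(b))
  # permutation p depends on the multiset, not the labelling order
  c <- burden_test(c(220, 190, 180, 200), c(260, 240), n_boot = 2000, seed = 77)
  expect_identical(a$p_value, c$p_value)
  expect_gte(a$p_value, 1 / 2001)
})

test_that("condition-wise tests report BH-adjusted p-values", {
  sch <- sbs96_scheme()
  counts <- draw_counts(list(example_background_signature()), 200, 18, seed = 3)
  colnames(counts) <- c(paste0("C", 1:6), paste0("A", 1:6), paste0("B", 1:6))
  counts[, 13:18] <- counts[, 13:18] + draw_counts(list(peaked_signature(seed = 2)),
                                                   400, 6, seed = 4)
  ct <- catalog_from_counts(counts, sch)
  man <- lineage_manifest(tibble::tibble(
    sample_id = c("GP", "P1", colnames(counts)),
    role = c("grandparent", "parent", rep("subclone", 18)),
    parent_id = c(NA, "GP", rep("P1", 18)),
    condition = c(NA, NA, rep("control", 6), rep("experimental:a", 6),
                  rep("experimental:b", 6))
  ))
  res <- condition_burden_tests(ct, man, n_boot = 2000, seed = 8)
  expect_setequal(res$condition, c("a", "b"))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(res$significant[res$condition == "b"])
  expect_false(res$significant[res$condition == "a"])
})

test_that("profile statistics summarise normalised profiles", {
  m <- matrix(c(10, 0, 0, 10), nrow = 2,
              dimnames = list(c("c1", "c2"), c("s1", "s2")))
  sch <- mutsigexp:::new_channel_scheme("toy", c("c1", "c2"), "SBS")
  ct <- mutsigexp:::new_mut_catalog(m, sch)
  ps <- profile_stats(ct)
  expect_equal(unname(ps$mu), c(0.5, 0.5))
  expect_equal(unname(ps$sigma), c(0.5, 0.5))  # population SD of (1,0) and (0,1)
  expect_equal(sum(ps$mu), 1)

  one <- profile_stats(ct, "s1")
  expect_equal(unname(one$sigma), c(0, 0))
  expect_equal(unname(one$mu), c(1, 0))

  m2 <- cbind(m, s3 = c(0, 0))
  rownames(m2) <- c("c1", "c2")
  expect_error(profile_stats(mutsigexp:::new_mut_catalog(m2, sch)),
               "Zero-burden sample.*s3")

  samp <- profile_stats(ct, sd_type = "sample")
  expect_equal(unname(samp$sigma), c(0.5, 0.5) * sqrt(2))
})

test_that("SNR evaluates signal over quadrature noise with degenerate cases", {
  mk <- function(mu, sigma) {
    structure(list(mu = mu, sigma = sigma, n_samples = 2,
                   labels = names(mu), sd_type = "population", scheme = "toy"),
              class = "profile_stats")
  }
  mu_c <- c(c1 = 0.5, c2 = 0.5); mu_e <- c(c1 = 0.7, c2 = 0.3)
  sd05 <- c(c1 = 0.05, c2 = 0.05)
  res <- snr(mk(mu_c, sd05), mk(mu_e, sd05))
  expect_equal(res$signal, sqrt(0.08))
  expect_equal(res$noise, 0.1)
  expect_equal(res$snr, sqrt(0.08) / 0.1)

  # identical means: snr 0 regardless of noise
  expect_equal(snr(mk(mu_c, sd05), mk(mu_c, sd05))$snr, 0)
  # zero variance with distinct means: flagged infinite
  zero <- c(c1 = 0, c2 = 0)
  degen <- snr(mk(mu_c, zero), mk(mu_e, zero))
  expect_true(degen$infinite)
  expect_identical(degen$snr, Inf)
  # 0/0 defined as 0
  expect_equal(snr(mk(mu_c, zero), mk(mu_c, zero))$snr, 0)

  # symmetry under exchanging groups; sigma scaling by k scales snr by 1/k
  expect_equal(snr(mk(mu_e, sd05), mk(mu_c, sd05))$snr, res$snr)
  expect_equal(snr(mk(mu_c, 3 * sd05), mk(mu_e, 3 * sd05))$snr, res$snr / 3)

  bad <- mk(c(x1 = 0.5, x2 = 0.5), sd05)
  expect_error(snr(mk(mu_c, sd05), bad), "different schemes")
})

test_that("cosine similarity has its closed-form values and invariances", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  # invariant to positive rescaling
  for (s in 1:5) {
    p <- withr::with_seed(s, stats::runif(10))
    q <- withr::with_seed(s + 100, stats::runif(10))
    expect_equal(cosine_similarity(7.3 * p, q), cosine_similarity(p, 0.2 * q))
  }
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("stability reports flag outlier replicate signatures", {
  sch <- sbs96_scheme()
  sig <- peaked_signature(seed = 4)
  same <- stability_report(list(a = sig, b = sig, c = sig))
  expect_equal(same$min_cosine, 1.0)
  expect_true(same$stable)

  orth <- signature_profile(
    setNames(as.numeric(names(sig) == names(sig)[which(sig == min(sig))[1]]),
             names(sig)), sch)
  # an orthogonal outlier breaks stability
  disjoint_a <- signature_profile(c(1, rep(0, 95)), sch)
  disjoint_b <- signature_profile(c(0, 1, rep(0, 94)), sch)
  mix <- stability_report(list(disjoint_a, disjoint_a, disjoint_b))
  expect_equal(mix$min_cosine, 0.0)
  expect_false(mix$stable)

  expect_error(stability_report(list(sig)), "Insufficient replicates")

  # simulator replicates at appreciable burden from one planted signature
  counts <- draw_counts(list(peaked_signature(seed = 9)), 500, 4, seed = 31)
  sigs <- lapply(1:4, function(i) signature_profile(counts[, i], sch))
  expect_true(stability_report(sigs)$stable)
})
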