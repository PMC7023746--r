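# Quality control: ploidy/VAF expectations, clonality verdicts, shared-variant
# relatedness, lineage scenarios, and the on-target edit check.

test_that("expected VAF is exact rational arithmetic over the ploidy model", {
  expect_equal(expected_vaf(2, 1), 0.5)
  expect_equal(expected_vaf(1, 1), 1.0)
  expect_equal(expected_vaf(3, 1), 1 / 3)
  for (p in 1:6) for (m in 1:p) {
    expect_identical(expected_vaf(p, m) * p, as.numeric(m))
  }
  expect_error(expected_vaf(2, 3), "cannot exceed")
  expect_error(expected_vaf(0, 1), "positive integers")
})

test_that("clonality verdicts follow the significance-plus-effect-size rule", {
  # pure clone: VAFs are binomial read sampling around the diploid expectation
  vafs_clonal <- withr::with_seed(11, rbinom(200, 30, 0.5) / 30)
  rep_c <- clonality_check(vafs_clonal, depths = rep(30, 200), ploidy = 2)
  expect_equal(rep_c$verdict, "clonal")
  expect_equal(rep_c$expected_vaf, 0.5)

  # equal mixture of two clones: half the mutations private at cell-fraction
  # 0.5, so their reads sample at half the expectation
  vafs_mixed <- withr::with_seed(12, c(rbinom(100, 30, 0.5), rbinom(100, 30, 0.25)) / 30)
  rep_m <- clonality_check(vafs_mixed, depths = rep(30, 200), ploidy = 2)
  expect_equal(rep_m$verdict, "polyclonal_suspect")
  expect_match(rep_m$note, "falsely elevated mutation burdens")

  # fewer than 20 usable mutations is inconclusive, not a verdict
  expect_error(clonality_check(rep(0.5, 5), ploidy = 2), "Insufficient data")

  # deep sequencing alone must not flag trivial deviations: tiny shift,
  # huge n -> significant test but above the effect floor
  vafs_tiny <- withr::with_seed(13, rbinom(5000, 1000, 0.48) / 1000)
  expect_equal(clonality_check(vafs_tiny, ploidy = 2)$verdict, "clonal")
})

test_that("clonality type-I error stays at or below alpha on pure clones", {
  hits <- withr::with_seed(99, vapply(1:1000, function(i) {
    v <- rbinom(200, 30, 0.5) / 30
    clonality_check(v, ploidy = 2)$verdict == "polyclonal_suspect"
  }, logical(1)))
  expect_lte(mean(hits), 0.005)
})

test_that("shared-variant matrices are symmetric and bounded by burdens", {
  svm <- shared_variant_matrix(list(A = c("m1", "m2"), B = c("m1", "m3")))
  expect_equal(svm$shared["A", "B"], 1L)
  expect_equal(unname(diag(svm$shared)), c(2L, 2L))

  ident <- shared_variant_matrix(list(A = c("m1", "m2"), B = c("m1", "m2")))
  expect_true(all(ident$shared == 2L))
  disj <- shared_variant_matrix(list(A = c("m1", "m2"), B = c("m3", "m4")))
  expect_equal(disj$shared["A", "B"], 0L)

  # property over random variant sets
  for (s in 1:10) {
    sets <- withr::with_seed(s, lapply(1:4, function(i) {
      sample(paste0("v", 1:50), sample(5:30, 1))
    }))
    names(sets) <- paste0("S", 1:4)
    svm <- shared_variant_matrix(sets)
    expect_identical(svm$shared, t(svm$shared))
    for (i in 1:4) for (j in 1:4) {
      expect_lte(svm$shared[i, j], min(svm$burdens[i], svm$burdens[j]))
    }
  }
})

test_that("lineage scenarios are classified from shared-variant structure", {
  parental <- paste0("p", 1:100)
  other <- paste0("q", 1:100)
  manifest <- lineage_manifest(tibble::tibble(
    sample_id = c("GP", "P1", paste0("P1_s", 1:6)),
    role = c("grandparent", "parent", rep("subclone", 6)),
    parent_id = c(NA, "GP", rep("P1", 6)),
    condition = c(NA, NA, rep("control", 6))
  ))
  subs <- paste0("P1_s", 1:6)

  # scenario 1: subclones inherit all parental mutations plus private ones
  sets <- c(list(GP = character(), P1 = parental),
            setNames(lapply(1:6, function(i) {
              c(parental, paste0("s", i, "_", 1:30))
            }), subs))
  res <- check_lineage(shared_variant_matrix(sets), manifest)
  expect_equal(res$scenario, "consistent")

  # scenario 2: the sequenced "parent" is unrelated; siblings still share
  sets2 <- sets
  sets2$P1 <- other
  res2 <- check_lineage(shared_variant_matrix(sets2), manifest)
  expect_equal(res2$scenario, "wrong_parent")

  # scenario 3: subclones 1, 4, 6 from one lineage; 2, 3, 5 from another
  sets3 <- c(list(GP = character(), P1 = parental),
             setNames(lapply(1:6, function(i) {
               base <- if (i %in% c(1, 4, 6)) parental else other
               c(base, paste0("s", i, "_", 1:30))
             }), subs))
  res3 <- check_lineage(shared_variant_matrix(sets3), manifest)
  expect_equal(res3$scenario, "mixed_parental")
  diag3 <- attr(res3, "diagnostics")
  groups <- split(diag3$sample_id, diag3$cluster)
  expect_setequal(vapply(groups, paste, "", collapse = ","),
                  c("P1_s1,P1_s4,P1_s6", "P1_s2,P1_s3,P1_s5"))

  # a parent absent from the matrix is an error
  sets4 <- sets[setdiff(names(sets), "P1")]
  expect_error(check_lineage(shared_variant_matrix(sets4), manifest),
               "absent from shared-variant matrix")
})

test_that("on-target edit check uses closed-interval overlap of indels", {
  rec <- tibble::tibble(
    sample_id = "s1", chrom = "chr1",
    pos = c(100L, 150L, 205L), ref = c("AT", "C", "A"),
    alt = c("", "G", ""), mclass = c("DEL", "SBS", "DEL")
  )
  hit <- on_target_edit_check(rec, "chr1", 90, 120)
  expect_equal(hit$status, "edited")
  expect_equal(hit$records$pos, 100L)

  # only SNVs inside the window
  expect_equal(on_target_edit_check(rec, "chr1", 140, 160)$status, "not_edited")
  # indel 1 bp outside the closed window
  expect_equal(on_target_edit_check(rec, "chr1", 190, 204)$status, "not_edited")
  # closed-boundary inclusion: the 2-bp deletion at 100 spans 100..101
  expect_equal(on_target_edit_check(rec, "chr1", 101, 110)$status, "edited")
  expect_error(on_target_edit_check(rec, "chr1", 50, 1), "Malformed")
  expect_error(on_target_edit_check(rec, "chr1", 1, 50000), "10 kb")
})

test_that("the QC battery ties lineage and clonality together on records", {
  exp <- simulate_experiment("polyclonal", seed = 21, n_parents = 1,
                             subclones_per_parent = 4,
                             reference_length = 30000)
  rep <- qc_report(exp$records, exp$manifest)
  expect_equal(rep$lineage$scenario, "consistent")
  flagged <- rep$clonality$sample_id[rep$clonality$verdict == "polyclonal_suspect"]
  expect_equal(flagged, exp$truth$polyclonal_sample)
  expect_true(any(grepl("not assessed", rep$notes)))
})
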