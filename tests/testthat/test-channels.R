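# Channel classification: substitution, doublet, indel and rearrangement
# schemes, catalog construction, and signature collapsing.

test_that("SBS classification is pyrimidine-oriented and strand-agnostic", {
  expect_equal(classify_sbs("ACG", "C", "T"), "A[C>T]G")
  expect_equal(classify_sbs("AGG", "G", "T"), "C[C>A]T")

  # exhaustive: both strands of every valid input agree, and the image is
  # exactly the 96 labels
  grid <- expand.grid(f5 = BASES <- c("A", "C", "G", "T"), ref = BASES,
                      alt = BASES, f3 = BASES, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  ctx <- paste0(grid$f5, grid$ref, grid$f3)
  fwd <- classify_sbs(ctx, grid$ref, grid$alt)
  rc <- classify_sbs(mutsigexp:::revcomp(ctx),
                     mutsigexp:::comp_base(grid$ref),
                     mutsigexp:::comp_base(grid$alt))
  expect_identical(fwd, rc)
  expect_setequal(fwd, sbs96_scheme()$labels)
  expect_length(unique(fwd), 96)
})

test_that("SBS classification rejects malformed input", {
  expect_error(classify_sbs("ANG", "N", "T"), "A/C/G/T")
  expect_error(classify_sbs("ACGT", "C", "T"), "3 nucleotides")
  expect_error(classify_sbs("ACG", "T", "A"), "Middle base")
  expect_error(classify_sbs("ACG", "C", "C"), "must differ")
})

test_that("DBS canonicalization yields exactly 78 strand-agnostic channels", {
  expect_equal(classify_dbs("AA", "TT"), "AA>TT")
  expect_equal(classify_dbs("TT", "AA"), "AA>TT")

  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  grid <- expand.grid(ref = dinucs, alt = dinucs, stringsAsFactors = FALSE)
  grid <- grid[substr(grid$ref, 1, 1) != substr(grid$alt, 1, 1) &
               substr(grid$ref, 2, 2) != substr(grid$alt, 2, 2), ]
  expect_equal(nrow(grid), 144)
  labels <- classify_dbs(grid$ref, grid$alt)
  # strand-agnostic: reverse complement maps to the same label
  expect_identical(labels, classify_dbs(mutsigexp:::revcomp(grid$ref),
                                        mutsigexp:::revcomp(grid$alt)))
  expect_length(unique(labels), 78)
  expect_error(classify_dbs("AA", "AT"), "Not a doublet")
})

test_that("flank-extended DBS classification yields exactly 1248 channels", {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  grid <- expand.grid(f5 = c("A", "C", "G", "T"), ref = dinucs, alt = dinucs,
                      f3 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  grid <- grid[substr(grid$ref, 1, 1) != substr(grid$alt, 1, 1) &
               substr(grid$ref, 2, 2) != substr(grid$alt, 2, 2), ]
  labels <- classify_dbs_flanked(grid$f5, grid$ref, grid$alt, grid$f3)
  expect_length(unique(labels), 1248)
  expect_setequal(unique(labels), dbs1248_scheme()$labels)
})

test_that("indel channels encode class, size/content, and junction mechanism", {
  pad <- strrep("A", 50)
  # 1-bp deletion of T inside a TTTTT run: 5 copies including the deleted one
  expect_equal(classify_indel("DEL", "T", pad, paste0("TTTT", pad)),
               "del.1bp_T/A.rep_5+")
  # 3-bp deletion whose 3' flank begins with 2 bp of the deleted prefix
  expect_equal(classify_indel("DEL", "TCG", pad, paste0("TC", pad)),
               "del.longer.mh")
  # 1-bp insertion of C with non-repetitive flanks
  expect_equal(classify_indel("INS", "C", pad, pad), "ins.1bp_C/G.none")
  # insertion next to existing copies counts reference copies only
  expect_equal(classify_indel("INS", "T", pad, paste0("TT", pad)),
               "ins.1bp_T/A.rep_2")
  # deletion of one of two copies
  expect_equal(classify_indel("DEL", "CG", pad, paste0("CG", pad)),
               "del.longer.rep_2")
  # microhomology via the 5' side
  expect_equal(classify_indel("DEL", "GAC", paste0(pad, "C"), strrep("T", 50)),
               "del.longer.mh")
  # all emitted labels are in the scheme
  expect_true(all(c("del.1bp_T/A.rep_5+", "del.longer.mh", "ins.1bp_C/G.none",
                    "ins.1bp_T/A.rep_2") %in% indel_scheme()$labels))
  expect_error(classify_indel("DEL", strrep("A", 100), pad, pad), "100 bp")
  expect_error(classify_indel("DEL", "T", "AAA", pad), "50 bp")
})

test_that("rearrangement channels bin sizes and single out translocations", {
  expect_equal(classify_rearrangement("tandem_duplication", 50000), "TD.10-100kb")
  expect_equal(classify_rearrangement("deletion", 5e6), "DEL.1-10Mb")
  expect_equal(classify_rearrangement("translocation", NA), "TRANS")
  expect_error(classify_rearrangement("translocation", 100), "must not carry")
  expect_error(classify_rearrangement("inversion", NA), "positive")

  sizes <- c(5e3, 5e4, 5e5, 5e6, 5e7)
  grid <- expand.grid(rtype = c("tandem_duplication", "deletion", "inversion"),
                      size = sizes, stringsAsFactors = FALSE)
  labels <- c(classify_rearrangement(grid$rtype, grid$size),
              classify_rearrangement("translocation", NA))
  expect_setequal(labels, rearrangement_scheme()$labels)
  expect_length(rearrangement_scheme()$labels, 16)
})

test_that("catalogs conserve mutations and report unclassifiable records", {
  ref <- c(chr1 = "AACGTACGTTAGCTAGCTAA")
  rec <- tibble::tibble(
    sample_id = "s1", chrom = "chr1", pos = c(3L, 7L, 3L),
    ref = "C", alt = c("T", "T", "A"), mclass = "SBS"
  )
  ct <- build_catalog(rec, sbs96_scheme(), ref)
  m <- catalog_matrix(ct)
  expect_equal(sum(m), 3)
  expect_equal(unname(m["A[C>T]G", "s1"]), 2)
  expect_equal(unname(m["A[C>A]G", "s1"]), 1)

  # empty record list: all-zero catalog with the full channel index
  empty <- build_catalog(rec[0, ], sbs96_scheme(), ref, samples = "s1")
  expect_equal(sum(catalog_matrix(empty)), 0)
  expect_equal(nrow(empty), 96)

  # N in context: unclassifiable, reported, excluded from column sums
  refN <- c(chr1 = "AANCGTACGT")
  recN <- tibble::tibble(sample_id = "s1", chrom = "chr1", pos = c(4L, 8L),
                         ref = "C", alt = "T", mclass = "SBS")
  ctN <- build_catalog(recN, sbs96_scheme(), refN)
  expect_equal(sum(catalog_matrix(ctN)), 1)
  expect_equal(nrow(catalog_unclassified(ctN)), 1)
  # conservation: classified + unclassifiable = input records
  expect_equal(sum(catalog_matrix(ctN)) + nrow(catalog_unclassified(ctN)),
               nrow(recN))

  # locus missing from the reference is an error naming the record
  bad <- tibble::tibble(sample_id = "s1", chrom = "chr1", pos = 999L,
                        ref = "C", alt = "T", mclass = "SBS")
  expect_error(build_catalog(bad, sbs96_scheme(), ref), "chr1:999")
  expect_error(build_catalog(dplyr::mutate(bad, chrom = "chrX"),
                             sbs96_scheme(), ref), "missing from reference")
})

test_that("collapsing a signature conserves weight channel by channel", {
  uniform <- signature_profile(rep(1, 96), sbs96_scheme())
  six <- collapse_signature(uniform, sbs6_scheme())
  expect_equal(as.numeric(six), rep(16 / 96, 6))
  expect_equal(sum(six), 1)

  # random profiles: conservation to within 1e-12, class weight = sum of its
  # 16 context weights
  for (s in 1:5) {
    w <- withr::with_seed(s, stats::runif(96))
    sig <- signature_profile(w, sbs96_scheme())
    col <- collapse_signature(sig, sbs6_scheme())
    expect_lt(abs(sum(col) - sum(sig)), 1e-12)
    cls <- substr(names(sig), 3, 5)
    expect_equal(as.numeric(col),
                 as.numeric(tapply(as.numeric(sig), cls, sum)[names(col)]))
  }
})
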