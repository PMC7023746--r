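# Catalogs: channels x samples count matrices, carried as a tibble with a
# `channel` column plus one column per sample, with the scheme and the report
# of unclassifiable records attached as attributes.

new_mut_catalog <- function(counts, scheme, unclassified = NULL) {
  stopifnot(is.matrix(counts), identical(rownames(counts), scheme$labels))
  tbl <- bind_cols(tibble(channel = scheme$labels),
                   as_tibble(counts, .name_repair = "minimal"))
  if (is.null(unclassified)) {
    unclassified <- tibble(sample_id = character(), chrom = character(),
                           pos = integer(), ref = character(), alt = character(),
                           reason = character())
  }
  structure(tbl, scheme = scheme, unclassified = unclassified,
            class = c("mut_catalog", class(tbl)))
}

#' Accessors for catalogs
#'
#' `catalog_matrix()` returns the channels x samples integer matrix,
#' `catalog_scheme()` the attached channel scheme, `catalog_unclassified()` the
#' report of records that could not be classified (never silently dropped), and
#' `sample_burdens()` the per-sample column sums (the mutation burdens).
#'
#' @param catalog A `mut_catalog` as returned by [build_catalog()].
#' @return A matrix, `channel_scheme`, tibble of unclassifiable records, or a
#'   tibble with columns `sample_id` and `burden` respectively.
#' @name catalog_accessors
#' @export
catalog_matrix <- function(catalog) {
  stopifnot(inherits(catalog, "mut_catalog"))
  m <- as.matrix(catalog[, setdiff(names(catalog), "channel"), drop = FALSE])
  rownames(m) <- catalog$channel
  storage.mode(m) <- "double"
  m
}

#' @rdname catalog_accessors
#' @export
catalog_scheme <- function(catalog) attr(catalog, "scheme")

#' @rdname catalog_accessors
#' @export
catalog_unclassified <- function(catalog) attr(catalog, "unclassified")

#' @rdname catalog_accessors
#' @export
sample_burdens <- function(catalog) {
  m <- catalog_matrix(catalog)
  tibble(sample_id = colnames(m), burden = unname(colSums(m)))
}

#' @export
print.mut_catalog <- function(x, ...) {
  sch <- catalog_scheme(x)
  cat("<mut_catalog> ", sch$name, ": ", length(sch$labels), " channels x ",
      ncol(x) - 1, " samples\n", sep = "")
  unc <- catalog_unclassified(x)
  if (nrow(unc) > 0) cat("  ", nrow(unc), " unclassifiable record(s); see catalog_unclassified()\n", sep = "")
  NextMethod()
}

#' @export
tidy.mut_catalog <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"channel",
                      names_to = "sample_id", values_to = "count")
}

validate_records <- function(records, need_vaf = FALSE) {
  required <- c("sample_id", "chrom", "pos", "ref", "alt", "mclass")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("Records are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(records$pos < 1, na.rm = TRUE)) abort("Positions must be 1-based (>= 1).")
  bad <- records$mclass %in% c("SBS", "DBS") & records$ref == records$alt
  if (any(bad, na.rm = TRUE)) abort("`ref` must differ from `alt`.")
  invisible(records)
}

classify_records <- function(records, scheme, reference = NULL, flank = 50L) {
  covered <- switch(scheme$class_covered,
                    SBS = "SBS", DBS = "DBS", indel = c("INS", "DEL"),
                    REARR = "REARR")
  if (!all(records$mclass %in% covered)) {
    abort(paste0("All records must be of class ", paste(covered, collapse = "/"),
                 " for scheme ", scheme$name, "."))
  }
  n <- nrow(records)
  channel <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  if (n == 0) return(list(channel = channel, reason = reason))

  needs_ref <- scheme$class_covered %in% c("SBS", "indel") ||
               scheme$name == "DBS1248"
  if (needs_ref) {
    if (is.null(reference)) abort("This scheme needs a `reference` for context lookup.")
    reference <- as_reference(reference)
    missing_chrom <- setdiff(unique(records$chrom), names(reference))
    if (length(missing_chrom) > 0) {
      abort(paste0("Chromosome(s) missing from reference: ",
                   paste(missing_chrom, collapse = ", ")))
    }
    beyond <- records$pos > nchar(reference)[records$chrom]
    if (any(beyond)) {
      i <- which(beyond)[1]
      abort(paste0("Locus missing from reference: ", records$chrom[i], ":",
                   records$pos[i], " (", records$sample_id[i], ")"))
    }
  }

  for (i in seq_len(n)) {
    res <- tryCatch({
      switch(records$mclass[i],
        SBS = {
          ctx <- ref_slice(reference[[records$chrom[i]]],
                           records$pos[i] - 1L, records$pos[i] + 1L)
          if (nchar(ctx) < 3) stop("context incomplete at sequence edge")
          if (substr(ctx, 2, 2) != records$ref[i]) {
            stop("reference base mismatch at locus")
          }
          classify_sbs(ctx, records$ref[i], records$alt[i])
        },
        DBS = {
          if (scheme$name == "DBS1248") {
            s <- reference[[records$chrom[i]]]
            f5 <- ref_slice(s, records$pos[i] - 1L, records$pos[i] - 1L)
            f3 <- ref_slice(s, records$pos[i] + 2L, records$pos[i] + 2L)
            if (nchar(f5) < 1 || nchar(f3) < 1) stop("context incomplete at sequence edge")
            classify_dbs_flanked(f5, records$ref[i], records$alt[i], f3)
          } else {
            classify_dbs(records$ref[i], records$alt[i])
          }
        },
        INS = ,
        DEL = {
          s <- reference[[records$chrom[i]]]
          seq_i <- if (records$mclass[i] == "DEL") records$ref[i] else records$alt[i]
          len <- nchar(seq_i)
          if (records$mclass[i] == "DEL") {
            f5 <- ref_slice(s, records$pos[i] - flank, records$pos[i] - 1L)
            f3 <- ref_slice(s, records$pos[i] + len, records$pos[i] + len + flank - 1L)
          } else {
            f5 <- ref_slice(s, records$pos[i] - flank + 1L, records$pos[i])
            f3 <- ref_slice(s, records$pos[i] + 1L, records$pos[i] + flank)
          }
          classify_indel(records$mclass[i], seq_i, f5, f3)
        },
        REARR = classify_rearrangement(records$rtype[i], records$size_bp[i])
      )
    }, error = function(e) structure(conditionMessage(e), class = "classify_fail"))
    if (inherits(res, "classify_fail")) reason[i] <- unclass(res) else channel[i] <- res
  }
  list(channel = channel, reason = reason)
}

#' Build a channels x samples catalog from mutation records
#'
#' Classifies every record into its channel (looking up flanking context in the
#' reference where the scheme needs it) and tabulates counts per channel and
#' sample. Records that cannot be classified — for example because their
#' context contains an ambiguous base (N) or falls at a sequence edge — are
#' reported via [catalog_unclassified()], never silently dropped; column sums
#' therefore equal the number of *classified* mutations per sample.
#'
#' @param records A data frame of mutation records with columns `sample_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `mclass` (one of SBS, DBS, INS,
#'   DEL, REARR; rearrangements additionally need `rtype` and `size_bp`).
#'   All records must belong to the class covered by `scheme`.
#' @param scheme A [channel_scheme][channel_schemes].
#' @param reference Reference sequence (named character vector, DNAStringSet,
#'   or FASTA path); required for SBS, indel and flank-extended DBS schemes.
#' @param samples Optional character vector fixing the sample columns (samples
#'   with no records get all-zero columns). Defaults to the samples present.
#' @return A `mut_catalog`.
#' @examples
#' ref <- c(chr1 = "ACGTACGTACGT")
#' rec <- tibble::tibble(sample_id = "s1", chrom = "chr1", pos = c(2, 6),
#'                       ref = "C", alt = "T", mclass = "SBS")
#' build_catalog(rec, sbs96_scheme(), ref)
#' @export
build_catalog <- function(records, scheme, reference = NULL, samples = NULL) {
  stopifnot(inherits(scheme, "channel_scheme"))
  validate_records(records)
  if (is.null(samples)) samples <- unique(records$sample_id)
  if (length(samples) == 0) samples <- "sample"
  cls <- classify_records(records, scheme, reference)
  ok <- !is.na(cls$channel)
  counts <- table(
    factor(cls$channel[ok], levels = scheme$labels),
    factor(records$sample_id[ok], levels = samples)
  )
  counts <- matrix(as.integer(counts), nrow = length(scheme$labels),
                   dimnames = list(scheme$labels, samples))
  unclassified <- records[!ok, , drop = FALSE]
  if (nrow(unclassified) > 0) {
    unclassified <- as_tibble(unclassified)
    unclassified$reason <- cls$reason[!ok]
  } else {
    unclassified <- NULL
  }
  new_mut_catalog(counts, scheme, unclassified)
}

#' Normalised mutation profiles of catalog samples
#'
#' Divides each sample column by its burden, so each profile sums to one.
#'
#' @inheritParams catalog_accessors
#' @param sample_ids Samples to keep (default: all).
#' @return A channels x samples matrix of profile weights.
#' @export
catalog_profiles <- function(catalog, sample_ids = NULL) {
  m <- catalog_matrix(catalog)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, colnames(m))
    if (length(missing) > 0) {
      abort(paste0("Sample(s) not in catalog: ", paste(missing, collapse = ", ")))
    }
    m <- m[, sample_ids, drop = FALSE]
  }
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0("Zero-burden sample(s): ",
                 paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  sweep(m, 2, totals, "/")
}
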