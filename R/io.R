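# Standard-format I/O: VCF mutation records (via vcfR), BEDPE rearrangements,
# TSV catalogs, TSV/YAML manifests, and whole-experiment export.

trim_indel <- function(pos, ref, alt) {
  # VCF anchored representation -> internal inserted/deleted sequence
  while (nchar(ref) > 0 && nchar(alt) > 0 && substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

#' Read somatic mutation records from a VCF
#'
#' Parses SNVs, doublets and small indels from a VCF 4.x file into the
#' package's record tibble. Multi-allelic rows are decomposed; indels are
#' converted from the anchored VCF representation to the inserted/deleted
#' sequence (`mclass` INS/DEL, `pos` at the first affected base for deletions
#' and at the anchor base for insertions); `AF` and `DP` are captured from the
#' INFO column when present. Adjacent same-sample SNVs are merged into one
#' doublet record (the merge is logged); note the merge is adjacency-based —
#' phase information, when present in genotypes, is not consulted because the
#' package's VCF surface carries no GT field.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sample_id Sample label for the records (default: file name stem).
#' @return A tibble of mutation records with columns `sample_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `mclass`, `vaf`, `depth`.
#' @export
read_variants <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(sample_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), mclass = character(),
                  vaf = double(), depth = double()))
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    af <- suppressWarnings(as.numeric(strsplit(info_field(fix$INFO[i], "AF"),
                                               ",")[[1]]))
    dp <- suppressWarnings(as.numeric(info_field(fix$INFO[i], "DP")))
    for (k in seq_along(alts)) {
      pos <- as.integer(fix$POS[i]); ref <- toupper(fix$REF[i])
      alt <- toupper(alts[k])
      vaf_k <- if (length(af) >= k) af[k] else NA_real_
      if (nchar(ref) == nchar(alt)) {
        mclass <- if (nchar(ref) == 1) "SBS" else if (nchar(ref) == 2) "DBS" else NA
        if (is.na(mclass)) next  # longer MNPs are out of the channel schemes
      } else {
        t <- trim_indel(pos, ref, alt)
        if (nchar(t$ref) > 0 && nchar(t$alt) > 0) next  # complex substitution
        if (nchar(t$ref) > 0) {
          mclass <- "DEL"; pos <- t$pos; ref <- t$ref; alt <- ""
        } else {
          mclass <- "INS"; pos <- t$pos - 1L; ref <- ""; alt <- t$alt
        }
      }
      rows[[length(rows) + 1]] <- tibble(
        sample_id = sample_id, chrom = fix$CHROM[i], pos = pos,
        ref = ref, alt = alt, mclass = mclass,
        vaf = vaf_k, depth = dp
      )
    }
  }
  rec <- arrange(bind_rows(rows), .data$chrom, .data$pos)
  merge_adjacent_snvs(rec)
}

# Merge runs of adjacent SNVs (same chrom, consecutive positions) into doublet
# records; greedy left-to-right pairing within a run. Logged via inform().
merge_adjacent_snvs <- function(rec) {
  if (nrow(rec) < 2) return(rec)
  snv <- which(rec$mclass == "SBS")
  if (length(snv) < 2) return(rec)
  drop <- logical(nrow(rec))
  merged <- list()
  i <- 1
  while (i < length(snv)) {
    a <- snv[i]; b <- snv[i + 1]
    if (!drop[a] && rec$chrom[a] == rec$chrom[b] && rec$pos[b] == rec$pos[a] + 1 &&
        rec$sample_id[a] == rec$sample_id[b]) {
      merged[[length(merged) + 1]] <- tibble(
        sample_id = rec$sample_id[a], chrom = rec$chrom[a], pos = rec$pos[a],
        ref = paste0(rec$ref[a], rec$ref[b]), alt = paste0(rec$alt[a], rec$alt[b]),
        mclass = "DBS",
        vaf = mean(c(rec$vaf[a], rec$vaf[b])),
        depth = mean(c(rec$depth[a], rec$depth[b]))
      )
      drop[c(a, b)] <- TRUE
      i <- i + 2
    } else {
      i <- i + 1
    }
  }
  if (length(merged) > 0) {
    inform(paste0("Merged ", length(merged),
                  " adjacent SNV pair(s) into doublet record(s)."))
    rec <- arrange(bind_rows(rec[!drop, , drop = FALSE], bind_rows(merged)),
                   .data$chrom, .data$pos)
  }
  rec
}

#' Write mutation records to a single-sample VCF
#'
#' Emits a VCF 4.2 file with `AF` and `DP` INFO fields. Doublets are written as
#' 2-bp MNP rows; indels are written in the anchored VCF convention (the base
#' before the event is included in REF/ALT), which requires the reference.
#'
#' @param records Mutation records for one sample.
#' @param path Output path.
#' @param reference Reference (required when records contain indels).
#' @return The path, invisibly.
#' @export
write_variants_vcf <- function(records, path, reference = NULL) {
  validate_records(records)
  if (length(unique(records$sample_id)) > 1) {
    abort("write_variants_vcf() writes one sample per file.")
  }
  has_indel <- any(records$mclass %in% c("INS", "DEL"))
  if (has_indel && is.null(reference)) {
    abort("Writing indels requires the `reference` for the VCF anchor base.")
  }
  if (!is.null(reference)) reference <- as_reference(reference)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=mutsigexp_", as.character(utils::packageVersion("mutsigexp"))),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (!is.null(reference)) {
      paste0("##contig=<ID=", names(reference), ",length=", nchar(reference), ">")
    },
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    pos <- records$pos[i]; ref <- records$ref[i]; alt <- records$alt[i]
    if (records$mclass[i] == "DEL") {
      anchor <- ref_slice(reference[[records$chrom[i]]], pos - 1L, pos - 1L)
      ref <- paste0(anchor, ref); alt <- anchor; pos <- pos - 1L
    } else if (records$mclass[i] == "INS") {
      anchor <- ref_slice(reference[[records$chrom[i]]], pos, pos)
      ref <- anchor; alt <- paste0(anchor, alt)
    }
    info <- character()
    if ("vaf" %in% names(records) && is.finite(records$vaf[i])) {
      info <- c(info, paste0("AF=", format(records$vaf[i], digits = 6)))
    }
    if ("depth" %in% names(records) && is.finite(records$depth[i])) {
      info <- c(info, paste0("DP=", records$depth[i]))
    }
    body[i] <- paste(records$chrom[i], pos, ".", ref, alt, ".", "PASS",
                     if (length(info) > 0) paste(info, collapse = ";") else ".",
                     sep = "\t")
  }
  ord <- order(records$chrom, records$pos)
  writeLines(c(header, body[ord]), path)
  invisible(path)
}

#' Read and write catalogs as TSV
#'
#' Catalogs round-trip through a plain TSV with the channel label in the first
#' column and one integer column per sample — small enough for human
#' inspection, which matters in this domain.
#'
#' @param catalog A `mut_catalog`.
#' @param path TSV path.
#' @param scheme Scheme the file is expected to match (labels are checked; an
#'   unknown label or a non-integer cell is an error).
#' @return `write_catalog()` returns the path invisibly; `read_catalog()`
#'   returns a `mut_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "mut_catalog"))
  readr::write_tsv(as_tibble(catalog), path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path, scheme) {
  stopifnot(inherits(scheme, "channel_scheme"))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"channel" %in% names(tbl)) abort("Catalog TSV must have a `channel` column.")
  unknown <- setdiff(tbl$channel, scheme$labels)
  if (length(unknown) > 0) {
    abort(paste0("Scheme mismatch: unknown channel label(s): ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  if (!setequal(tbl$channel, scheme$labels)) {
    abort("Catalog TSV does not cover every scheme channel.")
  }
  samples <- setdiff(names(tbl), "channel")
  m <- as.matrix(tbl[, samples, drop = FALSE])
  if (any(!is.finite(m)) || any(m != round(m)) || any(m < 0)) {
    abort("Catalog cells must be non-negative integers.")
  }
  m <- m[match(scheme$labels, tbl$channel), , drop = FALSE]
  rownames(m) <- scheme$labels
  storage.mode(m) <- "integer"
  new_mut_catalog(m, scheme)
}

#' Read and write lineage manifests
#'
#' Manifests are stored as TSV (columns `sample_id`, `role`, `parent_id`,
#' `condition`) or YAML (a list of sample entries with the same fields),
#' selected by file extension.
#'
#' @param manifest A [lineage_manifest()].
#' @param path File path ending in `.tsv` or `.yaml`/`.yml`.
#' @return `write_manifest()` the path invisibly; `read_manifest()` a
#'   validated `lineage_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- lineage_manifest(manifest)
  if (grepl("\\.ya?ml$", path)) {
    entries <- purrr::pmap(manifest, function(sample_id, role, parent_id, condition) {
      e <- list(sample_id = sample_id, role = role)
      if (!is.na(parent_id)) e$parent_id <- parent_id
      if (!is.na(condition)) e$condition <- condition
      e
    })
    yaml::write_yaml(list(samples = entries), path)
  } else {
    readr::write_tsv(as_tibble(manifest), path)
  }
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)$samples
    df <- bind_rows(lapply(raw, function(e) {
      tibble(sample_id = e$sample_id, role = e$role,
             parent_id = e$parent_id %||% NA_character_,
             condition = e$condition %||% NA_character_)
    }))
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  }
  lineage_manifest(df)
}

#' Read and write rearrangements as BEDPE
#'
#' BEDPE columns `chrom1, start1, end1, chrom2, start2, end2, name, score,
#' strand1, strand2, rtype`. On reading, intra-chromosomal events get a
#' fragment size of `start2 - start1` (breakend coordinates are 0-based
#' half-open per BEDPE); translocations (different chromosomes) carry no size.
#'
#' @param path BEDPE path.
#' @param sample_id Sample label for the records.
#' @return `read_bedpe()` a tibble of REARR records (`rtype`, `size_bp`);
#'   `write_bedpe()` the path invisibly.
#' @export
read_bedpe <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.bedpe$", "", basename(path))
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2", "rtype")
  tbl <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                         comment = "#")
  intra <- tbl$chrom1 == tbl$chrom2
  tibble(
    sample_id = sample_id, chrom = tbl$chrom1,
    pos = as.integer(tbl$start1 + 1L),
    ref = "N", alt = "N", mclass = "REARR",
    rtype = tbl$rtype,
    size_bp = ifelse(intra, abs(tbl$start2 - tbl$start1), NA_real_),
    chrom2 = tbl$chrom2, pos2 = as.integer(tbl$start2 + 1L)
  )
}

#' @rdname read_bedpe
#' @param records REARR mutation records with `rtype`, `size_bp` (and
#'   optionally `chrom2`, `pos2`).
#' @export
write_bedpe <- function(records, path) {
  if (!all(records$mclass == "REARR")) abort("write_bedpe() takes REARR records.")
  chrom2 <- records$chrom2 %||% records$chrom
  pos2 <- if ("pos2" %in% names(records)) {
    records$pos2
  } else {
    ifelse(is.na(records$size_bp), records$pos, records$pos + records$size_bp)
  }
  out <- data.frame(
    chrom1 = records$chrom, start1 = records$pos - 1L, end1 = records$pos,
    chrom2 = chrom2, start2 = pos2 - 1L, end2 = pos2,
    name = records$rtype, score = ".", strand1 = "+", strand2 = "+",
    rtype = records$rtype
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Export a synthetic experiment to standard formats
#'
#' Writes the reference FASTA, one VCF per sequenced sample, the manifest TSV,
#' and a JSON truth record into a directory.
#'
#' @param experiment A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(experiment$reference),
                              file.path(dir, "reference.fa"))
  for (s in experiment$manifest$sample_id) {
    rec <- experiment$records[experiment$records$sample_id == s, , drop = FALSE]
    write_variants_vcf(rec, file.path(dir, paste0(s, ".vcf")),
                       reference = experiment$reference)
  }
  write_manifest(experiment$manifest, file.path(dir, "manifest.tsv"))
  truth <- experiment$truth
  jsonlite::write_json(
    list(scenario = truth$scenario,
         treatment_burden = truth$treatment_burden,
         expected_vaf = truth$expected_vaf,
         burdens = truth$burdens,
         polyclonal_sample = truth$polyclonal_sample,
         mixed_groups = truth$mixed_groups,
         params = experiment$params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
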