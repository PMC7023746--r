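# Small sequence-string utilities shared across modules. These operate on
# plain character vectors of A/C/G/T (channel labels and short motifs), which
# keeps the classification hot path free of S4 container round-trips.

BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

rev_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

revcomp <- function(x) rev_string(comp_base(x))

is_acgt <- function(x) !is.na(x) & grepl("^[ACGT]+$", x)

#' Key a variant for identity comparisons
#'
#' Builds the `(chrom, pos, ref, alt)` key used for shared-variant counting and
#' de novo set arithmetic. Genotype and phase are deliberately ignored.
#'
#' @param records A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return A character vector of keys, one per record.
#' @export
variant_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

# 1-based inclusive substring lookup on a single reference chromosome string.
# All public coordinates are 1-based (VCF convention); this is the single
# audited conversion point onto R's substring arithmetic.
ref_slice <- function(seq, start, end) {
  substring(seq, pmax(start, 1L), pmin(end, nchar(seq)))
}

# Coerce a reference (named character vector, DNAStringSet, or FASTA path)
# to a named character vector of chromosome sequences.
as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", reference, ignore.case = TRUE)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (!is.character(reference) || is.null(names(reference))) {
    abort("`reference` must be a named character vector, DNAStringSet, or FASTA path.")
  }
  # FASTA headers may carry descriptions after the first token
  names(reference) <- sub("\\s.*$", "", names(reference))
  reference
}

#' @importFrom methods is
NULL
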