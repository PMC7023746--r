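# Channel classification for the four mutation classes. All classifiers are
# vectorised over their arguments and strand-agnostic where the scheme is.

#' Classify a single-base substitution into its 96-channel label
#'
#' The trinucleotide context 5' and 3' of the mutated base is taken into
#' account. Labels are pyrimidine-oriented: a purine reference (A or G) is
#' reverse-complemented together with its context, which swaps the 5' and 3'
#' flanks, so the classifier is invariant to the strand on which the call was
#' reported.
#'
#' @param context 3-nucleotide string(s) centred on the mutated base.
#' @param ref,alt Single reference and alternate bases; `ref` must equal the
#'   middle base of `context`.
#' @return Channel label(s) of the form `X[R>A]Y` with `R` in `{C, T}`.
#' @examples
#' classify_sbs("ACG", "C", "T")   # "A[C>T]G"
#' classify_sbs("AGG", "G", "T")   # "C[C>A]T" (reverse-complemented)
#' @export
classify_sbs <- function(context, ref, alt) {
  n <- max(length(context), length(ref), length(alt))
  context <- rep_len(toupper(context), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  if (!all(nchar(context) == 3)) abort("`context` must be 3 nucleotides.")
  if (!all(is_acgt(context) & is_acgt(ref) & is_acgt(alt)) ||
      !all(nchar(ref) == 1 & nchar(alt) == 1)) {
    abort("Bases must be drawn from A/C/G/T.")
  }
  if (!all(substr(context, 2, 2) == ref)) {
    abort("Middle base of `context` must equal `ref`.")
  }
  if (any(ref == alt)) abort("`ref` and `alt` must differ.")
  flip <- ref %in% c("A", "G")
  context[flip] <- revcomp(context[flip])
  ref[flip] <- comp_base(ref[flip])
  alt[flip] <- comp_base(alt[flip])
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3))
}

#' Classify a doublet-base substitution into its 78-channel label
#'
#' Doublets are strand-agnostic: each of the 144 ordered ref>alt dinucleotide
#' pairs is mapped to the canonical member of its {forward, reverse-complement}
#' pair. Canonical means the lexicographically smaller reference dinucleotide,
#' with ties (reverse-complement-palindromic references) broken by the smaller
#' alternate dinucleotide. Canonicalising all 144 pairs yields the 78 channels.
#'
#' @param ref,alt 2-nucleotide reference and alternate strings; both positions
#'   must differ between them.
#' @return Channel label(s) of the form `XY>ZW`.
#' @examples
#' classify_dbs("AA", "TT")  # "AA>TT"
#' classify_dbs("TT", "AA")  # "AA>TT" (reverse complement)
#' @export
classify_dbs <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  if (!all(is_acgt(ref) & is_acgt(alt) & nchar(ref) == 2 & nchar(alt) == 2)) {
    abort("`ref` and `alt` must be 2-nucleotide A/C/G/T strings.")
  }
  same <- substr(ref, 1, 1) == substr(alt, 1, 1) |
          substr(ref, 2, 2) == substr(alt, 2, 2)
  if (any(same)) abort("Not a doublet: both positions must differ between ref and alt.")
  rc_ref <- revcomp(ref)
  rc_alt <- revcomp(alt)
  flip <- rc_ref < ref | (rc_ref == ref & rc_alt < alt)
  ref[flip] <- rc_ref[flip]
  alt[flip] <- rc_alt[flip]
  paste0(ref, ">", alt)
}

#' Classify a doublet with flanking context (1248 channels)
#'
#' Extends the 78 doublet channels with one base of 5' and 3' context
#' (4 x 78 x 4 = 1248 channels). The flanks are reported relative to the
#' canonical orientation of the inner doublet: when the doublet itself is
#' flipped to its canonical strand the flanks are complemented and swapped;
#' when the inner doublet is already canonical in both orientations
#' (reverse-complement-palindromic pairs) the input orientation is kept.
#'
#' @param flank5,flank3 Single bases 5' and 3' of the doublet.
#' @inheritParams classify_dbs
#' @return Channel label(s) of the form `F[XY>ZW]G`.
#' @export
classify_dbs_flanked <- function(flank5, ref, alt, flank3) {
  n <- max(length(flank5), length(ref), length(alt), length(flank3))
  flank5 <- rep_len(toupper(flank5), n)
  flank3 <- rep_len(toupper(flank3), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  if (!all(is_acgt(flank5) & is_acgt(flank3) &
           nchar(flank5) == 1 & nchar(flank3) == 1)) {
    abort("Flanks must be single A/C/G/T bases.")
  }
  inner <- classify_dbs(ref, alt)  # validates the doublet
  rc_ref <- revcomp(ref)
  rc_alt <- revcomp(alt)
  flip <- rc_ref < ref | (rc_ref == ref & rc_alt < alt)
  new5 <- ifelse(flip, comp_base(flank3), flank5)
  new3 <- ifelse(flip, comp_base(flank5), flank3)
  paste0(new5, "[", inner, "]", new3)
}

count_adjacent_copies <- function(flank, motif, from_start) {
  k <- nchar(motif)
  n <- 0L
  repeat {
    piece <- if (from_start) {
      substr(flank, n * k + 1, (n + 1) * k)
    } else {
      len <- nchar(flank)
      substr(flank, len - (n + 1) * k + 1, len - n * k)
    }
    if (nchar(piece) < k || piece != motif) break
    n <- n + 1L
    if (n >= 10L) break  # cap well above the 5+ bin
  }
  n
}

#' Classify a small insertion or deletion
#'
#' Channels combine the indel class (insertion versus deletion), the motif
#' content and size (1 bp C/G, 1 bp T/A, or longer), and the nature of the
#' flanking sequence at the junction: repeat-mediated (`rep_N`, the number of
#' perfect copies of the indel motif adjacent in the reference, capped at 5+;
#' for deletions the count includes the deleted copy and is reported when >= 2,
#' for insertions when >= 1), junction microhomology (`mh`, >= 1 bp shared
#' between a >= 2 bp deletion and its flank when not repeat-mediated), or
#' `none`.
#'
#' @param mclass `"INS"` or `"DEL"`.
#' @param seq The inserted or deleted sequence (non-empty, < 100 bp).
#' @param flank5,flank3 Reference sequence immediately 5' and 3' of the event
#'   (each >= 50 bp so repeats and microhomology can be resolved).
#' @return A channel label such as `"del.1bp_T/A.rep_5+"` or `"ins.longer.none"`.
#' @examples
#' classify_indel("DEL", "T", strrep("A", 50), paste0("TTTT", strrep("A", 50)))
#' @export
classify_indel <- function(mclass, seq, flank5, flank3) {
  mclass <- toupper(mclass)
  if (length(mclass) > 1 || length(seq) > 1) {
    return(mapply(classify_indel, mclass, seq, flank5, flank3, USE.NAMES = FALSE))
  }
  if (!mclass %in% c("INS", "DEL")) abort("`mclass` must be INS or DEL.")
  seq <- toupper(seq); flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  if (!is_acgt(seq)) abort("Indel sequence must be a non-empty A/C/G/T string.")
  len <- nchar(seq)
  if (len >= 100) abort("Indel length must be < 100 bp (out of range).")
  if (nchar(flank5) < 50 || nchar(flank3) < 50 || !is_acgt(flank5) || !is_acgt(flank3)) {
    abort("Flanks must be A/C/G/T strings of at least 50 bp.")
  }
  size_part <- if (len == 1) {
    if (seq %in% c("C", "G")) "1bp_C/G" else "1bp_T/A"
  } else "longer"
  copies <- count_adjacent_copies(flank5, seq, from_start = FALSE) +
            count_adjacent_copies(flank3, seq, from_start = TRUE)
  if (mclass == "DEL") copies <- copies + 1L  # the deleted copy itself
  rep_floor <- if (mclass == "DEL") 2L else 1L
  mech <- if (copies >= rep_floor) {
    paste0("rep_", if (copies >= 5) "5+" else copies)
  } else if (mclass == "DEL" && len >= 2 &&
             (substr(flank3, 1, 1) == substr(seq, 1, 1) ||
              substr(flank5, nchar(flank5), nchar(flank5)) == substr(seq, len, len))) {
    "mh"
  } else "none"
  paste0(if (mclass == "INS") "ins" else "del", ".", size_part, ".", mech)
}

#' Classify a structural rearrangement
#'
#' Rearrangements are categorised by type — tandem duplication, deletion,
#' inversion, translocation — with intra-chromosomal types further binned by
#' the size of the rearranged fragment (five log-spaced bins).
#'
#' @param rtype One of `"tandem_duplication"`, `"deletion"`, `"inversion"`,
#'   `"translocation"` (vectorised).
#' @param size_bp Fragment size in bp; required (positive) for
#'   intra-chromosomal types and must be `NA` for translocations.
#' @return Labels such as `"TD.10-100kb"`, `"DEL.1-10Mb"`, `"TRANS"`.
#' @examples
#' classify_rearrangement("tandem_duplication", 50000)
#' classify_rearrangement("translocation", NA)
#' @export
classify_rearrangement <- function(rtype, size_bp = NA) {
  n <- max(length(rtype), length(size_bp))
  rtype <- rep_len(tolower(rtype), n)
  size_bp <- rep_len(size_bp, n)
  prefix <- c(tandem_duplication = "TD", deletion = "DEL", inversion = "INV",
              translocation = "TRANS")[rtype]
  if (anyNA(prefix)) abort("Unknown rearrangement type.")
  intra <- prefix != "TRANS"
  if (any(intra & (is.na(size_bp) | size_bp <= 0))) {
    abort("Intra-chromosomal rearrangements require a positive `size_bp`.")
  }
  if (any(!intra & !is.na(size_bp))) {
    abort("Translocations must not carry a `size_bp`.")
  }
  out <- rep("TRANS", n)
  if (any(intra)) {
    bin <- cut(size_bp[intra], breaks = c(0, 1e4, 1e5, 1e6, 1e7, Inf),
               labels = rearrangement_size_bins, right = FALSE)
    out[intra] <- paste0(prefix[intra], ".", as.character(bin))
  }
  out
}
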