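# Channel schemes: ordered, named label sets for one mutation class, plus
# optional collapse maps from a finer scheme onto this one.

new_channel_scheme <- function(name, labels, class_covered, collapse_map = NULL) {
  stopifnot(is.character(labels), !anyDuplicated(labels))
  if (!is.null(collapse_map)) {
    if (is.null(names(collapse_map)) || !all(collapse_map %in% labels)) {
      abort("`collapse_map` must be a named vector mapping fine labels onto scheme labels.")
    }
    if (!all(labels %in% collapse_map)) {
      abort("`collapse_map` must be surjective onto the scheme labels.")
    }
  }
  structure(
    list(name = name, labels = labels, class_covered = class_covered,
         collapse_map = collapse_map),
    class = "channel_scheme"
  )
}

#' @export
print.channel_scheme <- function(x, ...) {
  cat("<channel_scheme> ", x$name, ": ", length(x$labels), " channels (",
      x$class_covered, ")\n", sep = "")
  cat(" ", paste(head(x$labels, 6), collapse = ", "),
      if (length(x$labels) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Channel schemes for the four mutation classes
#'
#' Constructors for the channel sets used throughout the package:
#'
#' * `sbs96_scheme()` — the 96 single-base-substitution channels: 6 pyrimidine
#'   substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) in 16 trinucleotide
#'   contexts, labelled `X[R>A]Y`.
#' * `sbs6_scheme()` — the 6 substitution classes, with a collapse map from the
#'   96-channel scheme (each class pools its 16 contexts).
#' * `dbs78_scheme()` — the 78 strand-agnostic doublet-base-substitution
#'   channels, labelled `XY>ZW` in canonical orientation.
#' * `dbs1248_scheme()` — the flank-extended doublet channels
#'   (4 x 78 x 4 = 1248), labelled `F[XY>ZW]G`; flanks are reported relative to
#'   the canonical orientation of the inner doublet.
#' * `indel_scheme()` — small insertion/deletion channels combining class
#'   (ins/del), motif content and size (1 bp C/G, 1 bp T/A, longer), and the
#'   flanking-sequence mechanism (repeat-mediated `rep_N`, microhomology `mh`,
#'   or `none`); 34 channels.
#' * `rearrangement_scheme()` — tandem duplications, deletions and inversions in
#'   five size bins, plus translocations; 16 channels.
#'
#' @return A `channel_scheme` object: an ordered label set with the mutation
#'   class it covers and, for `sbs6_scheme()`, a collapse map from SBS-96.
#' @examples
#' sbs96_scheme()
#' length(dbs78_scheme()$labels)
#' @name channel_schemes
NULL

sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    unlist(lapply(BASES, function(f5) paste0(f5, "[", s, "]", BASES)))
  }))
}

#' @rdname channel_schemes
#' @export
sbs96_scheme <- function() {
  new_channel_scheme("SBS96", sbs96_labels(), "SBS")
}

#' @rdname channel_schemes
#' @export
sbs6_scheme <- function() {
  fine <- sbs96_labels()
  map <- setNames(substr(fine, 3, 5), fine)
  new_channel_scheme("SBS6", c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"),
                     "SBS", collapse_map = map)
}

dbs78_labels <- function() {
  dinucs <- as.vector(outer(BASES, BASES, paste0))
  pairs <- expand.grid(ref = dinucs, alt = dinucs, stringsAsFactors = FALSE)
  pairs <- pairs[substr(pairs$ref, 1, 1) != substr(pairs$alt, 1, 1) &
                 substr(pairs$ref, 2, 2) != substr(pairs$alt, 2, 2), ]
  sort(unique(classify_dbs(pairs$ref, pairs$alt)))
}

#' @rdname channel_schemes
#' @export
dbs78_scheme <- function() {
  new_channel_scheme("DBS78", dbs78_labels(), "DBS")
}

#' @rdname channel_schemes
#' @export
dbs1248_scheme <- function() {
  inner <- dbs78_labels()
  labels <- unlist(lapply(inner, function(d) {
    as.vector(outer(BASES, BASES, function(f5, f3) paste0(f5, "[", d, "]", f3)))
  }))
  new_channel_scheme("DBS1248", labels, "DBS")
}

indel_labels <- function() {
  rep_ins <- c("none", paste0("rep_", 1:4), "rep_5+")
  rep_del <- c("none", paste0("rep_", 2:4), "rep_5+")
  c(
    paste0("ins.1bp_C/G.", rep_ins),
    paste0("ins.1bp_T/A.", rep_ins),
    paste0("ins.longer.", rep_ins),
    paste0("del.1bp_C/G.", rep_del),
    paste0("del.1bp_T/A.", rep_del),
    paste0("del.longer.", c(rep_del, "mh"))
  )
}

#' @rdname channel_schemes
#' @export
indel_scheme <- function() {
  new_channel_scheme("ID34", indel_labels(), "indel")
}

rearrangement_size_bins <- c("<10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")

#' @rdname channel_schemes
#' @export
rearrangement_scheme <- function() {
  labels <- c(as.vector(outer(c("TD", "DEL", "INV"), rearrangement_size_bins,
                              paste, sep = ".")), "TRANS")
  new_channel_scheme("RS16", labels, "REARR")
}

#' Construct a signature profile over a channel scheme
#'
#' A signature profile is a non-negative weight per channel. Weights are
#' normalised to sum to one unless all are zero (the explicitly empty
#' signature, used when background subtraction removes everything).
#'
#' @param weights Numeric vector of non-negative weights. May be named by
#'   channel label; unnamed weights are matched to `scheme$labels` by position.
#' @param scheme A [channel_scheme][channel_schemes] the profile lives on.
#' @param normalize Divide by the total weight (default `TRUE`). Use `FALSE`
#'   to keep raw weights, e.g. when conserving mass through a collapse.
#' @return A `signature_profile`: named numeric vector with the scheme attached.
#' @examples
#' sig <- signature_profile(rep(1, 96), sbs96_scheme())
#' sum(sig)
#' @export
signature_profile <- function(weights, scheme, normalize = TRUE) {
  stopifnot(inherits(scheme, "channel_scheme"))
  if (is.null(names(weights))) {
    if (length(weights) != length(scheme$labels)) {
      abort("Unnamed `weights` must have one entry per scheme channel.")
    }
    names(weights) <- scheme$labels
  } else {
    missing <- setdiff(names(weights), scheme$labels)
    if (length(missing) > 0) {
      abort(paste0("Unknown channel label(s): ", paste(head(missing, 3), collapse = ", ")))
    }
    weights <- weights[match(scheme$labels, names(weights))]
    weights[is.na(weights)] <- 0
    names(weights) <- scheme$labels
  }
  if (any(weights < 0)) abort("Signature weights must be non-negative.")
  total <- sum(weights)
  if (normalize && total > 0) weights <- weights / total
  structure(weights, scheme = scheme$name, labels = scheme$labels,
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat("<signature_profile> on ", attr(x, "scheme"), " (", length(x),
      " channels, total weight ", format(sum(x)), ")\n", sep = "")
  top <- sort(unclass(x), decreasing = TRUE)
  top <- top[top > 0]
  cat("  top channels: ",
      paste(sprintf("%s=%.3f", names(head(top, 5)), head(top, 5)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.signature_profile <- function(x, ...) {
  tibble(channel = names(x), weight = as.numeric(x))
}

#' Collapse a signature onto a coarser channel scheme
#'
#' Pools the weights of a finer-grained signature (for example a cancer-derived
#' 96-channel signature) onto the channels actually used for an experiment,
#' following the target scheme's collapse map. Total weight is conserved; this
#' is the recommended direction of comparison between cancer-derived and
#' experimentally derived signatures (collapse the cancer signature, do not
#' stretch the experimental channels).
#'
#' @param sig A [signature_profile()] on the fine scheme.
#' @param target A [channel_scheme][channel_schemes] carrying a `collapse_map`
#'   covering every fine label.
#' @return A `signature_profile` on `target` with the pooled weights.
#' @examples
#' fine <- signature_profile(rep(1, 96), sbs96_scheme())
#' collapse_signature(fine, sbs6_scheme())
#' @export
collapse_signature <- function(sig, target) {
  stopifnot(inherits(sig, "signature_profile"), inherits(target, "channel_scheme"))
  map <- target$collapse_map
  if (is.null(map)) abort("`target` scheme has no collapse_map.")
  missing <- setdiff(names(sig), names(map))
  if (length(missing) > 0) {
    abort(paste0("Fine label(s) missing from collapse map: ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  pooled <- tapply(as.numeric(sig), map[names(sig)], sum)
  out <- setNames(numeric(length(target$labels)), target$labels)
  out[names(pooled)] <- pooled
  signature_profile(out, target, normalize = FALSE)
}

# Resolve a scheme by name (CLI and readers).
scheme_by_name <- function(name) {
  switch(tolower(name),
    sbs96 = sbs96_scheme(),
    sbs6 = sbs6_scheme(),
    dbs78 = dbs78_scheme(),
    dbs1248 = dbs1248_scheme(),
    id34 = , indel = indel_scheme(),
    rs16 = , rearrangement = rearrangement_scheme(),
    abort(paste0("Unknown scheme: ", name))
  )
}
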