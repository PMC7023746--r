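# Synthetic experiments with the statistical structure the framework assumes:
# lineages with genealogical variant sharing, signature-mixture catalogs,
# ploidy/depth-driven VAFs, and planted QC failure modes.

#' Example signatures for simulations
#'
#' `example_background_signature()` is a fixed, peaked 96-channel profile
#' emulating the intrinsic mutagenesis of cells in culture: dominated by C>A
#' channels (the oxidative-stress-like pattern typical of culture backgrounds)
#' over a small uniform floor. `peaked_signature()` draws a sparse signature
#' with `n_peaks` dominant channels — the shape for which cosine similarity and
#' background subtraction are most informative.
#'
#' @param scheme Channel scheme (default [sbs96_scheme()]).
#' @param n_peaks Number of dominant channels.
#' @param peak_weight Total weight shared equally by the peaks (default 0.9;
#'   the remainder is spread uniformly).
#' @param seed Integer seed choosing the peak channels.
#' @return A [signature_profile()].
#' @name example_signatures
#' @export
example_background_signature <- function(scheme = sbs96_scheme()) {
  w <- setNames(rep(0.25 / length(scheme$labels), length(scheme$labels)),
                scheme$labels)
  peaks <- c("A[C>A]A", "C[C>A]C", "T[C>A]T", "G[C>A]A")
  peaks <- intersect(peaks, scheme$labels)
  w[peaks] <- w[peaks] + 0.75 / length(peaks)
  signature_profile(w, scheme)
}

#' @rdname example_signatures
#' @export
peaked_signature <- function(scheme = sbs96_scheme(), n_peaks = 5,
                             peak_weight = 0.9, seed = 1) {
  labels <- scheme$labels
  peaks <- withr::with_seed(seed, sample(labels, n_peaks))
  w <- setNames(rep((1 - peak_weight) / length(labels), length(labels)), labels)
  w[peaks] <- w[peaks] + peak_weight / n_peaks
  signature_profile(w, scheme)
}

#' Generate a random reference sequence
#'
#' A uniform-composition A/C/G/T sequence, deterministic for a given seed,
#' optionally written to a standard FASTA file.
#'
#' @param length Sequence length (>= 10000 so channel contexts are plentiful).
#' @param seed Integer seed.
#' @param path Optional FASTA path to write (via Biostrings).
#' @param chrom Chromosome name (default `"chrS"`).
#' @return A named character vector of length one (the reference), invisibly
#'   carrying the path written, if any.
#' @export
make_reference <- function(length, seed = 1, path = NULL, chrom = "chrS") {
  if (length < 10000) abort("`length` must be at least 10000.")
  seq <- withr::with_seed(seed,
    paste(sample(BASES, length, replace = TRUE), collapse = ""))
  ref <- setNames(seq, chrom)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path)
  }
  ref
}

# Index of trinucleotide contexts: for each trinucleotide, the global (genome-
# concatenated) centre coordinates at which it occurs. Built once per reference
# and reused for every placement draw; global integer coordinates keep the
# placement loop allocation-free.
trinuc_index <- function(reference) {
  reference <- as_reference(reference)
  offsets <- cumsum(c(0, nchar(reference)))
  pos <- list()
  for (i in seq_along(reference)) {
    s <- reference[[i]]
    L <- nchar(s)
    if (L < 3) next
    tri <- substring(s, 1:(L - 2), 3:L)
    centre <- offsets[i] + 2:(L - 1)
    ok <- grepl("^[ACGT]{3}$", tri)
    for (t in names(sp <- split(centre[ok], tri[ok]))) {
      pos[[t]] <- c(pos[[t]], sp[[t]])
    }
  }
  structure(list(pos = pos, chroms = names(reference),
                 offsets = offsets, genome_length = offsets[length(offsets)]),
            class = "trinuc_index")
}

global_to_locus <- function(g, index) {
  ci <- findInterval(g - 0.5, index$offsets)
  list(chrom = index$chroms[ci], pos = as.integer(g - index$offsets[ci]))
}

locus_to_global <- function(chrom, pos, index) {
  index$offsets[match(chrom, index$chroms)] + pos
}

#' Draw mutation records from a signature
#'
#' Draws channel counts from the multinomial defined by the signature weights
#' and places each mutation at a uniformly chosen reference locus whose
#' trinucleotide context matches its channel (on either strand). Loci are
#' unique within a draw and never collide with `exclude`; re-classifying the
#' output reproduces the drawn channel counts exactly.
#'
#' @param signature A [signature_profile()] on the 96-channel SBS scheme.
#' @param burden Number of mutations to draw (>= 0).
#' @param reference Reference sequence (named character vector, DNAStringSet,
#'   or FASTA path).
#' @param seed Integer seed, or `NULL` to use the current RNG state (as when
#'   called inside [simulate_experiment()], which seeds the whole generation).
#' @param sample_id Sample label for the records.
#' @param exclude Character vector of `chrom:pos` locus keys to avoid.
#' @param index Prebuilt `trinuc_index` of the reference (built if missing).
#' @param .used Internal: a shared occupancy environment used by
#'   [simulate_experiment()] to keep loci unique across samples.
#' @return A tibble of SBS mutation records.
#' @export
sample_mutations <- function(signature, burden, reference, seed = NULL,
                             sample_id = "S1", exclude = character(),
                             index = NULL, .used = NULL) {
  stopifnot(inherits(signature, "signature_profile"))
  if (burden < 0) abort("`burden` must be non-negative.")
  empty <- tibble(sample_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), mclass = character())
  if (burden == 0) return(empty)
  if (sum(signature) == 0) abort("Cannot draw from an empty signature.")
  if (is.null(index)) index <- trinuc_index(reference)
  if (is.null(.used)) {
    .used <- new.env(parent = emptyenv())
    .used$mask <- logical(index$genome_length)
    if (length(exclude) > 0) {
      parts <- strsplit(exclude, ":", fixed = TRUE)
      g <- locus_to_global(vapply(parts, `[`, "", 1),
                           as.integer(vapply(parts, `[`, "", 2)), index)
      .used$mask[g[!is.na(g)]] <- TRUE
    }
  }

  draw <- function() {
    counts <- as.vector(rmultinom(1, burden, as.numeric(signature)))
    names(counts) <- names(signature)
    labs <- names(counts)[counts > 0]
    g_all <- integer(burden)
    ref_all <- character(burden)
    alt_all <- character(burden)
    filled <- 0L
    for (lab in labs) {
      k <- counts[[lab]]
      r <- substr(lab, 3, 3); a <- substr(lab, 5, 5)
      fwd <- paste0(substr(lab, 1, 1), r, substr(lab, 7, 7))
      rc <- revcomp(fwd)
      pool <- c(index$pos[[fwd]], index$pos[[rc]])
      n_fwd <- length(index$pos[[fwd]])
      is_fwd <- seq_along(pool) <= n_fwd
      free <- !.used$mask[pool]
      if (sum(free) < k) {
        abort(paste0("Placement error: not enough reference loci with context ",
                     "for channel ", lab, " (need ", k, ")."))
      }
      pool <- pool[free]; is_fwd <- is_fwd[free]
      pick <- sample.int(length(pool), k)
      g <- pool[pick]
      .used$mask[g] <- TRUE
      at <- filled + seq_len(k)
      g_all[at] <- g
      ref_all[at] <- ifelse(is_fwd[pick], r, comp_base(r))
      alt_all[at] <- ifelse(is_fwd[pick], a, comp_base(a))
      filled <- filled + k
    }
    loc <- global_to_locus(g_all, index)
    arrange(tibble(sample_id = sample_id, chrom = loc$chrom, pos = loc$pos,
                   ref = ref_all, alt = alt_all, mclass = "SBS"),
            .data$chrom, .data$pos)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a full subcloning experiment
#'
#' Generates a synthetic lineage with the generative structure the analytical
#' framework assumes. Each parental clone carries `parental_burden` background
#' mutations shared by descent with all of its subclones; each subclone adds
#' `private_burden` private background mutations (its own mutation-accumulation
#' phase) and, when its lineage is experimental, `treatment_burden` draws from
#' the treatment signature — the linear-combination model of experimental
#' mutagenesis. VAFs are binomial read-sampling at the ploidy-determined
#' expectation (`mutated_copies / ploidy` at the given depth); all loci are
#' unique within the experiment.
#'
#' Planted QC failure modes (`scenario`):
#' * `"clean"` — no defect;
#' * `"wrong_parent"` — the sample sequenced as the first parent is an
#'   unrelated clone (the subclones' true parent was never sequenced);
#' * `"mixed_parental"` — the first parent's declared subclones actually derive
#'   from two different parental lineages (with 6 subclones the groups are
#'   subclones 1, 4, 6 versus 2, 3, 5);
#' * `"polyclonal"` — the first subclone is not single-cell derived: half of
#'   its de novo mutations are carried by only half of its cells, halving
#'   their expected VAF.
#'
#' @param scenario One of `"clean"`, `"wrong_parent"`, `"mixed_parental"`,
#'   `"polyclonal"`.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param n_parents Number of parental clones (first `n_control_parents` are
#'   control lineages, the rest are experimental).
#' @param subclones_per_parent Subclones sequenced per parent.
#' @param parental_burden Background mutations shared by descent per lineage.
#' @param private_burden Private background mutations per subclone (the
#'   interface to the number of doublings in the accumulation phase).
#' @param background_signature,treatment_signature 96-channel
#'   [signature_profile()]s; a treatment signature is required when
#'   `treatment_burden > 0`.
#' @param treatment_burden Treatment-attributable mutations per experimental
#'   subclone.
#' @param ploidy,mutated_copies Ploidy model for expected VAFs.
#' @param depth Sequencing depth for binomial VAF sampling.
#' @param reference Optional reference (generated when `NULL`).
#' @param reference_length Length of the generated reference.
#' @param n_control_parents Number of control lineages (default 1).
#' @return A `synthetic_experiment`: `records` (all samples, with `vaf`,
#'   `depth` and an `origin` column), `manifest`, `reference`, and `truth`
#'   (planted signatures, burdens, scenario labels).
#' @export
simulate_experiment <- function(scenario = c("clean", "wrong_parent",
                                             "mixed_parental", "polyclonal"),
                                seed = 1,
                                n_parents = 2, subclones_per_parent = 4,
                                parental_burden = 200, private_burden = 150,
                                background_signature = example_background_signature(),
                                treatment_signature = NULL, treatment_burden = 0,
                                ploidy = 2, mutated_copies = 1, depth = 30,
                                reference = NULL, reference_length = 200000,
                                n_control_parents = 1) {
  scenario <- match.arg(scenario)
  if (treatment_burden > 0 && is.null(treatment_signature)) {
    abort("Config error: `treatment_burden > 0` requires a `treatment_signature`.")
  }
  if (n_parents < 1 || subclones_per_parent < 1 ||
      parental_burden < 0 || private_burden < 0 || treatment_burden < 0) {
    abort("Config error: counts and burdens must be non-negative.")
  }
  if (scenario == "mixed_parental" && subclones_per_parent < 2) {
    abort("Config error: mixed_parental needs at least 2 subclones per parent.")
  }
  p_clonal <- expected_vaf(ploidy, mutated_copies)

  withr::with_seed(seed, {
    if (is.null(reference)) {
      reference <- setNames(paste(sample(BASES, reference_length, replace = TRUE),
                                  collapse = ""), "chrS")
    } else {
      reference <- as_reference(reference)
    }
    index <- trinuc_index(reference)
    used <- new.env(parent = emptyenv())
    used$mask <- logical(index$genome_length)
    draw <- function(sig, burden, sample_id, origin) {
      rec <- sample_mutations(sig, burden, reference, seed = NULL,
                              sample_id = sample_id, index = index,
                              .used = used)
      if (nrow(rec) > 0) rec$origin <- origin
      rec
    }
    add_vaf <- function(rec, p) {
      rec$vaf <- rbinom(nrow(rec), depth, rep_len(p, nrow(rec))) / depth
      rec$depth <- depth
      rec
    }
    relabel <- function(rec, sample_id) { rec$sample_id <- sample_id; rec }

    parents <- paste0("P", seq_len(n_parents))
    man_rows <- list(tibble(sample_id = "GP", role = "grandparent",
                            parent_id = NA_character_, condition = NA_character_))
    rec_rows <- list()
    truth_burden <- list()
    mixed_groups <- NULL
    polyclonal_sample <- NA_character_

    for (i in seq_len(n_parents)) {
      p_id <- parents[i]
      experimental <- i > n_control_parents && n_parents > 1
      cond <- if (experimental) "experimental:treated" else "control"
      man_rows[[length(man_rows) + 1]] <-
        tibble(sample_id = p_id, role = "parent", parent_id = "GP",
               condition = NA_character_)

      lineage_set <- draw(background_signature, parental_burden, p_id, "parental")
      parent_sample <- lineage_set
      hidden_set <- NULL
      if (scenario == "wrong_parent" && i == 1) {
        # an unrelated clone was sequenced under the parent's label
        parent_sample <- draw(background_signature, parental_burden, p_id, "parental")
      }
      if (scenario == "mixed_parental" && i == 1) {
        hidden_set <- draw(background_signature, parental_burden, p_id, "parental")
        n_s <- subclones_per_parent
        idx_b <- if (n_s == 6) c(2L, 3L, 5L) else seq(2L, n_s, by = 2L)
        mixed_groups <- list(group_a = setdiff(seq_len(n_s), idx_b), group_b = idx_b)
      }
      rec_rows[[p_id]] <- add_vaf(parent_sample, p_clonal)

      for (j in seq_len(subclones_per_parent)) {
        s_id <- paste0(p_id, "_s", j)
        man_rows[[length(man_rows) + 1]] <-
          tibble(sample_id = s_id, role = "subclone", parent_id = p_id,
                 condition = cond)
        inherit_from <- if (!is.null(hidden_set) && j %in% mixed_groups$group_b) {
          hidden_set
        } else lineage_set
        inherited <- relabel(inherit_from, s_id)
        inherited$origin <- "inherited"
        private <- draw(background_signature, private_burden, s_id, "private")
        treated <- if (experimental && treatment_burden > 0) {
          draw(treatment_signature, treatment_burden, s_id, "treatment")
        } else NULL
        de_novo <- bind_rows(private, treated)
        if (scenario == "polyclonal" && i == 1 && j == 1 && nrow(de_novo) > 0) {
          polyclonal_sample <- s_id
          half <- sample.int(nrow(de_novo), floor(nrow(de_novo) / 2))
          p_vec <- rep(p_clonal, nrow(de_novo))
          p_vec[half] <- p_clonal / 2
          de_novo <- add_vaf(de_novo, p_vec)
        } else {
          de_novo <- add_vaf(de_novo, p_clonal)
        }
        rec_rows[[s_id]] <- bind_rows(add_vaf(inherited, p_clonal), de_novo)
        truth_burden[[s_id]] <- tibble(
          sample_id = s_id, parent_id = p_id, condition = cond,
          inherited = nrow(inherited), private = nrow(private),
          treatment = if (is.null(treated)) 0L else nrow(treated)
        )
      }
    }

    records <- bind_rows(rec_rows)
    manifest <- lineage_manifest(bind_rows(man_rows))
    structure(
      list(records = records, manifest = manifest, reference = reference,
           truth = list(scenario = scenario,
                        background_signature = background_signature,
                        treatment_signature = treatment_signature,
                        treatment_burden = treatment_burden,
                        burdens = bind_rows(truth_burden),
                        mixed_groups = mixed_groups,
                        polyclonal_sample = polyclonal_sample,
                        expected_vaf = p_clonal),
           params = list(seed = seed, n_parents = n_parents,
                         subclones_per_parent = subclones_per_parent,
                         parental_burden = parental_burden,
                         private_burden = private_burden,
                         treatment_burden = treatment_burden,
                         ploidy = ploidy, mutated_copies = mutated_copies,
                         depth = depth, n_control_parents = n_control_parents)),
      class = "synthetic_experiment"
    )
  })
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> scenario ", x$truth$scenario, ", seed ",
      x$params$seed, "\n  ", length(unique(x$records$sample_id)),
      " sequenced samples, ", nrow(x$records), " mutation records\n", sep = "")
  invisible(x)
}

#' De novo records of a subclone
#'
#' The subclone's mutations minus those of its declared parent — the calls an
#' analysis against the parental clone would yield.
#'
#' @param experiment A [simulate_experiment()] result or any records + manifest
#'   pair via the method arguments.
#' @param sample_id Subclone sample id.
#' @return A tibble of de novo mutation records.
#' @export
de_novo_records <- function(experiment, sample_id) {
  records <- experiment$records
  manifest <- experiment$manifest
  parent <- manifest$parent_id[manifest$sample_id == sample_id]
  rec_s <- records[records$sample_id == sample_id, , drop = FALSE]
  parent_keys <- variant_key(records[records$sample_id == parent, , drop = FALSE])
  as_tibble(rec_s[!variant_key(rec_s) %in% parent_keys, , drop = FALSE])
}
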