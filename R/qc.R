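# Quality control: ploidy-aware VAF clonality, shared-variant relatedness,
# lineage-scenario classification, and on-target edit verification.

#' Build and validate a lineage manifest
#'
#' The manifest declares the sample genealogy of an experiment: one
#' grandparental reference, parental clones derived from it, and single-cell
#' subclones of each parent, together with the condition of each subclone
#' (`"control"` or `"experimental:<name>"`).
#'
#' @param df A data frame with columns `sample_id`, `role` (one of
#'   `grandparent`, `parent`, `subclone`), `parent_id` (`NA` for the
#'   grandparent), and `condition` (`NA` allowed for non-subclones).
#' @return A `lineage_manifest` (a validated tibble).
#' @export
lineage_manifest <- function(df) {
  required <- c("sample_id", "role", "parent_id", "condition")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("Manifest is missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)[, required]
  if (anyDuplicated(df$sample_id)) abort("Sample ids must be unique.")
  if (!all(df$role %in% c("grandparent", "parent", "subclone"))) {
    abort("`role` must be grandparent, parent, or subclone.")
  }
  subs <- df[df$role == "subclone", ]
  parents <- df$sample_id[df$role == "parent"]
  if (any(is.na(subs$parent_id)) || !all(subs$parent_id %in% parents)) {
    abort("Every subclone must declare exactly one parent present in the manifest.")
  }
  ok_cond <- is.na(df$condition) |
    df$condition == "control" | grepl("^experimental:", df$condition)
  if (!all(ok_cond)) {
    abort("`condition` must be \"control\" or \"experimental:<name>\".")
  }
  structure(df, class = c("lineage_manifest", class(df)))
}

manifest_parents <- function(manifest) {
  manifest$sample_id[manifest$role == "parent"]
}

manifest_children <- function(manifest, parent_id) {
  manifest$sample_id[manifest$role == "subclone" &
                     !is.na(manifest$parent_id) & manifest$parent_id == parent_id]
}

#' Samples of a manifest by condition
#'
#' @param manifest A [lineage_manifest()].
#' @param condition `"control"` or an `"experimental:<name>"` label.
#' @return Character vector of subclone sample ids with that condition.
#' @export
condition_samples <- function(manifest, condition) {
  manifest$sample_id[!is.na(manifest$condition) & manifest$condition == condition]
}

#' Expected variant allele fraction under a ploidy model
#'
#' For a clonal mutation present on `mutated_copies` of `ploidy` total copies,
#' every cell carries it, and the expected fraction of sequencing reads showing
#' the variant is `mutated_copies / ploidy`: 0.5 for a heterozygous mutation in
#' a diploid model, 1 in a haploid, about 0.33 for a single copy in a triploid.
#'
#' @param ploidy Positive integer number of copies at the locus.
#' @param mutated_copies Positive integer number of mutated copies
#'   (default 1, the de novo case); must not exceed `ploidy`.
#' @return The expected VAF as a fraction.
#' @examples
#' expected_vaf(2, 1)  # 0.5
#' expected_vaf(3, 1)  # 0.333...
#' @export
expected_vaf <- function(ploidy, mutated_copies = 1) {
  if (any(ploidy < 1) || any(ploidy != round(ploidy)) ||
      any(mutated_copies < 1) || any(mutated_copies != round(mutated_copies))) {
    abort("`ploidy` and `mutated_copies` must be positive integers.")
  }
  if (any(mutated_copies > ploidy)) {
    abort("`mutated_copies` cannot exceed `ploidy`.")
  }
  mutated_copies / ploidy
}

#' VAF-based clonality check for a subclone
#'
#' Tests whether a subclone's de novo mutations look clonal: for a truly
#' single-cell-derived sample their VAFs scatter around the ploidy-determined
#' expectation, whereas a polyclonal or mosaic subclone shows a depressed mean
#' VAF (and a falsely elevated mutation burden, since subclonal mutations are
#' still counted). The verdict is `polyclonal_suspect` only when a one-sided
#' test that the mean VAF lies below expectation rejects at `alpha` *and* the
#' observed mean falls below `effect_floor` times the expectation — the effect
#' floor prevents deep sequencing from flagging trivial deviations.
#'
#' @param vafs Numeric vector of variant allele fractions (de novo mutations).
#' @param depths Integer read depths matching `vafs` (recorded in the report).
#' @param ploidy,mutated_copies Passed to [expected_vaf()].
#' @param alpha Significance level of the one-sided test (default 0.001).
#' @param effect_floor Effect-size floor as a fraction of the expected VAF
#'   (default 0.8).
#' @param sample_id Optional sample label for the report.
#' @return A `clonality_report` with the expected and observed mean VAF, the
#'   number of usable mutations, the test p-value, and the verdict. Fewer than
#'   20 usable mutations is an error (QC inconclusive, not a verdict).
#' @export
clonality_check <- function(vafs, depths = NULL, ploidy = 2, mutated_copies = 1,
                            alpha = 0.001, effect_floor = 0.8,
                            sample_id = NA_character_) {
  usable <- is.finite(vafs)
  if (!is.null(depths)) usable <- usable & is.finite(depths)
  vafs <- vafs[usable]
  if (length(vafs) < 20) {
    abort("Insufficient data: clonality assessment needs >= 20 mutations with VAF and depth.")
  }
  exp_vaf <- expected_vaf(ploidy, mutated_copies)
  obs <- mean(vafs)
  p <- stats::t.test(vafs, mu = exp_vaf, alternative = "less")$p.value
  suspect <- (p <= alpha) && (obs < effect_floor * exp_vaf)
  note <- if (suspect) {
    paste0("Mean VAF well below the ploidy expectation: consistent with a ",
           "polyclonal/mosaic subclone; lower average VAFs imply falsely ",
           "elevated mutation burdens, so quantitative burden is unreliable ",
           "(the mutational profile itself is usually unaffected).")
  } else {
    "VAF distribution consistent with a single-cell-derived (clonal) subclone."
  }
  structure(
    list(sample_id = sample_id, expected_vaf = exp_vaf, observed_mean_vaf = obs,
         n_mutations = length(vafs), p_value = p,
         mean_depth = if (is.null(depths)) NA_real_ else mean(depths[usable], na.rm = TRUE),
         verdict = if (suspect) "polyclonal_suspect" else "clonal", note = note),
    class = "clonality_report"
  )
}

#' @export
print.clonality_report <- function(x, ...) {
  cat("<clonality_report>", if (!is.na(x$sample_id)) x$sample_id else "", "\n",
      sprintf("  expected VAF %.3f, observed mean %.3f over %d mutations (p = %.3g)\n",
              x$expected_vaf, x$observed_mean_vaf, x$n_mutations, x$p_value),
      "  verdict: ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.clonality_report <- function(x, ...) {
  tibble(sample_id = x$sample_id, expected_vaf = x$expected_vaf,
         observed_mean_vaf = x$observed_mean_vaf, n_mutations = x$n_mutations,
         p_value = x$p_value, verdict = x$verdict, note = x$note)
}

#' Shared-variant matrix between samples
#'
#' Counts variants (keyed by chrom, pos, ref, alt) shared between every pair of
#' samples. Because all subclones inherit their parent's mutations, this matrix
#' exposes sample swaps, wrongly sequenced parents and mixed parental
#' populations.
#'
#' @param variants_by_sample Either a named list of variant-key character
#'   vectors (one per sample) or a records data frame with a `sample_id`
#'   column, which is keyed with [variant_key()].
#' @return A `shared_variants` object holding the symmetric count matrix; the
#'   diagonal equals each sample's burden.
#' @export
shared_variant_matrix <- function(variants_by_sample) {
  if (is.data.frame(variants_by_sample)) {
    validate_records(variants_by_sample)
    variants_by_sample <- split(variant_key(variants_by_sample),
                                variants_by_sample$sample_id)
  }
  if (is.null(names(variants_by_sample))) abort("Samples must be named.")
  sets <- lapply(variants_by_sample, unique)
  ids <- names(sets)
  k <- length(ids)
  shared <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    shared[i, i] <- length(sets[[i]])
    for (j in seq_len(i - 1L)) {
      shared[i, j] <- shared[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  structure(list(sample_ids = ids, shared = shared,
                 burdens = setNames(diag(shared), ids)),
            class = "shared_variants")
}

#' @export
print.shared_variants <- function(x, ...) {
  cat("<shared_variants> ", length(x$sample_ids), " samples\n", sep = "")
  print(x$shared)
  invisible(x)
}

#' @export
tidy.shared_variants <- function(x, ...) {
  as_tibble(as.data.frame.table(x$shared, responseName = "shared",
                                stringsAsFactors = FALSE)) |>
    rename(sample_a = "Var1", sample_b = "Var2")
}

# Connected components of the sibling graph under a shared-fraction cut,
# equivalent to cutting a single-linkage tree at theta_s.
sibling_clusters <- function(shared, burdens, ids, theta_s) {
  k <- length(ids)
  frac <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    denom <- min(burdens[ids[i]], burdens[ids[j]])
    frac[i, j] <- if (denom > 0) shared[ids[i], ids[j]] / denom else 0
  }
  adj <- frac >= theta_s
  cluster <- rep(0L, k)
  current <- 0L
  for (i in seq_len(k)) {
    if (cluster[i] > 0L) next
    current <- current + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (cluster[v] > 0L) next
      cluster[v] <- current
      queue <- c(queue, which(adj[v, ] & cluster == 0L))
    }
  }
  setNames(cluster, ids)
}

#' Classify each parental lineage into a QC scenario
#'
#' Scores the declared genealogy against the observed shared-variant structure.
#' For each parent with sequenced subclones the verdict is one of:
#'
#' * `consistent` — every declared subclone contains at least `theta_p` of its
#'   parent's mutations and carries at least one private mutation;
#' * `wrong_parent` — the subclones share heavily among themselves (so they are
#'   siblings from *some* lineage) but none contains `theta_p` of the declared
#'   parent: the wrong parental clone was sequenced;
#' * `mixed_parental` — single-linkage clustering of the pairwise
#'   shared-fraction (shared count over the smaller burden) at cut `theta_s`
#'   splits the declared siblings into two or more groups: the subclones derive
#'   from a mixed parental population.
#'
#' @param matrix A [shared_variant_matrix()] covering all manifest samples.
#' @param manifest A [lineage_manifest()]; parent samples must be in `matrix`.
#' @param theta_p Parent-containment threshold (default 0.9).
#' @param theta_s Sibling shared-fraction threshold (default 0.5).
#' @return A tibble with one row per parent (`parent_id`, `scenario`,
#'   `n_subclones`) carrying a `diagnostics` attribute with per-subclone
#'   parent-containment fractions, private-mutation counts, and cluster labels.
#' @export
check_lineage <- function(matrix, manifest, theta_p = 0.9, theta_s = 0.5) {
  stopifnot(inherits(matrix, "shared_variants"))
  manifest <- lineage_manifest(manifest)
  shared <- matrix$shared
  burdens <- matrix$burdens
  parents <- manifest_parents(manifest)
  missing <- setdiff(parents, matrix$sample_ids)
  if (length(missing) > 0) {
    abort(paste0("Parent sample(s) absent from shared-variant matrix: ",
                 paste(missing, collapse = ", ")))
  }
  rows <- list()
  diags <- list()
  for (p in parents) {
    subs <- manifest_children(manifest, p)
    subs <- intersect(subs, matrix$sample_ids)
    if (length(subs) == 0) next
    contain <- vapply(subs, function(s) {
      if (burdens[p] > 0) shared[p, s] / burdens[p] else 0
    }, numeric(1))
    private <- vapply(subs, function(s) burdens[s] - shared[p, s], numeric(1))
    cluster <- sibling_clusters(shared, burdens, subs, theta_s)
    scenario <- if (all(contain >= theta_p) && all(private >= 1)) {
      "consistent"
    } else if (max(cluster) >= 2) {
      "mixed_parental"
    } else {
      "wrong_parent"
    }
    rows[[p]] <- tibble(parent_id = p, scenario = scenario,
                        n_subclones = length(subs))
    diags[[p]] <- tibble(parent_id = p, sample_id = subs,
                         parent_containment = unname(contain),
                         n_private = unname(private),
                         cluster = unname(cluster))
  }
  out <- bind_rows(rows)
  attr(out, "diagnostics") <- bind_rows(diags)
  out
}

#' Check for an on-target editing scar
#'
#' Successful CRISPR-Cas9 editing leaves short indels near the gRNA-targeted
#' sequence; this check reports whether any indel record overlaps the target
#' window (1-based, closed on both ends).
#'
#' @param records Mutation records (any classes; only INS/DEL are considered).
#' @param chrom Target chromosome.
#' @param start,end 1-based closed interval bounds (window at most 10 kb).
#' @return A list with `status` (`"edited"` or `"not_edited"`) and `records`,
#'   the supporting indel records overlapping the window.
#' @export
on_target_edit_check <- function(records, chrom, start, end) {
  validate_records(records)
  if (!is.finite(start) || !is.finite(end) || start < 1 || end < start) {
    abort("Malformed target interval.")
  }
  if (end - start + 1 > 10000) abort("Target window must be at most 10 kb.")
  indels <- records[records$mclass %in% c("INS", "DEL") & records$chrom == chrom, ,
                    drop = FALSE]
  if (nrow(indels) > 0) {
    ev_end <- ifelse(indels$mclass == "DEL",
                     indels$pos + nchar(indels$ref) - 1L, indels$pos)
    hit <- indels$pos <= end & ev_end >= start
    indels <- indels[hit, , drop = FALSE]
  }
  list(status = if (nrow(indels) > 0) "edited" else "not_edited",
       records = as_tibble(indels))
}

#' Full QC battery over an experiment
#'
#' Runs the lineage scenario classification and per-subclone clonality checks
#' on a set of mutation records plus a manifest. De novo mutations for the
#' clonality check are each subclone's variants minus those of its declared
#' parent. Copy-number stability and driver-mutation screening need CNV calls
#' and annotation databases, so they are reported as not assessed.
#'
#' @param records Mutation records for all samples (with `vaf` and `depth`
#'   columns where available).
#' @param manifest A [lineage_manifest()].
#' @param ploidy,mutated_copies Ploidy model for [clonality_check()].
#' @param theta_p,theta_s Lineage thresholds, see [check_lineage()].
#' @param alpha,effect_floor Clonality rule parameters, see [clonality_check()].
#' @return A `qc_report` list: `lineage` tibble, `clonality` tibble (verdict or
#'   `"inconclusive"` per subclone), the `shared_variants` object, and `notes`.
#' @export
qc_report <- function(records, manifest, ploidy = 2, mutated_copies = 1,
                      theta_p = 0.9, theta_s = 0.5,
                      alpha = 0.001, effect_floor = 0.8) {
  validate_records(records)
  manifest <- lineage_manifest(manifest)
  keys <- split(variant_key(records), records$sample_id)
  for (id in setdiff(manifest$sample_id, names(keys))) keys[[id]] <- character()
  svm <- shared_variant_matrix(keys)
  lineage <- check_lineage(svm, manifest, theta_p = theta_p, theta_s = theta_s)

  has_vaf <- "vaf" %in% names(records)
  clon_rows <- list()
  for (s in manifest$sample_id[manifest$role == "subclone"]) {
    parent <- manifest$parent_id[manifest$sample_id == s]
    de_novo_keys <- setdiff(keys[[s]], keys[[parent]])
    rec_s <- records[records$sample_id == s, , drop = FALSE]
    rec_s <- rec_s[variant_key(rec_s) %in% de_novo_keys, , drop = FALSE]
    rep <- if (!has_vaf || sum(is.finite(rec_s$vaf)) < 20) {
      tibble(sample_id = s, expected_vaf = expected_vaf(ploidy, mutated_copies),
             observed_mean_vaf = NA_real_, n_mutations = sum(is.finite(rec_s$vaf)),
             p_value = NA_real_, verdict = "inconclusive",
             note = "Fewer than 20 de novo mutations with VAF; clonality not assessed.")
    } else {
      tidy(clonality_check(rec_s$vaf,
                           depths = if ("depth" %in% names(rec_s)) rec_s$depth,
                           ploidy = ploidy, mutated_copies = mutated_copies,
                           alpha = alpha, effect_floor = effect_floor,
                           sample_id = s))
    }
    clon_rows[[s]] <- rep
  }
  structure(
    list(lineage = lineage, clonality = bind_rows(clon_rows), shared = svm,
         notes = c("Copy-number stability: not assessed (requires CNV calling).",
                   "Driver-mutation screening: not assessed (requires annotation databases).")),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n\nLineage scenarios:\n")
  print(x$lineage)
  cat("\nClonality verdicts:\n")
  print(x$clonality[, c("sample_id", "observed_mean_vaf", "verdict")])
  cat("\n", paste(x$notes, collapse = "\n"), "\n", sep = "")
  invisible(x)
}
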