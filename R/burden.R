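# Quantitative and qualitative comparison of experimental versus control
# subclones: burden testing, profile mean/SD summaries, the signal-to-noise
# ratio, and cosine-similarity stability of extracted signatures.

#' Test for an excess mutation burden in experimental subclones
#'
#' Compares the mean mutation burden of experimental subclones against the
#' control subclones. Two machineries are provided:
#'
#' * `method = "permutation"` (default): the p-value comes from a group-label
#'   permutation test of the difference in mean burden — group labels are
#'   reshuffled `n_boot` times and the observed difference is ranked within the
#'   permuted differences. This test is calibrated at any group size. The
#'   bootstrap distribution of control means (the "expected" burden
#'   distribution of the control population) is still computed and reported in
#'   `null_quantiles`.
#' * `method = "bootstrap"`: the observed experimental mean is ranked directly
#'   within `n_boot` bootstrap means of the control burdens (resampled with
#'   replacement at the control group size). This ranks the observation against
#'   control-mean variability only and is anti-conservative when the
#'   experimental group is small; it is provided for comparability.
#'
#' Both use the add-one rank correction, so the smallest achievable p-value is
#' `1/(n_boot + 1)`. A p-value at or below `p_cutoff` (default 0.01) flags a
#' significantly different mutation burden.
#'
#' @param control_burdens,experimental_burdens Integer burdens per subclone;
#'   at least 2 controls and 1 experimental subclone.
#' @param n_boot Number of permutations / bootstrap resamples (>= 1000).
#' @param seed Integer seed; the result records it and is bit-for-bit
#'   reproducible given it.
#' @param alternative `"greater"` (excess burden, default), `"less"`, or
#'   `"two.sided"`.
#' @param method `"permutation"` or `"bootstrap"`, see above.
#' @param p_cutoff Significance cutoff (default 0.01).
#' @return A `burden_test` object; see [tidy()]/[glance()] methods.
#' @examples
#' bt <- burden_test(c(200, 210, 190, 205), c(480, 520, 501), seed = 1)
#' glance(bt)
#' @export
burden_test <- function(control_burdens, experimental_burdens,
                        n_boot = 2000, seed = 1,
                        alternative = c("greater", "less", "two.sided"),
                        method = c("permutation", "bootstrap"),
                        p_cutoff = 0.01) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(control_burdens) < 2) {
    abort("Insufficient controls: at least 2 control subclones are required.")
  }
  if (length(experimental_burdens) < 1) {
    abort("At least one experimental subclone is required.")
  }
  if (n_boot < 1000) abort("`n_boot` must be at least 1000.")
  nc <- length(control_burdens)
  ne <- length(experimental_burdens)
  obs_c <- mean(control_burdens)
  obs_e <- mean(experimental_burdens)

  res <- withr::with_seed(seed, {
    boot_means <- colMeans(matrix(sample(control_burdens, nc * n_boot, replace = TRUE),
                                  nrow = nc))
    if (method == "bootstrap") {
      exceed <- switch(alternative,
        greater = sum(boot_means >= obs_e),
        less = sum(boot_means <= obs_e),
        two.sided = 2 * min(sum(boot_means >= obs_e), sum(boot_means <= obs_e))
      )
      p <- min(1, (1 + exceed) / (n_boot + 1))
    } else {
      x <- c(control_burdens, experimental_burdens)
      total <- sum(x)
      n <- nc + ne
      obs_diff <- obs_e - obs_c
      # difference of means is a function of the permuted experimental-group sum
      perm_sum_e <- vapply(seq_len(n_boot),
                           function(b) sum(x[sample.int(n, ne)]), numeric(1))
      perm_diff <- perm_sum_e / ne - (total - perm_sum_e) / nc
      exceed <- switch(alternative,
        greater = sum(perm_diff >= obs_diff),
        less = sum(perm_diff <= obs_diff),
        two.sided = sum(abs(perm_diff) >= abs(obs_diff))
      )
      p <- min(1, (1 + exceed) / (n_boot + 1))
    }
    list(p = p, boot_means = boot_means)
  })

  structure(
    list(observed_burden = obs_e, control_mean = obs_c,
         null_quantiles = quantile(res$boot_means, c(0.005, 0.025, 0.5, 0.975, 0.995)),
         p_value = res$p, significant = res$p <= p_cutoff, p_cutoff = p_cutoff,
         alternative = alternative, method = method,
         n_control = nc, n_experimental = ne, n_boot = n_boot, seed = seed),
    class = "burden_test"
  )
}

#' @export
print.burden_test <- function(x, ...) {
  cat("<burden_test> ", x$method, ", one-sided ", x$alternative, "\n",
      sprintf("  experimental mean %.1f vs control mean %.1f (n = %d vs %d)\n",
              x$observed_burden, x$control_mean, x$n_experimental, x$n_control),
      sprintf("  p = %.4g (%ssignificant at %.2g); n_boot = %d, seed = %d\n",
              x$p_value, if (x$significant) "" else "not ", x$p_cutoff,
              x$n_boot, x$seed), sep = "")
  invisible(x)
}

#' @rdname burden_test
#' @param x A `burden_test`.
#' @param ... Unused.
#' @export
glance.burden_test <- function(x, ...) {
  tibble(observed_burden = x$observed_burden, control_mean = x$control_mean,
         p_value = x$p_value, significant = x$significant,
         alternative = x$alternative, method = x$method,
         n_control = x$n_control, n_experimental = x$n_experimental,
         n_boot = x$n_boot, seed = x$seed)
}

#' @rdname burden_test
#' @export
tidy.burden_test <- function(x, ...) glance(x)

#' Burden tests for every experimental condition of a catalog
#'
#' Runs [burden_test()] for each `experimental:<name>` condition in the
#' manifest against the control subclones, and adjusts the p-values across
#' conditions with Benjamini-Hochberg (reported alongside the raw p-values).
#'
#' @param catalog A `mut_catalog` covering the manifest's subclones.
#' @param manifest A [lineage_manifest()].
#' @inheritParams burden_test
#' @return A tibble with one row per condition: burden means, raw and
#'   BH-adjusted p-values, and the significance flag on the raw p-value.
#' @export
condition_burden_tests <- function(catalog, manifest, n_boot = 2000, seed = 1,
                                   alternative = "greater",
                                   method = "permutation", p_cutoff = 0.01) {
  manifest <- lineage_manifest(manifest)
  burdens <- sample_burdens(catalog)
  ctrl_ids <- intersect(condition_samples(manifest, "control"), burdens$sample_id)
  conds <- unique(manifest$condition[grepl("^experimental:", manifest$condition %||% "")])
  conds <- conds[!is.na(conds)]
  if (length(conds) == 0) abort("Manifest declares no experimental conditions.")
  ctrl <- burdens$burden[match(ctrl_ids, burdens$sample_id)]
  rows <- imap(setNames(conds, conds), function(cond, nm) {
    ids <- intersect(condition_samples(manifest, cond), burdens$sample_id)
    bt <- burden_test(ctrl, burdens$burden[match(ids, burdens$sample_id)],
                      n_boot = n_boot, seed = seed, alternative = alternative,
                      method = method, p_cutoff = p_cutoff)
    mutate(glance(bt), condition = sub("^experimental:", "", nm), .before = 1)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Per-channel mean and spread of normalised profiles
#'
#' Normalises each sample's catalog column to a profile (summing to one) and
#' summarises the group with a per-channel mean and standard deviation. The SD
#' is the population SD by default (divide by n), reading the group spread as a
#' descriptive "variability of mutation profiles among subclones"; set
#' `sd_type = "sample"` for the n-1 estimator.
#'
#' @param catalog A `mut_catalog`.
#' @param sample_ids Samples forming the group (default: all catalog samples).
#'   Every sample must have at least one mutation.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A `profile_stats` object with fields `mu`, `sigma`, `n_samples`.
#' @export
profile_stats <- function(catalog, sample_ids = NULL,
                          sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  profiles <- catalog_profiles(catalog, sample_ids)
  mu <- rowMeans(profiles)
  n <- ncol(profiles)
  centred <- profiles - mu
  sigma <- if (n == 1) {
    rep(0, nrow(profiles))
  } else if (sd_type == "population") {
    sqrt(rowSums(centred^2) / n)
  } else {
    sqrt(rowSums(centred^2) / (n - 1))
  }
  structure(list(mu = mu, sigma = setNames(sigma, names(mu)), n_samples = n,
                 labels = rownames(profiles), sd_type = sd_type,
                 scheme = catalog_scheme(catalog)$name),
            class = "profile_stats")
}

#' @export
print.profile_stats <- function(x, ...) {
  cat("<profile_stats> ", x$n_samples, " sample(s) on ", x$scheme,
      "; total sigma ", format(sqrt(sum(x$sigma^2)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.profile_stats <- function(x, ...) {
  tibble(channel = x$labels, mu = unname(x$mu), sigma = unname(x$sigma))
}

#' Signal-to-noise ratio between control and experimental profiles
#'
#' The signal is the Euclidean distance between the group mean profiles; the
#' noise is the within-group profile variability. By default the per-channel
#' SDs of the two groups are combined in quadrature (treating the group noises
#' as independent): `noise = sqrt(||sigma_C||^2 + ||sigma_E||^2)`. A large SNR
#' means the experimental spectra separate from the controls well beyond
#' replicate noise, so the experiment-associated signature can be extracted
#' with confidence. Zero noise with a non-zero signal is flagged infinite;
#' 0/0 is defined as 0.
#'
#' @param control,experimental [profile_stats()] objects on the same scheme
#'   and channel order.
#' @param noise_method `"quadrature"` (default) or `"mean_sd"` (the mean of all
#'   per-channel SDs across both groups — an alternative reading of the noise
#'   denominator).
#' @return An `snr_result` with fields `signal`, `noise`, `snr`, `infinite`.
#' @export
snr <- function(control, experimental, noise_method = c("quadrature", "mean_sd")) {
  noise_method <- match.arg(noise_method)
  stopifnot(inherits(control, "profile_stats"), inherits(experimental, "profile_stats"))
  if (!identical(control$labels, experimental$labels)) {
    abort("Profile stats are on different schemes or channel orders.")
  }
  signal <- sqrt(sum((experimental$mu - control$mu)^2))
  noise <- switch(noise_method,
    quadrature = sqrt(sum(control$sigma^2) + sum(experimental$sigma^2)),
    mean_sd = mean(c(control$sigma, experimental$sigma))
  )
  infinite <- noise == 0 && signal > 0
  value <- if (infinite) Inf else if (noise == 0) 0 else signal / noise
  structure(list(signal = signal, noise = noise, snr = value,
                 infinite = infinite, noise_method = noise_method),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("<snr_result> signal %.4g / noise %.4g = SNR %s (%s)\n",
              x$signal, x$noise,
              if (x$infinite) "Inf (degenerate: zero noise)" else format(x$snr, digits = 4),
              x$noise_method))
  invisible(x)
}

#' @export
tidy.snr_result <- function(x, ...) {
  tibble(signal = x$signal, noise = x$noise, snr = x$snr, infinite = x$infinite,
         noise_method = x$noise_method)
}

#' Cosine similarity between two profiles
#'
#' The normalised dot product `dot(p, q) / (||p|| ||q||)`. For non-negative
#' profiles the value lies in `[0, 1]`; it is invariant to positive rescaling
#' of either argument. Note it is most informative for peaked signatures and is
#' not a linear scale.
#'
#' @param p,q Signature profiles or plain non-negative numeric vectors of the
#'   same length; each must have at least one non-zero entry.
#' @return A number in `[0, 1]`.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 1))  # 0.5
#' @export
cosine_similarity <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) abort("Profiles must have the same length/scheme.")
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) abort("Cosine similarity is undefined for a zero vector.")
  min(1, max(sum(p * q) / (np * nq), -1))
}

#' Stability of signatures extracted from replicate subclones
#'
#' Signatures extracted from subclones of the same parental clone should agree;
#' the report computes all pairwise cosine similarities and flags the set as
#' stable when the minimum exceeds the threshold (default 0.9).
#'
#' @param signatures A list of at least two signature profiles (or numeric
#'   vectors) on a common scheme.
#' @param threshold Stability cutoff on the minimum pairwise cosine.
#' @return A `stability_report` with the pairwise cosine matrix, `min_cosine`,
#'   `mean_cosine`, and the `stable` flag.
#' @export
stability_report <- function(signatures, threshold = 0.9) {
  if (length(signatures) < 2) {
    abort("Insufficient replicates: at least two signatures are required.")
  }
  k <- length(signatures)
  ids <- names(signatures) %||% paste0("sig", seq_len(k))
  m <- matrix(1, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- cosine_similarity(signatures[[i]], signatures[[j]])
  }
  off <- m[lower.tri(m)]
  structure(list(cosine = m, min_cosine = min(off), mean_cosine = mean(off),
                 threshold = threshold, stable = min(off) > threshold),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d signatures; min cosine %.3f, mean %.3f -> %s (threshold %.2f)\n",
              nrow(x$cosine), x$min_cosine, x$mean_cosine,
              if (x$stable) "stable" else "NOT stable", x$threshold))
  invisible(x)
}

#' @export
tidy.stability_report <- function(x, ...) {
  as_tibble(as.data.frame.table(x$cosine, responseName = "cosine",
                                stringsAsFactors = FALSE)) |>
    rename(sig_a = "Var1", sig_b = "Var2") |>
    filter(.data$sig_a != .data$sig_b)
}

#' @export
glance.stability_report <- function(x, ...) {
  tibble(min_cosine = x$min_cosine, mean_cosine = x$mean_cosine,
         threshold = x$threshold, stable = x$stable)
}
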