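# Background-signature subtraction: bootstrap per-channel confidence intervals
# around the experimental centroid, a closed-form maximal background scale, and
# clamping of within-CI negative residuals.

#' Bootstrap the per-channel count distribution of a sample
#'
#' Redraws the sample's N mutations `n_boot` times from the multinomial with
#' probabilities equal to the observed profile, giving a per-channel
#' distribution of mutation numbers from which a central confidence interval is
#' read off (99% by default: the 0.5 and 99.5 percentiles).
#'
#' @param counts Non-negative integer counts per channel (total >= 1); names
#'   are preserved.
#' @param n_boot Number of bootstrap replicates (>= 1000).
#' @param seed Integer seed; identical seeds give identical CI bounds.
#' @param level CI coverage (default 0.99).
#' @return A list with `mean`, `lower`, `upper` per channel and the replicate
#'   matrix `draws` (channels x n_boot).
#' @export
bootstrap_channel_distribution <- function(counts, n_boot = 1000, seed = 1,
                                           level = 0.99) {
  counts <- setNames(as.numeric(counts), names(counts))
  total <- sum(counts)
  if (total < 1) abort("Empty sample: total count must be >= 1.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (n_boot < 1000) abort("`n_boot` must be at least 1000.")
  draws <- withr::with_seed(seed, rmultinom(n_boot, total, counts / total))
  rownames(draws) <- names(counts)
  a <- (1 - level) / 2
  list(
    mean = rowMeans(draws),
    lower = apply(draws, 1, quantile, probs = a),
    upper = apply(draws, 1, quantile, probs = 1 - a),
    draws = draws, level = level, n_boot = n_boot, seed = seed
  )
}

#' Fit the background (intrinsic) mutagenesis model from controls
#'
#' The averaged mutation burden and profile of the control subclones represent
#' the background mutagenesis of the cellular system: the model profile is the
#' mean of the normalised control profiles (so controls with unequal burdens
#' contribute equally) and the model burden is the mean control burden.
#'
#' @param control_catalog A `mut_catalog` of control subclones (>= 2 samples,
#'   each with at least one mutation).
#' @param sample_ids Optional subset of catalog samples to use as controls.
#' @return A `background_model` with fields `profile` (a
#'   [signature_profile()]) and `burden`.
#' @export
fit_background <- function(control_catalog, sample_ids = NULL) {
  m <- catalog_matrix(control_catalog)
  if (!is.null(sample_ids)) m <- m[, sample_ids, drop = FALSE]
  if (ncol(m) < 2) {
    abort("Missing controls: at least 2 control subclones are required.")
  }
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0("Zero-burden control(s): ",
                 paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  profiles <- sweep(m, 2, totals, "/")
  structure(
    list(profile = signature_profile(rowMeans(profiles),
                                     catalog_scheme(control_catalog)),
         burden = mean(totals), n_controls = ncol(m),
         scheme = catalog_scheme(control_catalog)$name),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat("<background_model> burden ", format(x$burden), " over ", x$n_controls,
      " controls on ", x$scheme, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.background_model <- function(x, ...) tidy(x$profile)

#' Subtract the background signature from experimental profiles
#'
#' Extracts the experiment-associated signature by removing the background
#' (control-derived) contribution from the centroid of the experimental
#' subclone profiles:
#'
#' 1. The centroid expected counts are the mean experimental burden times the
#'    centroid (mean normalised) profile.
#' 2. Each subclone is bootstrapped (multinomial redraws of its own counts);
#'    per replicate the subclone redraws are averaged into a replicate
#'    centroid, whose per-channel central CI (99% by default) is reported as
#'    the distribution of mutation numbers for each channel. The background is
#'    bootstrapped alongside (multinomial redraws at the background burden),
#'    and the per-channel tolerance `w_c` — how far below its expectation the
#'    residual can fall by resampling noise alone — is the bootstrap mean
#'    minus the lower CI bound of the replicate residuals (centroid minus
#'    bootstrapped background).
#' 3. The background counts (`background burden x background profile`) are
#'    scaled by the largest factor `alpha* <= 1` that leaves every channel's
#'    residual above `-w_c` — the closed-form realisation of "reduce the
#'    initial background mutation burden" when straight subtraction would push
#'    channels below what resampling noise explains.
#' 4. Residuals that are still negative at `alpha*` lie within CI noise and are
#'    set to zero (and recorded); the clamped residuals, normalised, are the
#'    extracted signature, and their sum is the attributed burden.
#'
#' @param experimental_catalog A `mut_catalog` of experimental subclones
#'   (>= 1 sample) on the same scheme as the background.
#' @param background A [fit_background()] model. A zero-burden background
#'   leaves the centroid untouched.
#' @param n_boot Bootstrap replicates (>= 1000).
#' @param seed Integer seed (results reproducible given `seed` and `n_boot`).
#' @param level CI coverage (default 0.99).
#' @param sample_ids Optional subset of catalog samples.
#' @return A `subtraction_result` with the extracted `signature`, the
#'   `attributed_burden`, per-channel CIs, the zeroed channels, and the
#'   background scale `alpha`.
#' @export
subtract_background <- function(experimental_catalog, background,
                                n_boot = 1000, seed = 1, level = 0.99,
                                sample_ids = NULL) {
  stopifnot(inherits(background, "background_model"))
  scheme <- catalog_scheme(experimental_catalog)
  if (!identical(scheme$name, background$scheme)) {
    abort("Experimental catalog and background model are on different schemes.")
  }
  if (n_boot < 1000) abort("`n_boot` must be at least 1000.")
  m <- catalog_matrix(experimental_catalog)
  if (!is.null(sample_ids)) m <- m[, sample_ids, drop = FALSE]
  if (ncol(m) < 1) abort("At least one experimental subclone is required.")
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0("Zero-burden experimental sample(s): ",
                 paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  profiles <- sweep(m, 2, totals, "/")
  centroid_profile <- rowMeans(profiles)
  mean_burden <- mean(totals)
  centroid <- mean_burden * centroid_profile

  beta <- as.numeric(background$profile)
  B <- background$burden

  # replicate centroids: bootstrap each subclone, average normalised redraws;
  # the background is bootstrapped alongside (multinomial at its burden)
  boot <- withr::with_seed(seed, {
    acc <- matrix(0, nrow(m), n_boot)
    for (s in seq_len(ncol(m))) {
      draws <- rmultinom(n_boot, totals[s], profiles[, s])
      acc <- acc + draws / totals[s]
    }
    centroids <- mean_burden * acc / ncol(m)
    bg_draws <- if (B > 0 && sum(beta) > 0) {
      rmultinom(n_boot, round(B), beta)
    } else {
      matrix(0, nrow(m), n_boot)
    }
    list(centroids = centroids, bg = bg_draws)
  })
  a <- (1 - level) / 2
  lower <- apply(boot$centroids, 1, quantile, probs = a)
  upper <- apply(boot$centroids, 1, quantile, probs = 1 - a)
  # per-channel tolerance for negative residuals: how far below its expectation
  # the residual (centroid minus bootstrapped background) can fall by
  # resampling noise alone
  resid_boot <- boot$centroids - boot$bg
  w <- rowMeans(resid_boot) - apply(resid_boot, 1, quantile, probs = a)

  if (B > 0) {
    active <- beta > 0
    alpha <- min(1, min((centroid[active] + w[active]) / (B * beta[active])))
  } else {
    alpha <- 1
  }
  if (alpha <= 1e-6) {
    abort(paste0("Degenerate subtraction: the background burden saturates the ",
                 "experimental centroid (alpha* = 0); the signal is ",
                 "indistinguishable from background."))
  }
  residual <- centroid - alpha * B * beta
  zeroed <- names(centroid)[residual < 0]
  clamped <- pmax(residual, 0)
  attributed <- sum(clamped)
  sig <- signature_profile(clamped, scheme,
                           normalize = attributed > 0)

  structure(
    list(signature = sig, attributed_burden = attributed,
         background_scale = alpha, zeroed_channels = zeroed,
         centroid = centroid, residual = residual,
         channel_tolerance = setNames(w, names(centroid)),
         channel_ci = tibble(channel = names(centroid),
                             lower = unname(lower), upper = unname(upper)),
         mean_experimental_burden = mean_burden,
         background_burden = B, level = level,
         n_subclones = ncol(m), n_boot = n_boot, seed = seed),
    class = "subtraction_result"
  )
}

#' @export
print.subtraction_result <- function(x, ...) {
  cat("<subtraction_result>\n",
      sprintf("  attributed burden %.1f of mean experimental burden %.1f\n",
              x$attributed_burden, x$mean_experimental_burden),
      sprintf("  background scale alpha* = %.3f (background burden %.1f)\n",
              x$background_scale, x$background_burden),
      sprintf("  %d channel(s) zeroed within the %.0f%% CI; n_boot = %d, seed = %d\n",
              length(x$zeroed_channels), 100 * x$level, x$n_boot, x$seed),
      sep = "")
  invisible(x)
}

#' @rdname subtract_background
#' @param x A `subtraction_result`.
#' @param ... Unused.
#' @export
tidy.subtraction_result <- function(x, ...) {
  tibble(channel = names(x$centroid),
         centroid = unname(x$centroid),
         residual = unname(x$residual),
         weight = as.numeric(x$signature),
         ci_lower = x$channel_ci$lower,
         ci_upper = x$channel_ci$upper,
         zeroed = names(x$centroid) %in% x$zeroed_channels)
}

#' @rdname subtract_background
#' @export
glance.subtraction_result <- function(x, ...) {
  tibble(attributed_burden = x$attributed_burden,
         mean_experimental_burden = x$mean_experimental_burden,
         background_burden = x$background_burden,
         background_scale = x$background_scale,
         n_zeroed = length(x$zeroed_channels),
         ci_level = x$level, n_subclones = x$n_subclones,
         n_boot = x$n_boot, seed = x$seed)
}

#' Per-subclone signature extraction for stability assessment
#'
#' Applies [subtract_background()] to each experimental subclone separately and
#' returns the list of extracted signatures, ready for [stability_report()].
#'
#' @inheritParams subtract_background
#' @return A named list of [signature_profile()]s, one per subclone.
#' @export
per_subclone_signatures <- function(experimental_catalog, background,
                                    n_boot = 1000, seed = 1, level = 0.99,
                                    sample_ids = NULL) {
  m <- catalog_matrix(experimental_catalog)
  ids <- sample_ids %||% colnames(m)
  sigs <- lapply(seq_along(ids), function(i) {
    subtract_background(experimental_catalog, background, n_boot = n_boot,
                        seed = seed + i - 1L, level = level,
                        sample_ids = ids[i])$signature
  })
  setNames(sigs, ids)
}
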