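# Shared fixtures built in code: a small seeded reference (reused across test
# files) and a catalog constructor for count matrices produced directly by
# multinomial draws (bypassing placement when only the counts matter).

test_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- make_reference(50000, seed = 424242)
    ref
  }
})

catalog_from_counts <- function(counts, scheme = sbs96_scheme()) {
  if (is.null(rownames(counts))) rownames(counts) <- scheme$labels
  mutsigexp:::new_mut_catalog(counts, scheme)
}

background_model_from <- function(profile, burden, n_controls = 4) {
  structure(list(profile = profile, burden = burden, n_controls = n_controls,
                 scheme = attr(profile, "scheme")),
            class = "background_model")
}

# multinomial catalog of `n` samples at fixed burden(s) from signature(s)
draw_counts <- function(signatures, burdens, n, seed, prefix = "s") {
  withr::with_seed(seed, {
    m <- sapply(seq_len(n), function(i) {
      total <- numeric(length(signatures[[1]]))
      for (k in seq_along(signatures)) {
        total <- total + rmultinom(1, burdens[k], as.numeric(signatures[[k]]))
      }
      total
    })
    colnames(m) <- paste0(prefix, seq_len(n))
    m
  })
}
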