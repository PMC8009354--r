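# shared builders for synthetic test spectra and a cached copy of the
# default full-size dataset (used by several files; generated once)

flat_spectrum <- function(value = 0.4, range = c(820, 1700)) {
  spectrum(seq.int(range[1], range[2]), rep(value, diff(range) + 1))
}

# analytic spectrum: linear continuum times (1 - sum of Gaussian dips);
# returns both the sampled spectrum and the continuous function
analytic_spectrum <- function(range = c(850, 1700), c0 = 0.45,
                              slope = 0, dips = list()) {
  fun <- function(wl) {
    absorb <- rep(0, length(wl))
    for (d in dips) {
      absorb <- absorb + d$depth * exp(-(wl - d$centre)^2 / (2 * d$sigma^2))
    }
    (c0 + slope * (wl - range[1])) * (1 - absorb)
  }
  grid <- seq.int(range[1], range[2])
  list(spectrum = spectrum(grid, fun(grid)), fun = fun)
}

.test_cache <- new.env(parent = emptyenv())

# default-condition dataset (292 leaves, 3 species, jitter 5 nm,
# noise 0.002) with its index table and a fixed fold plan
full_study <- function() {
  if (is.null(.test_cache$study)) {
    ds <- generate_dataset()
    tab <- suppressMessages(
      build_index_table(join_samples(ds$spectra, ds$metadata)))
    .test_cache$study <- list(
      ds = ds, tab = tab,
      folds = make_folds(nrow(tab), k = 10, seed = 42))
  }
  .test_cache$study
}
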