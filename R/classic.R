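#' Names of the ten classical fixed-band water indices
#' @return character vector in canonical column order.
#' @export
classic_index_names <- function() {
  c("WI", "SRWI", "NDWI_1240", "RDI", "RATIO_975", "RATIO_1200",
    "DWI", "MSI", "NDII", "GVMI")
}

#' Compute the ten classical fixed-band water indices
#'
#' All indices use the same predefined wavelengths for every leaf:
#' \describe{
#'   \item{WI}{rho900 / rho970 (Water Index)}
#'   \item{SRWI}{rho858 / rho1240 (Simple Ratio Water Index)}
#'   \item{NDWI_1240}{(rho860 - rho1240) / (rho860 + rho1240)}
#'   \item{RDI}{(rho1116 - min rho over \[1120, 1150\]) / rho1116
#'     (Relative Depth Index)}
#'   \item{RATIO_975}{2 * mean rho\[960, 990\] /
#'     (mean rho\[920, 940\] + mean rho\[1090, 1100\])}
#'   \item{RATIO_1200}{2 * mean rho\[1180, 1220\] /
#'     (mean rho\[1090, 1110\] + mean rho\[1265, 1285\])}
#'   \item{DWI}{(y1 - rho970) + (y2 - rho1200), with y_i the straight line
#'     through (850, rho850) and (1080, rho1080) evaluated at 970 and
#'     1200 nm (Depth Water Index)}
#'   \item{MSI}{rho1600 / rho820 (Moisture Stress Index)}
#'   \item{NDII}{(rho860 - rho1600) / (rho860 + rho1600)}
#'   \item{GVMI}{((rho820 + 0.1) - (rho1600 + 0.02)) /
#'     ((rho820 + 0.1) + (rho1600 + 0.02))}
#' }
#' Band means are unweighted arithmetic means over integer wavelengths,
#' range-inclusive. The RDI minimum is taken over 1120-1150 nm. An index
#' whose bands the spectrum does not cover is returned as `NA`.
#'
#' @param s a `leaf_spectrum` on a 1-nm grid; full coverage of
#'   820-1600 nm yields all ten indices.
#' @return named numeric vector of the ten index values.
#' @export
compute_classic_indices <- function(s) {
  stopifnot(inherits(s, "leaf_spectrum"))
  r <- function(wl) reflectance_at(s, wl)
  val <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  out <- c(
    WI        = val(r(900) / r(970)),
    SRWI      = val(r(858) / r(1240)),
    NDWI_1240 = val((r(860) - r(1240)) / (r(860) + r(1240))),
    RDI       = val({
      keep <- s$wavelength >= 1120 & s$wavelength <= 1150
      if (!any(keep)) stop("band missing")
      (r(1116) - min(s$reflectance[keep])) / r(1116)
    }),
    RATIO_975  = val(2 * band_mean(s, 960, 990) /
                       (band_mean(s, 920, 940) + band_mean(s, 1090, 1100))),
    RATIO_1200 = val(2 * band_mean(s, 1180, 1220) /
                       (band_mean(s, 1090, 1110) + band_mean(s, 1265, 1285))),
    DWI       = val({
      line <- continuum_line(r(850), r(1080))
      (line(970) - r(970)) + (line(1200) - r(1200))
    }),
    MSI       = val(r(1600) / r(820)),
    NDII      = val((r(860) - r(1600)) / (r(860) + r(1600))),
    GVMI      = val(((r(820) + 0.1) - (r(1600) + 0.02)) /
                      ((r(820) + 0.1) + (r(1600) + 0.02)))
  )
  out[classic_index_names()]
}

# Straight line through (850, rho850) and (1080, rho1080); the DWI's
# non-absorption continuum over the NIR plateau.
continuum_line <- function(rho850, rho1080) {
  slope <- (rho1080 - rho850) / 230
  intercept <- rho850 - slope * 850
  function(x) slope * x + intercept
}

#' Build the per-leaf index table
#'
#' One row per sample with the three SAIs, the ten classical indices, and
#' the gravimetric targets (EWT in g cm^-2, FMC as a fraction). Indices a
#' spectrum cannot support are `NA`; per-index missing counts are reported
#' via `message()`.
#'
#' @param samples a `leaf_samples` object from [join_samples()], or a
#'   `spectrum_set` plus `metadata`.
#' @param metadata optional metadata data.frame when `samples` is a
#'   `spectrum_set`.
#' @param windows SAI windows, default [default_windows()].
#' @param smooth logical, passed to [locate_feature()].
#' @return data.frame: sample_id, species, SAI_970, SAI_1200, SAI_1660,
#'   the ten classical indices, ewt, fmc.
#' @export
build_index_table <- function(samples, metadata = NULL,
                              windows = default_windows(), smooth = TRUE) {
  if (inherits(samples, "spectrum_set")) {
    if (is.null(metadata)) stop("metadata required with a spectrum_set",
                                call. = FALSE)
    samples <- join_samples(samples, metadata)
  }
  stopifnot(inherits(samples, "leaf_samples"))
  set <- samples$spectra
  ids <- sample_ids(set)
  sai_names <- names(windows)
  cols <- c(sai_names, classic_index_names())
  if (length(ids) == 0L) {
    out <- samples$meta[c("sample_id", "species")]
    for (cn in cols) out[[cn]] <- numeric(0)
    out$ewt <- numeric(0); out$fmc <- numeric(0)
    return(out)
  }
  vals <- t(vapply(ids, function(id) {
    s <- get_spectrum(set, id)
    sais <- tryCatch(compute_sai_family(s, windows, smooth = smooth),
                     error = function(e) {
                       v <- rep(NA_real_, length(windows))
                       names(v) <- sai_names
                       v
                     })
    c(as.numeric(sais)[match(sai_names, names(sais))],
      compute_classic_indices(s))
  }, numeric(length(cols))))
  colnames(vals) <- cols
  n_missing <- colSums(is.na(vals))
  if (any(n_missing > 0L)) {
    bad <- n_missing[n_missing > 0L]
    message("missing index values: ",
            paste(names(bad), bad, sep = "=", collapse = ", "))
  }
  data.frame(sample_id = ids, species = samples$meta$species,
             vals, ewt = samples$meta$ewt, fmc = samples$meta$fmc,
             row.names = NULL, check.names = FALSE)
}
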