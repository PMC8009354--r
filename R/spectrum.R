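#' Construct a single leaf reflectance spectrum
#'
#' A spectrum is a pair of parallel vectors: strictly increasing wavelengths
#' in nanometres and dimensionless reflectance values. Reflectance is
#' expected in \[0, 1\]; values outside \[-0.05, 1.2\] are rejected, values
#' outside \[0, 1\] but within the rejection bounds are kept with a warning
#' (sensor noise near zero and specular spikes both occur in field data).
#' Percent-style input (maximum > 1.5) is auto-detected and divided by 100.
#'
#' @param wavelength numeric vector of wavelengths (nm), strictly increasing.
#' @param reflectance numeric vector of reflectance values, same length.
#' @param sample_id optional sample identifier carried for error messages.
#' @return An object of class `leaf_spectrum`: a list with elements
#'   `wavelength` and `reflectance`.
#' @examples
#' s <- spectrum(350:2500, rep(0.4, 2151))
#' range(s$wavelength)
#' @export
spectrum <- function(wavelength, reflectance, sample_id = NULL) {
  wavelength <- as.numeric(wavelength)
  reflectance <- as.numeric(reflectance)
  who <- if (is.null(sample_id)) "spectrum" else paste0("sample '", sample_id, "'")
  if (length(wavelength) != length(reflectance)) {
    stop(who, ": wavelength and reflectance lengths differ (",
         length(wavelength), " vs ", length(reflectance), ")", call. = FALSE)
  }
  if (length(wavelength) < 1L) stop(who, ": empty spectrum", call. = FALSE)
  if (anyNA(wavelength) || any(!is.finite(wavelength))) {
    stop(who, ": non-finite wavelengths", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop(who, ": wavelengths must be strictly increasing", call. = FALSE)
  }
  if (anyNA(reflectance) || any(!is.finite(reflectance))) {
    stop(who, ": non-finite reflectance values", call. = FALSE)
  }
  if (max(reflectance) > 1.5) {
    warning(who, ": reflectance looks percent-scaled (max ",
            format(max(reflectance)), "); dividing by 100", call. = FALSE)
    reflectance <- reflectance / 100
  }
  if (any(reflectance < -0.05 | reflectance > 1.2)) {
    stop(who, ": reflectance outside [-0.05, 1.2]", call. = FALSE)
  }
  if (any(reflectance < 0 | reflectance > 1)) {
    warning(who, ": reflectance outside [0, 1] retained", call. = FALSE)
  }
  structure(list(wavelength = wavelength, reflectance = reflectance,
                 sample_id = sample_id),
            class = "leaf_spectrum")
}

#' @export
print.leaf_spectrum <- function(x, ...) {
  cat("<leaf_spectrum> ", length(x$wavelength), " bands, ",
      min(x$wavelength), "-", max(x$wavelength), " nm, reflectance ",
      sprintf("%.3f-%.3f", min(x$reflectance), max(x$reflectance)), "\n",
      sep = "")
  invisible(x)
}

#' Reflectance at given wavelengths
#'
#' Exact lookup on the spectrum's grid; wavelengths not on the grid are an
#' error (resample first).
#'
#' @param s a `leaf_spectrum`.
#' @param wl numeric vector of wavelengths (nm).
#' @return numeric vector of reflectance values.
#' @export
reflectance_at <- function(s, wl) {
  idx <- match(wl, s$wavelength)
  if (anyNA(idx)) {
    stop("wavelength(s) not on spectrum grid: ",
         paste(wl[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  s$reflectance[idx]
}

#' Mean reflectance over an inclusive wavelength band
#'
#' Unweighted arithmetic mean over all grid wavelengths in \[lo, hi\]
#' (both ends included).
#'
#' @param s a `leaf_spectrum`.
#' @param lo,hi band limits (nm), inclusive.
#' @return scalar mean reflectance.
#' @export
band_mean <- function(s, lo, hi) {
  keep <- s$wavelength >= lo & s$wavelength <= hi
  if (!any(keep)) stop("band [", lo, ", ", hi, "] not covered", call. = FALSE)
  mean(s$reflectance[keep])
}

#' Resample a spectrum to a 1-nm integer grid
#'
#' Linear interpolation onto integer nanometre wavelengths spanning the
#' input range; no extrapolation. A spectrum already on a 1-nm integer grid
#' is returned unchanged. Interior gaps wider than `max_gap` nm are an
#' error rather than silently bridged.
#'
#' @param s a `leaf_spectrum`.
#' @param max_gap widest interior wavelength gap (nm) that linear
#'   interpolation is allowed to fill. Default 5.
#' @return a `leaf_spectrum` on an integer 1-nm grid.
#' @export
resample_to_1nm <- function(s, max_gap = 5) {
  stopifnot(inherits(s, "leaf_spectrum"))
  if (length(s$wavelength) < 2L) {
    stop("need at least 2 wavelengths to resample", call. = FALSE)
  }
  wl <- s$wavelength
  if (all(wl == round(wl)) && all(diff(wl) == 1)) return(s)
  gaps <- diff(wl)
  if (any(gaps > max_gap)) {
    bad <- which(gaps > max_gap)[1L]
    stop("gap of ", gaps[bad], " nm between ", wl[bad], " and ", wl[bad + 1L],
         " exceeds max_gap = ", max_gap,
         if (!is.null(s$sample_id)) paste0(" (sample '", s$sample_id, "')") else "",
         call. = FALSE)
  }
  grid <- seq.int(ceiling(min(wl)), floor(max(wl)))
  refl <- stats::approx(wl, s$reflectance, xout = grid, method = "linear")$y
  spectrum(grid, refl, sample_id = s$sample_id)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate readings of the same leaf (the
#' usual protocol takes several readings per leaf and uses their mean).
#' All replicates must share the same wavelength grid.
#'
#' @param replicates list of `leaf_spectrum` objects on one grid.
#' @return a single `leaf_spectrum`.
#' @export
average_replicates <- function(replicates) {
  if (inherits(replicates, "leaf_spectrum")) replicates <- list(replicates)
  if (length(replicates) < 1L) stop("need at least one replicate", call. = FALSE)
  stopifnot(all(vapply(replicates, inherits, logical(1), "leaf_spectrum")))
  wl <- replicates[[1L]]$wavelength
  for (r in replicates[-1L]) {
    if (length(r$wavelength) != length(wl) || any(r$wavelength != wl)) {
      stop("replicate wavelength grids differ", call. = FALSE)
    }
  }
  m <- vapply(replicates, `[[`, numeric(length(wl)), "reflectance")
  spectrum(wl, rowMeans(as.matrix(m)), sample_id = replicates[[1L]]$sample_id)
}

#' Construct a set of spectra on a shared grid
#'
#' @param spectra named list of `leaf_spectrum` objects, all on the same
#'   wavelength grid; names are the sample ids (unique).
#' @return An object of class `spectrum_set`: list with `grid` (shared
#'   wavelengths) and `reflectance` (samples x wavelengths matrix with
#'   sample-id rownames).
#' @export
spectrum_set <- function(spectra) {
  stopifnot(length(spectra) >= 1L, !is.null(names(spectra)))
  if (anyDuplicated(names(spectra))) {
    stop("duplicate sample ids: ",
         paste(unique(names(spectra)[duplicated(names(spectra))]), collapse = ", "),
         call. = FALSE)
  }
  grid <- spectra[[1L]]$wavelength
  for (i in seq_along(spectra)) {
    wl <- spectra[[i]]$wavelength
    if (length(wl) != length(grid) || any(wl != grid)) {
      stop("sample '", names(spectra)[i], "' is not on the shared grid",
           call. = FALSE)
    }
  }
  R <- t(vapply(spectra, `[[`, numeric(length(grid)), "reflectance"))
  rownames(R) <- names(spectra)
  structure(list(grid = grid, reflectance = R), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$reflectance), " samples x ",
      length(x$grid), " bands (", min(x$grid), "-", max(x$grid), " nm)\n",
      sep = "")
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) nrow(x$reflectance)

#' Extract one sample's spectrum from a set
#'
#' @param set a `spectrum_set`.
#' @param sample_id sample identifier (rowname).
#' @return a `leaf_spectrum`.
#' @export
get_spectrum <- function(set, sample_id) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!sample_id %in% rownames(set$reflectance)) {
    stop("unknown sample_id '", sample_id, "'", call. = FALSE)
  }
  spectrum(set$grid, set$reflectance[sample_id, ], sample_id = sample_id)
}

#' Sample identifiers of a spectrum set
#' @param set a `spectrum_set`.
#' @return character vector of sample ids in row order.
#' @export
sample_ids <- function(set) rownames(set$reflectance)
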