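#' Define an absorption window with shoulder search ranges
#'
#' An absorption window is a named wavelength interval \[a, b\] holding one
#' absorption feature, with two sub-intervals at its edges in which the
#' left and right shoulders (local reflectance maxima flanking the dip)
#' are searched. All intervals are inclusive integer nm.
#'
#' @param name index name, e.g. `"SAI_1200"`.
#' @param window length-2 numeric, the full window \[a, b\].
#' @param left_search length-2 numeric inside `window` for the left shoulder.
#' @param right_search length-2 numeric inside `window` for the right shoulder.
#' @return list of class `absorption_window`.
#' @export
absorption_window <- function(name, window, left_search, right_search) {
  stopifnot(length(window) == 2L, length(left_search) == 2L,
            length(right_search) == 2L)
  if (!(window[1] <= left_search[1] && left_search[2] < right_search[1] &&
        right_search[2] <= window[2])) {
    stop("shoulder search ranges must be ordered inside the window",
         call. = FALSE)
  }
  structure(list(name = name, window = window,
                 left_search = left_search, right_search = right_search),
            class = "absorption_window")
}

#' Default absorption windows for the three SAIs
#'
#' The water absorption features near 970 nm (window 915-1085 nm) and
#' 1200 nm (1085-1265 nm), and the dry-matter (lignin/cellulose) feature
#' near 1660 nm (1630-1690 nm). Shoulders of these leaf features sit at
#' the window edges, so the search sub-ranges take roughly the outer
#' quarter of each window on each side; all ranges are configurable.
#'
#' @return named list of three [absorption_window()] objects.
#' @export
default_windows <- function() {
  list(
    SAI_970  = absorption_window("SAI_970",  c(915, 1085),
                                 c(915, 940),  c(1060, 1085)),
    SAI_1200 = absorption_window("SAI_1200", c(1085, 1265),
                                 c(1085, 1110), c(1240, 1265)),
    SAI_1660 = absorption_window("SAI_1660", c(1630, 1690),
                                 c(1630, 1645), c(1675, 1690))
  )
}

# Savitzky-Golay smoothing used only to LOCATE extrema; reflectance values
# are always read from the raw spectrum at the located wavelengths.
smooth_for_location <- function(refl, n = 15L, p = 2L) {
  if (length(refl) < n) return(refl)
  as.numeric(signal::sgolayfilt(refl, p = p, n = n))
}

#' Locate the absorption peak and shoulders of one feature
#'
#' The left shoulder is the reflectance maximum over the window's left
#' search range, the right shoulder the maximum over the right search
#' range, and the peak the reflectance minimum strictly between the two
#' shoulders. Ties resolve to the smallest wavelength. With `smooth = TRUE`
#' (default) a local quadratic (Savitzky-Golay, 15-nm window) smoothed
#' copy of the spectrum is used both to locate the extrema and to read
#' the reflectances at the located wavelengths: the local quadratic is
#' the natural low-order estimate of the true reflectance at a point,
#' and reading raw single channels would inject the full per-channel
#' measurement noise into a ratio of three point reads. `smooth = FALSE`
#' disables smoothing entirely (raw locations and raw values).
#'
#' A window with no interior dip -- the "minimum" sits right next to a
#' shoulder on a monotone slope -- is marked invalid. An exactly constant
#' window is the no-absorption case: ties resolve to the range edges, the
#' feature stays valid and its SAI evaluates to exactly 1.
#'
#' @param s a `leaf_spectrum` on a 1-nm grid covering the window.
#' @param w an [absorption_window()].
#' @param smooth logical; smooth before locating extrema (default TRUE).
#' @return list of class `absorption_feature` with elements `name`,
#'   `lambda1`, `lambda2`, `lambda_m` (nm), `rho1`, `rho2`, `rho_m`
#'   (raw reflectance), `valid`, `reason`, and `d`, `baseline_at_peak`,
#'   `sai` still `NA` (filled by [compute_sai()]).
#' @export
locate_feature <- function(s, w, smooth = TRUE) {
  stopifnot(inherits(s, "leaf_spectrum"), inherits(w, "absorption_window"))
  wl <- s$wavelength
  if (min(wl) > w$window[1] || max(wl) < w$window[2]) {
    stop("spectrum (", min(wl), "-", max(wl), " nm) does not cover window ",
         w$name, " [", w$window[1], ", ", w$window[2], "]", call. = FALSE)
  }
  in_win <- which(wl >= w$window[1] & wl <= w$window[2])
  loc <- s$reflectance
  if (smooth) {
    # smooth the window plus a margin so filter edge effects stay outside
    lo <- max(1L, min(in_win) - 14L); hi <- min(length(wl), max(in_win) + 14L)
    seg <- lo:hi
    loc[seg] <- smooth_for_location(s$reflectance[seg])
  }
  idx_l <- which(wl >= w$left_search[1] & wl <= w$left_search[2])
  idx_r <- which(wl >= w$right_search[1] & wl <= w$right_search[2])
  i1 <- idx_l[which.max(loc[idx_l])]   # which.max: smallest index on ties
  i2 <- idx_r[which.max(loc[idx_r])]
  feat <- list(name = w$name,
               lambda1 = wl[i1], lambda2 = wl[i2], lambda_m = NA_real_,
               rho1 = loc[i1], rho2 = loc[i2],
               rho_m = NA_real_, d = NA_real_, baseline_at_peak = NA_real_,
               sai = NA_real_, valid = FALSE, reason = "")
  interior <- if (i2 - i1 >= 2L) (i1 + 1L):(i2 - 1L) else integer(0)
  if (length(interior) == 0L) {
    feat$reason <- "no interior wavelengths between shoulders"
    return(structure(feat, class = "absorption_feature"))
  }
  im <- interior[which.min(loc[interior])]
  feat$lambda_m <- wl[im]
  feat$rho_m <- loc[im]
  span <- loc[i1:i2]
  if (max(span) - min(span) < 1e-12) {
    # constant window: no absorption, SAI will evaluate to exactly 1
    feat$valid <- TRUE
    return(structure(feat, class = "absorption_feature"))
  }
  if (im == i1 + 1L || im == i2 - 1L) {
    feat$reason <- "no interior dip (minimum adjacent to a shoulder)"
    return(structure(feat, class = "absorption_feature"))
  }
  feat$valid <- TRUE
  structure(feat, class = "absorption_feature")
}

#' @export
print.absorption_feature <- function(x, ...) {
  cat("<absorption_feature> ", x$name,
      ": shoulders ", x$lambda1, "/", x$lambda2, " nm, peak ", x$lambda_m,
      " nm, valid=", x$valid,
      if (!is.na(x$sai)) paste0(", SAI=", sprintf("%.4f", x$sai)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Absorption symmetry parameter d
#'
#' d = (lambda2 - lambda_m) / (lambda2 - lambda1), in (0, 1): the peak's
#' relative position measured from the right shoulder. It is exactly the
#' weight for which d*rho1 + (1-d)*rho2 equals the straight nonabsorption
#' baseline through the two shoulders evaluated at lambda_m.
#'
#' @param lambda1,lambda2 shoulder wavelengths (nm), lambda1 < lambda2.
#' @param lambda_m peak wavelength (nm), strictly between the shoulders.
#' @return d, dimensionless in (0, 1).
#' @examples
#' compute_d(1085, 1265, 1175)  # 0.5 (symmetric feature)
#' @export
compute_d <- function(lambda1, lambda2, lambda_m) {
  if (!(lambda1 < lambda_m && lambda_m < lambda2)) {
    stop("need lambda1 < lambda_m < lambda2 (got ", lambda1, ", ",
         lambda_m, ", ", lambda2, ")", call. = FALSE)
  }
  (lambda2 - lambda_m) / (lambda2 - lambda1)
}

#' Spectral absorption index of a located feature
#'
#' SAI = (d*rho1 + (1-d)*rho2) / rho_m: the nonabsorption baseline (the
#' straight line between the shoulders) evaluated at the peak wavelength,
#' divided by the reflectance at the peak -- a relative absorption depth.
#' SAI = 1 means no absorption; deeper dips give larger SAI.
#'
#' @param f an `absorption_feature` from [locate_feature()], valid, with
#'   rho_m > 0.
#' @return the SAI value (dimensionless scalar). The completed feature
#'   (with `d`, `baseline_at_peak` and `sai` filled) is attached as
#'   attribute `"feature"`.
#' @export
compute_sai <- function(f) {
  f <- complete_feature(f)
  structure(f$sai, feature = f)
}

complete_feature <- function(f) {
  stopifnot(inherits(f, "absorption_feature"))
  if (!isTRUE(f$valid)) {
    stop("feature ", f$name, " is not valid (", f$reason, ")", call. = FALSE)
  }
  if (!is.finite(f$rho_m) || f$rho_m <= 0) {
    stop("peak reflectance must be > 0", call. = FALSE)
  }
  f$d <- compute_d(f$lambda1, f$lambda2, f$lambda_m)
  f$baseline_at_peak <- f$d * f$rho1 + (1 - f$d) * f$rho2
  f$sai <- f$baseline_at_peak / f$rho_m
  f
}

#' Compute the three SAIs of one spectrum
#'
#' Runs [locate_feature()] and [compute_sai()] for each configured window
#' (by default the 970/1200/1660-nm features). A window with no usable
#' dip yields `NA` with the reason recorded.
#'
#' @param s a `leaf_spectrum` covering all windows.
#' @param windows named list of [absorption_window()]s; default
#'   [default_windows()].
#' @param smooth logical, passed to [locate_feature()].
#' @return named numeric vector of SAI values (`NA` where invalid), with
#'   the full feature list as attribute `"features"`.
#' @export
compute_sai_family <- function(s, windows = default_windows(), smooth = TRUE) {
  feats <- lapply(windows, function(w) locate_feature(s, w, smooth = smooth))
  vals <- vapply(feats, function(f) {
    if (!isTRUE(f$valid)) return(NA_real_)
    as.numeric(compute_sai(f))
  }, numeric(1))
  names(vals) <- names(windows)
  feats <- lapply(feats, function(f) {
    if (isTRUE(f$valid)) complete_feature(f) else f
  })
  structure(vals, features = feats)
}
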