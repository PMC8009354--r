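#' Default run configuration
#'
#' Collects every tunable of the pipeline in one list: the wavelength
#' grid range, the three SAI windows and shoulder search ranges, the
#' location-smoothing switch, and the cross-validation settings (k, seed
#' and the R2cv variant).
#'
#' @return list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    grid_range = c(350, 2500),
    windows = default_windows(),
    smooth = TRUE,
    cv = list(k = 10, seed = 20190515, r2_variant = "corr"),
    forms = regression_forms
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys present in the file override the defaults; everything else keeps
#' its default. SAI windows are given as
#' `windows: {SAI_1200: {window: [1085, 1265], left: [1085, 1110],
#' right: [1240, 1265]}}`.
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config '", path, "'",
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(raw$grid_range)) cfg$grid_range <- as.numeric(raw$grid_range)
  if (!is.null(raw$smooth)) cfg$smooth <- isTRUE(raw$smooth)
  if (!is.null(raw$windows)) {
    cfg$windows <- lapply(names(raw$windows), function(nm) {
      w <- raw$windows[[nm]]
      absorption_window(nm, as.numeric(w$window), as.numeric(w$left),
                        as.numeric(w$right))
    })
    names(cfg$windows) <- names(raw$windows)
  }
  for (key in c("k", "seed", "r2_variant")) {
    if (!is.null(raw$cv[[key]])) cfg$cv[[key]] <- raw$cv[[key]]
  }
  if (!is.null(raw$forms)) cfg$forms <- match.arg(raw$forms,
                                                  regression_forms,
                                                  several.ok = TRUE)
  cfg
}
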