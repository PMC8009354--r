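#' Equivalent water thickness
#'
#' EWT = (FW - DW) / A: the mass of leaf water per unit (single-sided)
#' leaf area, in g cm^-2. Vectorised.
#'
#' @param fw fresh weight (g).
#' @param dw dry weight (g).
#' @param area leaf area (cm^2).
#' @return EWT in g cm^-2.
#' @examples
#' compute_ewt(0.50, 0.30, 20)  # 0.010
#' @export
compute_ewt <- function(fw, dw, area) {
  check_gravimetric(fw, dw)
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("area must be finite and > 0", call. = FALSE)
  }
  (fw - dw) / area
}

#' Fuel moisture content
#'
#' FMC = (FW - DW) / FW: leaf water as a fraction of fresh mass,
#' dimensionless in (0, 1). Conventionally reported as a percentage;
#' this package keeps it as a fraction internally and formats as percent
#' only at output boundaries. Vectorised.
#'
#' @inheritParams compute_ewt
#' @return FMC as a fraction in (0, 1).
#' @examples
#' compute_fmc(0.50, 0.30)  # 0.40, i.e. 40%
#' @export
compute_fmc <- function(fw, dw) {
  check_gravimetric(fw, dw)
  (fw - dw) / fw
}

check_gravimetric <- function(fw, dw) {
  if (any(!is.finite(fw)) || any(!is.finite(dw))) {
    stop("weights must be finite", call. = FALSE)
  }
  if (any(dw <= 0)) stop("dry weight must be > 0", call. = FALSE)
  if (any(fw <= dw)) stop("fresh weight must exceed dry weight", call. = FALSE)
  invisible(TRUE)
}
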