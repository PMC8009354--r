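#' Generator defaults mirroring the three-species study design
#'
#' Per-species sample counts and EWT/FMC ranges follow the pooled
#' leaf dataset this package's analyses are designed around: VJ (n = 46,
#' EWT 0.006-0.010 g cm^-2, FMC 57.4-67.2%), VL (n = 66, EWT 0.006-0.013,
#' FMC 62.6-77.5%), VX (n = 180, EWT 0.008-0.016, FMC 45.16-82.72%).
#' Per-leaf absorption-centre jitter is Normal(0, 5 nm) and measurement
#' noise Normal(0, 0.002) reflectance units.
#'
#' @param n_per_species named integer vector of samples per species.
#' @param jitter_sd per-leaf absorption-centre jitter SD (nm).
#' @param noise_sd additive reflectance noise SD.
#' @param seed integer RNG seed.
#' @return list of class `generator_config`.
#' @export
default_generator_config <- function(n_per_species = c(VJ = 46, VL = 66,
                                                       VX = 180),
                                     jitter_sd = 5, noise_sd = 0.002,
                                     seed = 20190515) {
  ranges <- list(
    VJ = list(ewt = c(0.006, 0.010), fmc = c(0.5740, 0.6720)),
    VL = list(ewt = c(0.006, 0.013), fmc = c(0.6260, 0.7750)),
    VX = list(ewt = c(0.008, 0.016), fmc = c(0.4516, 0.8272)))
  species <- names(n_per_species)
  stopifnot(!is.null(species), all(n_per_species >= 1))
  specs <- lapply(species, function(sp) {
    rg <- if (sp %in% names(ranges)) ranges[[sp]]
          else list(ewt = c(0.006, 0.016), fmc = c(0.45, 0.83))
    list(n = as.integer(n_per_species[[sp]]), ewt_range = rg$ewt,
         fmc_range = rg$fmc, jitter_sd = jitter_sd)
  })
  names(specs) <- species
  structure(list(species_specs = specs, noise_sd = noise_sd, seed = seed,
                 area_range = c(10, 40), water_shift = 8,
                 grid = 350:2500), class = "generator_config")
}

# water and dry-matter absorption features: nominal centre (nm),
# Gaussian width (nm), and dip depth at the reference water status
# (EWT = 0.010 g cm^-2 for water bands; FMC deficit 1 - fmc = 0.40 for
# the dry-matter band). Widths of the 970/1200/1660 features are set so
# each dip is contained within its shoulder window -- the shoulders at
# the window edges must be near-absorption-free local maxima, which is
# the premise of the shoulder-baseline construction.
water_bands <- data.frame(
  centre = c(970, 1200, 1450, 1950),
  sigma  = c(20, 25, 45, 60),
  depth_ref = c(0.06, 0.12, 0.55, 0.75))
dry_band <- list(centre = 1660, sigma = 12, depth_ref = 0.08)

# smooth continuum: red-edge sigmoid rising 0.05 -> 0.48 across
# 700-760 nm, gently declining beyond 1300 nm
continuum_reflectance <- function(wl) {
  c0 <- 0.05 + 0.43 * stats::plogis((wl - 730) / 8)
  c0 * ifelse(wl > 1300, 1 - 1.2e-4 * (wl - 1300), 1)
}

#' Generate one leaf-like reflectance spectrum with known ground truth
#'
#' The spectrum is a smooth continuum multiplied by Gaussian absorption
#' dips plus i.i.d. noise:
#' rho(wl) = C(wl) * (1 - sum_k D_k * exp(-(wl - mu_k)^2 / (2*sigma_k^2)))
#' + eps(wl). Water dips sit near 970/1200/1450/1950 nm with depths
#' proportional to EWT (at EWT = 0.010 g cm^-2: 0.06/0.12/0.55/0.75,
#' capped at 0.95); a dry-matter (lignin/cellulose) dip near 1660 nm has
#' depth 0.08 * (1 - fmc) / 0.40, so it strengthens as FMC falls. Water
#' dip centres shift toward shorter wavelengths as EWT rises
#' (`water_shift` nm per 0.010 g cm^-2 above the 0.010 midpoint, the
#' blue-shift reported for wetter leaves) and every centre additionally
#' gets Normal(0, jitter) per-leaf jitter -- the leaf-to-leaf spectral
#' heterogeneity the adaptive SAIs are designed for. Reflectance is
#' clipped to (0.001, 1).
#'
#' @param ewt equivalent water thickness (g cm^-2), >= 0.
#' @param fmc fuel moisture content fraction in \[0, 1).
#' @param jitter per-leaf centre jitter SD (nm).
#' @param noise_sd additive noise SD (reflectance units).
#' @param seed optional seed; `NULL` (default) draws from the current
#'   RNG stream.
#' @param grid integer wavelength grid (nm).
#' @param water_shift deterministic blue-shift of water-band centres, nm
#'   per 0.010 g cm^-2 of EWT above 0.010 (default 8).
#' @param sample_id optional id stored on the spectrum.
#' @return list: `spectrum` (a `leaf_spectrum`) and `truth` (list with
#'   `ewt`, `fmc`, and per-band `centres` and `depths`).
#' @export
generate_leaf_spectrum <- function(ewt, fmc, jitter = 5, noise_sd = 0.002,
                                   seed = NULL, grid = 350:2500,
                                   water_shift = 8, sample_id = NULL) {
  stopifnot(ewt >= 0, fmc >= 0, fmc < 1, jitter >= 0, noise_sd >= 0)
  gen <- function() {
    depths <- pmin(water_bands$depth_ref * ewt / 0.010, 0.95)
    centres <- water_bands$centre - water_shift * (ewt - 0.010) / 0.010 +
      stats::rnorm(nrow(water_bands), 0, jitter)
    d_depth <- min(dry_band$depth_ref * (1 - fmc) / 0.40, 0.95)
    d_centre <- dry_band$centre + stats::rnorm(1, 0, jitter)
    if (any(depths < 0) || d_depth < 0) {
      stop("negative dip depth after scaling", call. = FALSE)
    }
    all_centres <- c(centres, d_centre)
    all_sigma <- c(water_bands$sigma, dry_band$sigma)
    all_depth <- c(depths, d_depth)
    absorb <- rep(0, length(grid))
    for (k in seq_along(all_centres)) {
      absorb <- absorb + all_depth[k] *
        exp(-(grid - all_centres[k])^2 / (2 * all_sigma[k]^2))
    }
    refl <- continuum_reflectance(grid) * (1 - absorb) +
      stats::rnorm(length(grid), 0, noise_sd)
    refl <- pmin(pmax(refl, 0.001), 1 - 1e-9)
    names(all_depth) <- names(all_centres) <-
      c(paste0("w", water_bands$centre), "dry1660")
    list(spectrum = spectrum(grid, refl, sample_id = sample_id),
         truth = list(ewt = ewt, fmc = fmc, centres = all_centres,
                      depths = all_depth))
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

#' Generate a full synthetic leaf dataset with ground truth
#'
#' Draws EWT, FMC and leaf area uniformly within each species' ranges,
#' then back-solves the gravimetric measurements so that the EWT and FMC
#' formulas reproduce the drawn truths exactly: water mass W = EWT * A,
#' FW = W / FMC, DW = FW - W. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [default_generator_config()] (or a modified copy).
#' @return list of class `synthetic_dataset`: `spectra` (a
#'   `spectrum_set`), `metadata` (data.frame sample_id, species,
#'   fresh_weight, dry_weight, area), `truth` (data.frame sample_id,
#'   species, true_ewt, true_fmc and per-band centre/depth columns).
#' @export
generate_dataset <- function(cfg = default_generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_local_seed(cfg$seed, {
    spectra <- list(); meta <- list(); truth <- list()
    for (sp in names(cfg$species_specs)) {
      spec <- cfg$species_specs[[sp]]
      for (i in seq_len(spec$n)) {
        id <- sprintf("%s%03d", sp, i)
        ewt <- stats::runif(1, spec$ewt_range[1], spec$ewt_range[2])
        fmc <- stats::runif(1, spec$fmc_range[1], spec$fmc_range[2])
        if (fmc >= 1) stop("FMC must be < 1 to back-solve weights",
                           call. = FALSE)
        area <- stats::runif(1, cfg$area_range[1], cfg$area_range[2])
        water <- ewt * area
        fw <- water / fmc
        dw <- fw - water
        g <- generate_leaf_spectrum(ewt, fmc, jitter = spec$jitter_sd,
                                    noise_sd = cfg$noise_sd,
                                    grid = cfg$grid,
                                    water_shift = cfg$water_shift,
                                    sample_id = id)
        spectra[[id]] <- g$spectrum
        meta[[id]] <- data.frame(sample_id = id, species = sp,
                                 fresh_weight = fw, dry_weight = dw,
                                 area = area)
        truth[[id]] <- data.frame(sample_id = id, species = sp,
                                  true_ewt = ewt, true_fmc = fmc,
                                  t(g$truth$centres) |>
                                    `colnames<-`(paste0("centre_",
                                                        names(g$truth$centres))),
                                  t(g$truth$depths) |>
                                    `colnames<-`(paste0("depth_",
                                                        names(g$truth$depths))))
      }
    }
    structure(list(spectra = spectrum_set(spectra),
                   metadata = do.call(rbind, c(meta,
                                               list(make.row.names = FALSE))),
                   truth = do.call(rbind, c(truth,
                                            list(make.row.names = FALSE)))),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$metadata), " leaves (",
      paste(names(table(x$metadata$species)),
            table(x$metadata$species), sep = ": ", collapse = ", "),
      "), grid ", min(x$spectra$grid), "-", max(x$spectra$grid), " nm\n",
      sep = "")
  invisible(x)
}
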