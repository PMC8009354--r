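#' Read leaf reflectance spectra from CSV
#'
#' Two layouts are supported. `wide`: one row per sample, a `sample_id`
#' column (or first column) plus one column per wavelength, column names
#' the wavelength in nm (an `X`/`wl_` prefix is tolerated). `long`: columns
#' `sample_id`, `wavelength_nm`, `reflectance`; several rows for the same
#' (sample, wavelength) are treated as replicate readings and averaged.
#' All samples must end up on one shared wavelength grid; a sample missing
#' a wavelength that others have is an error naming the sample and the
#' wavelength.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param layout `"wide"` or `"long"`.
#' @return a [spectrum_set()] on the file's native grid.
#' @export
read_spectra <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") read_spectra_wide(df) else read_spectra_long(df)
}

parse_wavelength_names <- function(nms) {
  suppressWarnings(as.numeric(sub("^(X|x|wl_|lambda_)", "", nms)))
}

read_spectra_wide <- function(df) {
  nms <- names(df)
  id_col <- if ("sample_id" %in% nms) "sample_id" else nms[1L]
  wl_cols <- setdiff(nms, id_col)
  wl <- parse_wavelength_names(wl_cols)
  if (anyNA(wl)) {
    stop("non-numeric wavelength column(s): ",
         paste(wl_cols[is.na(wl)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(wl)) {
    stop("duplicate wavelength columns: ",
         paste(unique(wl[duplicated(wl)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(wl)
  ids <- as.character(df[[id_col]])
  spectra <- lapply(seq_len(nrow(df)), function(i) {
    vals <- suppressWarnings(
      as.numeric(unlist(df[i, wl_cols[ord]], use.names = FALSE)))
    if (anyNA(vals)) {
      stop("non-numeric reflectance in row ", i, " (sample '", ids[i], "')",
           call. = FALSE)
    }
    spectrum(wl[ord], vals, sample_id = ids[i])
  })
  names(spectra) <- ids
  spectrum_set(spectra)
}

read_spectra_long <- function(df) {
  need <- c("sample_id", "wavelength_nm", "reflectance")
  if (!all(need %in% names(df))) {
    stop("long layout needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  refl <- suppressWarnings(as.numeric(df$reflectance))
  if (anyNA(refl)) {
    stop("non-numeric reflectance at row(s) ",
         paste(utils::head(which(is.na(refl)), 5L), collapse = ", "),
         call. = FALSE)
  }
  wl_all <- suppressWarnings(as.numeric(df$wavelength_nm))
  if (anyNA(wl_all)) {
    stop("non-numeric wavelength_nm at row(s) ",
         paste(utils::head(which(is.na(wl_all)), 5L), collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(df$sample_id)
  grid <- sort(unique(wl_all))
  spectra <- lapply(split(seq_len(nrow(df)), ids), function(rows) {
    id <- ids[rows[1L]]
    # replicate rows for one (sample, wavelength) are averaged
    m <- tapply(refl[rows], wl_all[rows], mean)
    wl <- as.numeric(names(m))
    missing <- setdiff(grid, wl)
    if (length(missing) > 0L) {
      stop("sample '", id, "' missing wavelength(s) ",
           paste(utils::head(missing, 5L), collapse = ", "), " nm",
           call. = FALSE)
    }
    spectrum(wl, as.numeric(m), sample_id = id)
  })
  spectrum_set(spectra[unique(ids)])
}

#' Write a spectrum set to CSV
#'
#' Inverse of [read_spectra()]; full precision (up to 15 significant
#' digits) so that a write/read round trip reproduces values to ~1e-12.
#'
#' @param set a `spectrum_set`.
#' @param path output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(set, "spectrum_set"))
  if (layout == "wide") {
    df <- data.frame(sample_id = rownames(set$reflectance),
                     set$reflectance, check.names = FALSE)
    names(df) <- c("sample_id", set$grid)
  } else {
    df <- data.frame(
      sample_id = rep(rownames(set$reflectance), each = length(set$grid)),
      wavelength_nm = rep(set$grid, times = nrow(set$reflectance)),
      reflectance = as.vector(t(set$reflectance)))
  }
  old <- options(digits = 15)
  on.exit(options(old))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read leaf gravimetric metadata from CSV
#'
#' Requires columns `sample_id`, `species`, `fresh_weight` (g),
#' `dry_weight` (g), `area` (cm^2). Rows must satisfy
#' fresh_weight > dry_weight > 0 and area > 0; violations are reported with
#' the offending sample ids.
#'
#' @param path CSV file path.
#' @return data.frame with the five validated columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "fresh_weight", "dry_weight", "area")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  for (col in c("fresh_weight", "dry_weight", "area")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(df[[col]])) {
      stop("non-numeric ", col, " for sample(s) ",
           paste(df$sample_id[is.na(df[[col]])], collapse = ", "),
           call. = FALSE)
    }
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !(df$fresh_weight > df$dry_weight & df$dry_weight > 0)
  if (any(bad)) {
    stop("need fresh_weight > dry_weight > 0; violated by sample(s) ",
         paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  bad_area <- !(df$area > 0)
  if (any(bad_area)) {
    stop("need area > 0; violated by sample(s) ",
         paste(df$sample_id[bad_area], collapse = ", "), call. = FALSE)
  }
  df
}

#' Join spectra with gravimetric metadata into leaf samples
#'
#' Every spectrum must have a metadata row; EWT and FMC are computed on
#' join (see [compute_ewt()], [compute_fmc()]).
#'
#' @param set a `spectrum_set`.
#' @param metadata data.frame from [read_metadata()].
#' @return list of class `leaf_samples` with elements `spectra` (the set)
#'   and `meta` (metadata restricted to and ordered like the set, with
#'   `ewt` and `fmc` columns appended).
#' @export
join_samples <- function(set, metadata) {
  stopifnot(inherits(set, "spectrum_set"))
  ids <- sample_ids(set)
  unknown <- setdiff(ids, metadata$sample_id)
  if (length(unknown) > 0L) {
    stop("no metadata for sample(s) ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  meta$ewt <- compute_ewt(meta$fresh_weight, meta$dry_weight, meta$area)
  meta$fmc <- compute_fmc(meta$fresh_weight, meta$dry_weight)
  structure(list(spectra = set, meta = meta), class = "leaf_samples")
}

#' @export
print.leaf_samples <- function(x, ...) {
  cat("<leaf_samples> ", nrow(x$meta), " leaves, species: ",
      paste(sort(unique(x$meta$species)), collapse = ", "), "\n", sep = "")
  invisible(x)
}
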