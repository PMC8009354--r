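#' Build a k-fold cross-validation plan
#'
#' Samples are randomly permuted and dealt round-robin into k folds, so
#' fold sizes differ by at most one. Deterministic given the seed; the
#' caller's RNG state is untouched.
#'
#' @param n number of samples.
#' @param k number of folds (default 10).
#' @param seed integer seed for the permutation.
#' @return list of class `fold_plan`: `k`, `seed`, `assignment` (integer
#'   vector of length n with values in 1..k).
#' @export
make_folds <- function(n, k = 10, seed = 20190515) {
  if (!(n >= k && k >= 2)) {
    stop("need n >= k >= 2 (got n = ", n, ", k = ", k, ")", call. = FALSE)
  }
  perm <- with_local_seed(seed, sample.int(n))
  assignment <- integer(n)
  assignment[perm] <- rep_len(seq_len(k), n)
  structure(list(k = as.integer(k), seed = seed, assignment = assignment),
            class = "fold_plan")
}

# run expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

regression_forms <- c("linear", "quadratic", "exponential")

min_points <- function(form) if (form == "linear") 3L else 4L

#' Fit one index-to-target functional form
#'
#' `linear`: y = b1*x + b0 and `quadratic`: y = b2*x^2 + b1*x + b0 by
#' ordinary least squares; `exponential`: y = a*exp(b*x) by
#' Levenberg-Marquardt nonlinear least squares started from the
#' log-linear fit (requires y > 0 for the start; near-zero or negative
#' responses make the form inapplicable).
#'
#' @param x numeric predictor (index values).
#' @param y numeric response (ewt or fmc).
#' @param form one of `"linear"`, `"quadratic"`, `"exponential"`.
#' @return list of class `form_fit` with `form`, `coef` (named numeric),
#'   and `n`.
#' @export
fit_form <- function(x, y, form = regression_forms) {
  form <- match.arg(form)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_points(form)) {
    stop("need at least ", min_points(form), " finite points for ", form,
         " fit (got ", length(x), ")", call. = FALSE)
  }
  coef <- switch(form,
    linear = {
      fit <- stats::lm(y ~ x)
      c(b0 = unname(stats::coef(fit)[1]), b1 = unname(stats::coef(fit)[2]))
    },
    quadratic = {
      fit <- stats::lm(y ~ x + I(x^2))
      cf <- stats::coef(fit)
      if (anyNA(cf)) stop("singular design for quadratic fit", call. = FALSE)
      c(b0 = unname(cf[1]), b1 = unname(cf[2]), b2 = unname(cf[3]))
    },
    exponential = {
      if (any(y <= 0)) {
        stop("exponential form needs positive responses", call. = FALSE)
      }
      init <- stats::coef(stats::lm(log(y) ~ x))
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(b * x),
                          start = list(a = exp(unname(init[1])),
                                       b = unname(init[2])),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) stop("exponential fit did not converge: ",
                                 conditionMessage(e), call. = FALSE))
      cf <- stats::coef(fit)
      c(a = unname(cf["a"]), b = unname(cf["b"]))
    })
  if (anyNA(coef)) stop("singular design for ", form, " fit", call. = FALSE)
  structure(list(form = form, coef = coef, n = length(x)), class = "form_fit")
}

#' @export
predict.form_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  cf <- object$coef
  switch(object$form,
    linear = cf["b0"] + cf["b1"] * x,
    quadratic = cf["b0"] + cf["b1"] * x + cf["b2"] * x^2,
    exponential = cf["a"] * exp(cf["b"] * x)) |> unname()
}

#' @export
print.form_fit <- function(x, ...) {
  cat("<form_fit> ", format_equation(x), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Format a fitted equation in report style
#'
#' @param fit a `form_fit`.
#' @param digits decimals for coefficients (default 3, table style).
#' @return character scalar such as `"y = 0.204*x-0.205"`.
#' @export
format_equation <- function(fit, digits = 3) {
  f <- function(v) sprintf(paste0("%.", digits, "f"), v)
  signed <- function(v) ifelse(v < 0, f(v), paste0("+", f(v)))
  cf <- fit$coef
  switch(fit$form,
    linear = paste0("y = ", f(cf["b1"]), "*x", signed(cf["b0"])),
    quadratic = paste0("y = ", f(cf["b2"]), "*x^2", signed(cf["b1"]), "*x",
                       signed(cf["b0"])),
    exponential = paste0("y = ", f(cf["a"]), "*e^(", f(cf["b"]), "*x)"))
}

# overall association p-value of the full-data fit: F-test against the
# intercept-only model (df1 = model parameters - 1)
association_p_value <- function(x, y, fit) {
  pred <- predict(fit, x)
  n <- length(y)
  p <- length(fit$coef)
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(NA_real_)
  fstat <- ((sst - sse) / (p - 1)) / (sse / (n - p))
  stats::pf(fstat, p - 1, n - p, lower.tail = FALSE)
}

#' Cross-validate one index / target / form combination
#'
#' Fits the form on k-1 folds and predicts the held-out fold, repeating
#' over all folds so every used sample is predicted exactly once
#' out-of-fold. Rows with a missing index or target value are dropped
#' (reported via `message()`); the fold plan rows for dropped samples are
#' ignored.
#'
#' Pooled out-of-fold metrics: R2cv is by default the squared Pearson
#' correlation between out-of-fold predictions and observations
#' (`r2_variant = "corr"`); `"sse"` gives 1 - SSE/SST instead. RMSEcv is
#' the root mean squared out-of-fold error and rRMSEcv = RMSEcv divided
#' by the mean of the observed target.
#'
#' @param table index table from [build_index_table()].
#' @param index_name column to use as predictor.
#' @param target `"ewt"` or `"fmc"`.
#' @param form regression form, see [fit_form()].
#' @param folds a [make_folds()] plan for `nrow(table)` samples.
#' @param r2_variant `"corr"` (default) or `"sse"`.
#' @return list of class `cv_fit`: `index_name`, `target`, `form`,
#'   `coef` (full-data fit), `equation`, `p_value`, `predictions`
#'   (data.frame sample_id / fold / observed / predicted), `r2cv`,
#'   `rmse_cv`, `rrmse_cv`, `n_used`.
#' @export
cross_validate <- function(table, index_name, target, form = "linear",
                           folds, r2_variant = c("corr", "sse")) {
  r2_variant <- match.arg(r2_variant)
  for (col in c(index_name, target)) {
    if (!col %in% names(table)) {
      stop("column '", col, "' not in table; available: ",
           paste(setdiff(names(table), c("sample_id", "species")),
                 collapse = ", "), call. = FALSE)
    }
  }
  stopifnot(inherits(folds, "fold_plan"))
  if (length(folds$assignment) != nrow(table)) {
    stop("fold plan is for ", length(folds$assignment),
         " samples but table has ", nrow(table), call. = FALSE)
  }
  x <- table[[index_name]]; y <- table[[target]]
  keep <- is.finite(x) & is.finite(y)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " sample(s) with missing ",
            index_name, " or ", target)
  }
  idx <- which(keep)
  fold_of <- folds$assignment[idx]
  pred <- numeric(length(idx))
  for (f in sort(unique(fold_of))) {
    test <- fold_of == f
    if (sum(!test) < min_points(form)) {
      stop("fold ", f, " leaves only ", sum(!test),
           " training points for ", form, " fit", call. = FALSE)
    }
    fit_f <- fit_form(x[idx[!test]], y[idx[!test]], form)
    pred[test] <- predict(fit_f, x[idx[test]])
  }
  obs <- y[idx]
  r2 <- if (r2_variant == "corr") {
    if (stats::sd(pred) == 0 || stats::sd(obs) == 0) 0
    else stats::cor(pred, obs)^2
  } else {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  rmse <- sqrt(mean((obs - pred)^2))
  full <- fit_form(x[idx], y[idx], form)
  structure(list(
    index_name = index_name, target = target, form = form,
    coef = full$coef, equation = format_equation(full),
    p_value = association_p_value(x[idx], y[idx], full),
    predictions = data.frame(
      sample_id = if ("sample_id" %in% names(table)) table$sample_id[idx]
                  else as.character(idx),
      fold = fold_of, observed = obs, predicted = pred),
    r2cv = r2, rmse_cv = rmse, rrmse_cv = rmse / mean(obs),
    n_used = length(idx)), class = "cv_fit")
}

#' @export
print.cv_fit <- function(x, ...) {
  cat("<cv_fit> ", x$index_name, " -> ", x$target, " (", x$form, "): ",
      x$equation, "; R2cv = ", sprintf("%.3f", x$r2cv),
      ", rRMSEcv = ", sprintf("%.2f%%", 100 * x$rrmse_cv),
      ", n = ", x$n_used, "\n", sep = "")
  invisible(x)
}

#' Rank indices by cross-validated skill for one target
#'
#' For every index the candidate forms are cross-validated and the form
#' with the highest R2cv kept; indices are then sorted by decreasing
#' R2cv. Indices whose full-data association has p >= alpha are marked
#' not significant (`n.s.`).
#'
#' @param table index table.
#' @param target `"ewt"` or `"fmc"`.
#' @param forms candidate forms (default all three).
#' @param folds fold plan; default a fresh [make_folds()] on
#'   `nrow(table)`.
#' @param index_names indices to rank; default every index column.
#' @param alpha significance level for the n.s. flag (default 0.05).
#' @param r2_variant passed to [cross_validate()].
#' @return data.frame with columns index, form, p_value, significant,
#'   equation, r2cv, rrmse_cv (fraction), n_used; one row per index,
#'   sorted by r2cv descending. Full `cv_fit` objects in attribute
#'   `"fits"` (named by index).
#' @export
rank_indices <- function(table, target, forms = regression_forms,
                         folds = NULL, index_names = NULL, alpha = 0.05,
                         r2_variant = "corr") {
  if (is.null(index_names)) {
    index_names <- setdiff(names(table),
                           c("sample_id", "species", "ewt", "fmc"))
  }
  if (length(index_names) < 1L) stop("no index columns", call. = FALSE)
  if (is.null(folds)) folds <- make_folds(nrow(table), k = 10)
  best <- list()
  for (ix in index_names) {
    fits <- list()
    for (fm in forms) {
      fit <- tryCatch(
        suppressMessages(cross_validate(table, ix, target, fm, folds,
                                        r2_variant = r2_variant)),
        error = function(e) NULL)
      if (!is.null(fit)) fits[[fm]] <- fit
    }
    if (length(fits) == 0L) {
      message("index ", ix, ": no form could be fitted; skipped")
      next
    }
    best[[ix]] <- fits[[which.max(vapply(fits, `[[`, numeric(1), "r2cv"))]]
  }
  if (length(best) == 0L) stop("no index could be fitted", call. = FALSE)
  rep <- data.frame(
    index = names(best),
    form = vapply(best, `[[`, character(1), "form"),
    p_value = vapply(best, `[[`, numeric(1), "p_value"),
    significant = vapply(best, function(f) isTRUE(f$p_value < alpha),
                         logical(1)),
    equation = vapply(best, `[[`, character(1), "equation"),
    r2cv = vapply(best, `[[`, numeric(1), "r2cv"),
    rrmse_cv = vapply(best, `[[`, numeric(1), "rrmse_cv"),
    n_used = vapply(best, `[[`, integer(1), "n_used"),
    row.names = NULL)
  rep <- rep[order(-rep$r2cv), , drop = FALSE]
  rownames(rep) <- NULL
  structure(rep, fits = best)
}

#' Similarity of two indices' cross-validated predictions
#'
#' Squared Pearson correlation between the out-of-fold prediction vectors
#' of two indices fitted to the same target on the same folds -- high
#' similarity means the two indices carry the same information about the
#' target. Only samples with both indices present are used.
#'
#' @param table index table.
#' @param index_a,index_b index column names.
#' @param target `"ewt"` or `"fmc"`.
#' @param form_a,form_b regression forms (default linear).
#' @param folds fold plan; default [make_folds()] on `nrow(table)`.
#' @return squared correlation (scalar); the two `cv_fit`s as attribute
#'   `"fits"`.
#' @export
similarity_analysis <- function(table, index_a, index_b, target,
                                form_a = "linear", form_b = "linear",
                                folds = NULL) {
  if (is.null(folds)) folds <- make_folds(nrow(table), k = 10)
  common <- is.finite(table[[index_a]]) & is.finite(table[[index_b]]) &
    is.finite(table[[target]])
  sub <- table[common, , drop = FALSE]
  sub_folds <- folds
  sub_folds$assignment <- folds$assignment[common]
  fa <- suppressMessages(
    cross_validate(sub, index_a, target, form_a, sub_folds))
  fb <- suppressMessages(
    cross_validate(sub, index_b, target, form_b, sub_folds))
  if (nrow(fa$predictions) != nrow(fb$predictions)) {
    stop("prediction vectors differ in length", call. = FALSE)
  }
  pa <- fa$predictions$predicted; pb <- fb$predictions$predicted
  r2 <- if (stats::sd(pa) == 0 || stats::sd(pb) == 0) 0
        else stats::cor(pa, pb)^2
  structure(r2, fits = list(fa, fb))
}

#' Per-species regression fits
#'
#' Fits the given form separately within each species (full-data fits, no
#' cross-validation) and summarises the spread of the coefficients across
#' species -- a small spread means one shared index-target relation holds
#' across species. Species with fewer than `min_n` usable samples are
#' skipped with a warning.
#'
#' @param table index table with a `species` column.
#' @param target `"ewt"` or `"fmc"`.
#' @param index_name predictor column.
#' @param form regression form.
#' @param min_n minimum samples per species (default 5).
#' @return list: `fits` data.frame (species, n, one column per
#'   coefficient, equation), `coef_range` named numeric (max - min of
#'   each coefficient across fitted species).
#' @export
group_by_species <- function(table, target, index_name, form = "linear",
                             min_n = 5) {
  if (!"species" %in% names(table)) stop("no species column", call. = FALSE)
  out <- list()
  for (sp in unique(table$species)) {
    sub <- table[table$species == sp, , drop = FALSE]
    ok <- is.finite(sub[[index_name]]) & is.finite(sub[[target]])
    if (sum(ok) < min_n) {
      warning("species ", sp, " has ", sum(ok),
              " usable samples (< ", min_n, "); skipped", call. = FALSE)
      next
    }
    fit <- fit_form(sub[[index_name]][ok], sub[[target]][ok], form)
    out[[sp]] <- c(list(species = sp, n = sum(ok)), as.list(fit$coef),
                   list(equation = format_equation(fit)))
  }
  if (length(out) == 0L) stop("no species with enough samples", call. = FALSE)
  fits <- do.call(rbind, lapply(out, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(fits) <- NULL
  coef_cols <- setdiff(names(fits), c("species", "n", "equation"))
  coef_range <- vapply(coef_cols, function(cn) {
    v <- fits[[cn]]; max(v) - min(v)
  }, numeric(1))
  list(fits = fits, coef_range = coef_range)
}
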