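test_that("fold plans are balanced, deterministic and validated", {
  fp <- make_folds(292, 10, seed = 1)
  sizes <- as.vector(table(fp$assignment))
  expect_equal(sort(sizes), c(rep(29, 8), 30, 30))
  expect_equal(sort(unique(fp$assignment)), 1:10)
  # leave-one-out at n = k
  expect_equal(sort(make_folds(10, 10, seed = 2)$assignment), 1:10)
  expect_identical(make_folds(50, 5, seed = 7), make_folds(50, 5, seed = 7))
  expect_false(identical(make_folds(50, 5, seed = 7)$assignment,
                         make_folds(50, 5, seed = 8)$assignment))
  expect_error(make_folds(5, 10), "n >= k")
})

test_that("each functional form recovers exact and noisy truths", {
  x <- c(1, 2, 3, 4, 5)
  fit <- fit_form(x, 2 * x + 1, "linear")
  expect_equal(unname(fit$coef), c(1, 2), tolerance = 1e-10)
  expect_equal(predict(fit, 10), 21, tolerance = 1e-10)

  fitq <- fit_form(x, 3 * x^2 - 2 * x + 0.5, "quadratic")
  expect_equal(unname(fitq$coef), c(0.5, -2, 3), tolerance = 1e-8)

  fite <- fit_form(x, 0.4 * exp(0.3 * x), "exponential")
  expect_equal(unname(fite$coef), c(0.4, 0.3), tolerance = 1e-6)

  # known slope under noise: estimate within 3 standard errors
  set.seed(123)
  n <- 200; sigma <- 0.5
  xn <- runif(n, 0, 10); yn <- 1.7 * xn + 2 + rnorm(n, 0, sigma)
  fl <- fit_form(xn, yn, "linear")
  se <- sigma / (sd(xn) * sqrt(n - 1))
  expect_lt(abs(fl$coef[["b1"]] - 1.7), 3 * se)

  expect_error(fit_form(c(1, 2), c(1, 2), "linear"), "at least 3")
  expect_error(fit_form(c(1, 2, 3), c(1, 2, 3), "quadratic"), "at least 4")
})

test_that("cross-validation is exact on a noiseless linear relation", {
  set.seed(4)
  n <- 60
  tab <- data.frame(sample_id = as.character(1:n), idx = runif(n, 1, 2))
  tab$ewt <- 0.2 * tab$idx - 0.19
  folds <- make_folds(n, 10, seed = 3)
  for (variant in c("corr", "sse")) {
    cv <- cross_validate(tab, "idx", "ewt", "linear", folds,
                         r2_variant = variant)
    expect_equal(cv$r2cv, 1, tolerance = 1e-10)
    expect_lt(cv$rrmse_cv, 1e-10)
  }
})

test_that("out-of-fold predictions cover every used sample exactly once", {
  study <- full_study()
  cv <- cross_validate(study$tab, "SAI_1200", "ewt", "linear", study$folds)
  expect_equal(sort(cv$predictions$sample_id), sort(study$tab$sample_id))
  expect_equal(cv$n_used, nrow(study$tab))
  # relative RMSE definition: RMSE over the mean of the observations,
  # recomputed independently from the prediction table
  p <- cv$predictions
  rmse <- sqrt(sum((p$observed - p$predicted)^2) / nrow(p))
  expect_equal(cv$rrmse_cv, rmse / (sum(p$observed) / nrow(p)),
               tolerance = 1e-12)
})

test_that("an index unrelated to the target scores near zero", {
  set.seed(77)
  n <- 300
  tab <- data.frame(idx = rnorm(n), ewt = runif(n, 0.006, 0.016))
  cv <- cross_validate(tab, "idx", "ewt", "linear", make_folds(n, 10, 5))
  expect_lt(cv$r2cv, 0.05)
})

test_that("R2cv of a linear fit is invariant to affine index rescaling", {
  study <- full_study()
  tab <- study$tab
  tab$scaled <- 100 * tab$SAI_1200 - 57
  a <- cross_validate(tab, "SAI_1200", "ewt", "linear", study$folds)
  b <- cross_validate(tab, "scaled", "ewt", "linear", study$folds)
  expect_equal(a$r2cv, b$r2cv, tolerance = 1e-9)
  expect_equal(a$rrmse_cv, b$rrmse_cv, tolerance = 1e-9)
})

test_that("added index noise monotonically degrades R2cv", {
  study <- full_study()
  tab <- study$tab
  set.seed(2024)
  r2 <- sapply(c(0, 0.02, 0.05, 0.12), function(s) {
    tab$noisy <- tab$SAI_1200 + rnorm(nrow(tab), 0, s)
    cross_validate(tab, "noisy", "ewt", "linear", study$folds)$r2cv
  })
  expect_true(all(diff(r2) < 0))
})

test_that("index ranking reports the strongest index first", {
  study <- full_study()
  rep <- rank_indices(study$tab, "ewt", forms = c("linear", "quadratic"),
                      folds = study$folds,
                      index_names = c("SAI_970", "SAI_1200", "RATIO_1200",
                                      "WI", "MSI"))
  expect_equal(rep$index[1], "SAI_1200")
  expect_lt(match("SAI_970", rep$index), match("MSI", rep$index))
  expect_true(all(c("index", "p_value", "significant", "equation",
                    "r2cv", "rrmse_cv") %in% names(rep)))
  expect_true(all(diff(rep$r2cv) <= 0))
  expect_true(rep$significant[rep$index == "SAI_1200"])
  # single index gives a one-row report
  one <- rank_indices(study$tab, "ewt", forms = "linear",
                      folds = study$folds, index_names = "WI")
  expect_equal(nrow(one), 1)
})

test_that("prediction similarity is 1 for self and near 0 for noise", {
  study <- full_study()
  tab <- study$tab
  expect_equal(as.numeric(
    similarity_analysis(tab, "SAI_1200", "SAI_1200", "ewt",
                        folds = study$folds)), 1, tolerance = 1e-12)
  # two uninformative indices: their prediction vectors collapse toward
  # the fold training means, which both share, so the null similarity is
  # bounded away from zero -- but stays well below informative pairs
  set.seed(9)
  tab$rand_a <- rnorm(nrow(tab)); tab$rand_b <- rnorm(nrow(tab))
  expect_lt(as.numeric(
    similarity_analysis(tab, "rand_a", "rand_b", "ewt",
                        folds = study$folds)), 0.6)
  # the adaptive index and its fixed-band counterpart track the same dip
  expect_gt(as.numeric(
    similarity_analysis(tab, "SAI_1200", "RATIO_1200", "ewt",
                        folds = study$folds)), 0.8)
})

test_that("species sharing one relation give nearly identical fits", {
  set.seed(15)
  n <- 90
  tab <- data.frame(species = rep(c("VJ", "VL", "VX"), each = n / 3),
                    idx = runif(n, 1.0, 1.3))
  tab$ewt <- 0.2 * tab$idx - 0.19 + rnorm(n, 0, 0.0002)
  gs <- group_by_species(tab, "ewt", "idx", "linear")
  expect_equal(nrow(gs$fits), 3)
  expect_lt(gs$coef_range[["b1"]], 0.05 * 0.2)
  # single-species input gives a single fit
  one <- group_by_species(tab[tab$species == "VX", ], "ewt", "idx", "linear")
  expect_equal(nrow(one$fits), 1)
  # an undersized species is skipped with a warning
  tab2 <- rbind(tab, data.frame(species = "ZZ", idx = c(1, 1.2),
                                ewt = c(0.01, 0.012)))
  expect_warning(gs2 <- group_by_species(tab2, "ewt", "idx", "linear"),
                 "ZZ")
  expect_false("ZZ" %in% gs2$fits$species)
})
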