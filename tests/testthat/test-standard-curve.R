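test_that("the 5PL closed form behaves at its landmarks", {
  expect_equal(fivepl(100, 50, 20000, 100, 1.2, 1), (50 + 20000) / 2)
  expect_equal(fivepl(0, 50, 20000, 100, 1.2, 0.8), 50)
  expect_equal(fivepl(10, 0, 1, 1, 1, 1), 1 / 1.1)
  expect_error(fivepl(-1, 0, 1, 1, 1, 1), "non-negative")

  # strict monotonicity over random parameter draws
  set.seed(4)
  for (i in 1:20) {
    b <- runif(1, 0, 100); t <- b + runif(1, 100, 1e5)
    e <- 10^runif(1, 0, 3); h <- runif(1, 0.3, 3); a <- runif(1, 0.3, 3)
    x <- sort(e * 10^runif(50, -2, 2))
    y <- fivepl(x, b, t, e, h, a)
    expect_true(all(diff(y) > 0))
    expect_true(all(y > b & y < t))
  }
})

test_that("the analytic inverse round-trips the forward curve", {
  set.seed(8)
  x <- 10^runif(100, -2, 4)
  y <- fivepl(x, 30, 25000, 120, 1.1, 0.7)
  back <- fivepl_inverse(y, 30, 25000, 120, 1.1, 0.7)
  expect_equal(back, x, tolerance = 1e-9)
  expect_true(is.na(fivepl_inverse(30, 30, 25000, 120, 1.1, 0.7)))
})

test_that("censoring classification follows the standards span and asymptotes", {
  fit <- fit_5pl(tibble::tibble(
    conc = rep(10000 / 4^(0:7), 2),
    fluorescence = rep(fivepl(10000 / 4^(0:7), 50, 20000, 100, 1.2, 1), 2)
  ))
  lo <- fit$standards_fl_range[1L]
  mapped <- inverse_5pl(fit, c(fit$bottom, (fit$bottom + lo) / 2, lo + 1,
                               fit$top, fit$top + 100))
  expect_equal(mapped$censor_status,
               c("oor_low", "extrapolated", "in_range", "oor_high", "oor_high"))
  expect_true(is.na(mapped$concentration[1]))
  expect_false(is.na(mapped$concentration[2]))  # extrapolated still mapped

  # round trip at the EC50 midpoint
  mid <- inverse_5pl(fit, predict(fit, fit$ec50))
  expect_equal(mid$concentration, fit$ec50, tolerance = 1e-6)

  # censoring conservation on arbitrary responses
  fl <- runif(500, 0, 25000)
  st <- inverse_5pl(fit, fl)$censor_status
  expect_equal(sum(table(st)), 500L)
})

test_that("noise-free standards recover the generating parameters", {
  cc <- 10000 / 4^(0:7)
  truth <- c(50, 20000, 100, 1.2, 0.8)
  std <- tibble::tibble(conc = rep(cc, 2),
                        fluorescence = rep(fivepl(cc, 50, 20000, 100, 1.2, 0.8), 2))
  for (w in c("inverse_response_squared", "none")) {
    fit <- fit_5pl(std, weight_mode = w)
    est <- c(fit$bottom, fit$top, fit$ec50, fit$hill, fit$asym)
    expect_equal(est, truth, tolerance = 1e-6)
  }
  # fit idempotence: refit on the fitted curve's own predictions
  std2 <- tibble::tibble(conc = cc, fluorescence = predict(fit_5pl(std), cc))
  refit <- fit_5pl(std2)
  expect_equal(refit$ec50, 100, tolerance = 1e-6)
})

test_that("ec50 is recovered within 5% median error under 1% noise", {
  conc <- 10000 / 4^(0:7)
  base <- fivepl(conc, 50, 20000, 100, 1.2, 0.8)
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    fl <- rep(base, 2) * exp(rnorm(16, 0, 0.01))
    fit <- fit_5pl(tibble::tibble(conc = rep(conc, 2), fluorescence = fl))
    abs(fit$ec50 - 100) / 100
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("response weighting improves low-end recovery on heteroscedastic data", {
  conc <- 10000 / 4^(0:7)
  base <- fivepl(conc, 50, 20000, 100, 1.2, 1)
  low_err <- function(fit) {
    # relative back-calculation error at the two lowest standards; a level the
    # fitted curve cannot back-calculate at all counts as maximal error
    rec <- fit$recovery[fit$recovery$conc <= conc[7L], ]
    e <- abs(rec$recovery - 1)
    e[is.na(e)] <- 1
    mean(e)
  }
  res <- vapply(1:30, function(s) {
    set.seed(100 + s)
    fl <- rep(base, 3) * exp(rnorm(24, 0, 0.05))  # constant-CV noise
    std <- tibble::tibble(conc = rep(conc, 3), fluorescence = fl)
    c(w = low_err(fit_5pl(std, "inverse_response_squared")),
      u = low_err(fit_5pl(std, "none")))
  }, numeric(2))
  expect_lt(mean(res["w", ]), mean(res["u", ]))
})

test_that("blank-based LOD follows mean + k * sd and censors below the curve", {
  fit <- fit_5pl(tibble::tibble(
    conc = rep(10000 / 4^(0:7), 2),
    fluorescence = rep(fivepl(10000 / 4^(0:7), 50, 20000, 100, 1.2, 1), 2)
  ))
  expect_equal(lod_from_blanks(fit, c(60, 60, 60))$lod_fl, 60)
  expect_equal(lod_from_blanks(fit, c(10, 12, 14), k = 2)$lod_fl, 16)
  below <- lod_from_blanks(fit, c(10, 12, 14), k = 2)
  expect_true(is.na(below$lod_conc))       # 16 < bottom = 50
  expect_equal(below$status, "oor_low")
  expect_error(lod_from_blanks(fit, 10), "at least 2")
})

test_that("map_dataset fills sample wells and never alters fluorescence", {
  ds <- toy_plate_table()
  fits <- fit_standard_curves(ds)
  expect_error(map_dataset(ds, fits["nope"]), "IL-8")
  mapped <- map_dataset(ds, fits)
  expect_identical(mapped$fluorescence, ds$fluorescence)
  samp <- mapped[mapped$well_role == "sample", ]
  expect_true(all(samp$censor_status != "unset"))
  expect_identical(is.na(samp$concentration),
                   samp$censor_status %in% c("oor_low", "oor_high"))
  # fluorescence analysis path keeps every record regardless of status
  expect_equal(nrow(prepare_model_data(mapped, "fluorescence")),
               nrow(samp))
})

test_that("noise-free generated data map back to their latent concentrations", {
  cfg <- generator_config(
    n_analytes = 4L, design = balanced_design(),
    var_patient = 0.02, var_plategroup = 0.01, var_resid = 0.01,
    analyte_baselines = seq(3, 9, length.out = 4L),
    fl_noise_cv = 1e-12, quantization_step = 1e-8, seed = 21L
  )
  gen <- generate_dataset(cfg)
  mapped <- map_dataset(gen$data, fit_standard_curves(gen$data))
  samp <- dplyr::filter(mapped, .data$well_role == "sample",
                        .data$censor_status == "in_range")
  key <- dplyr::distinct(samp, .data$patient_id, .data$tissue,
                         .data$condition, .data$analyte, .data$concentration)
  truth <- dplyr::select(gen$truth$latent, "patient_id", "tissue",
                         "condition", "analyte", "latent")
  joined <- dplyr::inner_join(key, truth,
                              by = c("patient_id", "tissue", "condition",
                                     "analyte"))
  expect_gt(nrow(joined), 50L)
  expect_equal(unname(joined$concentration), unname(2^joined$latent),
               tolerance = 1e-6)
})
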