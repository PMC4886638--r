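test_that("with negligible random variation the mixed model matches OLS", {
  cfg <- recovery_config(n_analytes = 4L, conditions = 2L, seed = 14L,
                         var_patient = 0, var_plategroup = 0)
  gen <- generate_dataset(cfg)
  fit <- suppressWarnings(fit_lmm(gen$data, "fluorescence", "global"))
  dat <- prepare_model_data(gen$data, "fluorescence")
  ols <- lm(log2_response ~ analyte + tissue + condition +
              analyte:tissue + analyte:condition, data = dat)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-4)
})

test_that("the REML criterion matches a dense-matrix oracle at the optimum", {
  cfg <- recovery_config(n_analytes = 2L, tissues = 2L, conditions = 2L,
                         patients_per_cell = 3L, seed = 6L)
  gen <- generate_dataset(cfg)
  # tiny instance: a variance component may pin at its zero boundary
  fit <- suppressWarnings(fit_lmm(gen$data, "fluorescence", "global"))
  dat <- fit$data
  n <- nrow(dat)
  expect_lte(n, 60L)

  X <- model.matrix(fit$fixed_formula, dat)
  Z1 <- model.matrix(~ 0 + plate_group, dat)
  Z2 <- model.matrix(~ 0 + patient_id, dat)
  V <- fit$varcomps[["plate_group"]] * tcrossprod(Z1) +
    fit$varcomps[["patient_id"]] * tcrossprod(Z2) +
    fit$sigma2 * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  y <- dat$log2_response
  p <- ncol(X)
  oracle <- -0.5 * as.numeric(
    (n - p) * log(2 * pi) + determinant(V)$modulus +
      determinant(XtViX)$modulus + t(y) %*% P %*% y
  )
  expect_equal(fit$loglik, oracle, tolerance = 1e-6)

  # the optimum is a local maximum of the REML criterion in each variance
  reml_at <- function(v1, v2, s2) {
    V <- v1 * tcrossprod(Z1) + v2 * tcrossprod(Z2) + s2 * diag(n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    -0.5 * as.numeric((n - p) * log(2 * pi) + determinant(V)$modulus +
                        determinant(XtViX)$modulus + t(y) %*% P %*% y)
  }
  v <- c(fit$varcomps[["plate_group"]], fit$varcomps[["patient_id"]],
         fit$sigma2)
  for (i in 1:3) {
    up <- v; up[i] <- up[i] * 1.1
    dn <- v; dn[i] <- dn[i] * 0.9
    expect_lte(reml_at(up[1], up[2], up[3]), oracle + 1e-8)
    expect_lte(reml_at(dn[1], dn[2], dn[3]), oracle + 1e-8)
  }
})

test_that("omnibus Wald tests have df = levels - 1 and match an explicit oracle", {
  cfg <- recovery_config(n_analytes = 3L, seed = 19L)
  gen <- generate_dataset(cfg)
  fit <- fit_lmm(gen$data, "fluorescence", "global")
  a <- fit$xlevels$analyte[2L]
  omni <- omnibus_factor_test(fit, a, "tissue")
  expect_equal(omni$df, 3L)

  # independent construction of L from raw model-matrix rows
  tt <- delete.response(terms(fit$fixed_formula))
  grid <- expand.grid(tissue = fit$xlevels$tissue,
                      condition = fit$xlevels$condition,
                      stringsAsFactors = FALSE)
  grid$analyte <- a
  mm <- model.matrix(tt, grid, xlev = fit$xlevels)
  rows <- do.call(rbind, lapply(split(as.data.frame(mm), grid$tissue),
                                colMeans))
  L <- rows[-1, , drop = FALSE] - matrix(rows[1, ], nrow(rows) - 1L,
                                         ncol(rows), byrow = TRUE)
  est <- L %*% fit$beta
  chisq <- drop(t(est) %*% solve(L %*% fit$vcov_beta %*% t(L), est))
  expect_equal(omni$chisq, chisq, tolerance = 1e-8)

  # invariance to the reference level used in constructing L
  L2 <- rows[-2, , drop = FALSE] - matrix(rows[2, ], nrow(rows) - 1L,
                                          ncol(rows), byrow = TRUE)
  est2 <- L2 %*% fit$beta
  chisq2 <- drop(t(est2) %*% solve(L2 %*% fit$vcov_beta %*% t(L2), est2))
  expect_equal(chisq, chisq2, tolerance = 1e-8)
})

test_that("pairwise contrasts agree with adjusted-mean differences", {
  cfg <- recovery_config(n_analytes = 3L, seed = 23L)
  gen <- generate_dataset(cfg)
  fit <- fit_lmm(gen$data, "fluorescence", "global")
  pc <- pairwise_condition_contrasts(fit, reference = "Normal")
  expect_true(all(pc$df == 1L))
  expect_true(all(pc$p_holm >= pc$p_raw))
  for (a in fit$xlevels$analyte) {
    am <- adjusted_means(fit, a, "condition")
    for (cond in setdiff(fit$xlevels$condition, "Normal")) {
      v <- pc$value[pc$analyte == a & pc$contrast == paste0("Normal-", cond)]
      d <- am$estimate[am$level == "Normal"] - am$estimate[am$level == cond]
      expect_equal(v, d, tolerance = 1e-9)
    }
  }
  # balanced design with negligible random variation: adjusted means equal
  # raw cell means (GLS collapses to OLS and the design is orthogonal)
  cfg0 <- recovery_config(n_analytes = 3L, seed = 24L,
                          var_patient = 0, var_plategroup = 0)
  gen0 <- generate_dataset(cfg0)
  fit0 <- suppressWarnings(fit_lmm(gen0$data, "fluorescence", "global"))
  dat <- prepare_model_data(gen0$data, "fluorescence")
  a <- fit0$xlevels$analyte[1L]
  am <- adjusted_means(fit0, a, "tissue")
  raw <- tapply(dat$log2_response[dat$analyte == a],
                dat$tissue[dat$analyte == a], mean)
  expect_equal(unname(am$estimate), as.numeric(raw[am$level]), tolerance = 1e-6)
})

test_that("analytes dropped for concentration stay present for fluorescence", {
  cfg <- generator_config(n_analytes = 6L,
                          analyte_baselines = seq(2, 9, length.out = 6L),
                          seed = 2L)
  gen <- generate_dataset(cfg)
  target <- "gp130 (14)"
  low <- inject_low_abundance(gen$data, target, depth = 4)
  mapped <- map_dataset(low, fit_standard_curves(low))
  keep <- filter_estimable_analytes(mapped, "concentration")
  expect_true(target %in% keep$dropped)

  conc_ds <- dplyr::filter(mapped, !(.data$well_role == "sample" &
                                       .data$analyte %in% keep$dropped))
  fit_conc <- fit_lmm(conc_ds, "concentration", "global")
  pc <- pairwise_condition_contrasts(fit_conc,
                                     analytes = sort(unique(mapped$analyte)))
  expect_true(target %in% attr(pc, "missing_analytes"))
  expect_false(target %in% pc$analyte)

  fit_fl <- fit_lmm(mapped, "fluorescence", "global")
  pc_fl <- pairwise_condition_contrasts(fit_fl)
  expect_true(target %in% pc_fl$analyte)
})

test_that("model comparison is null for identical models and detects effects", {
  cfg <- recovery_config(n_analytes = 3L, seed = 33L)
  gen <- generate_dataset(cfg)
  g <- suppressWarnings(fit_lmm(gen$data, "fluorescence", "global"))
  r <- suppressWarnings(fit_lmm(gen$data, "fluorescence", "reduced"))

  self <- compare_models(g, g)
  expect_equal(self$chisq, 0)
  expect_equal(self$p, 1)

  cmp <- compare_models(r, g)
  expect_equal(cmp$df_diff, g$fixed_df - r$fixed_df)
  expect_lt(cmp$p, 0.05)  # generator draws real condition effects

  expect_error(compare_models(g, r), "not nested")
})

test_that("the likelihood-ratio comparison holds its type-I error without effects", {
  analytes3 <- c("April (42)", "Baff (37)", "CD163 (46)")
  zero_cond <- matrix(0, 3L, 4L,
                      dimnames = list(analytes3,
                                      c("Normal", "DiseaseA", "DiseaseB",
                                        "DiseaseC")))
  rej <- vapply(1:60, function(s) {
    cfg <- recovery_config(n_analytes = 3L, seed = 4000L + s,
                           condition_effects = zero_cond)
    gen <- generate_dataset(cfg)
    r <- suppressWarnings(fit_lmm(gen$data, "fluorescence", "reduced", "ml"))
    g <- suppressWarnings(fit_lmm(gen$data, "fluorescence", "global", "ml"))
    compare_models(r, g)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.15)
})

test_that("Holm adjustment steps down with monotonicity and a cap", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  set.seed(10)
  p <- runif(40)
  h <- holm_adjust(p)
  expect_true(all(h >= p))
  ord <- order(p)
  expect_true(all(diff(h[ord]) >= -1e-15))
})
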