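#' Fit the global or reduced mixed-effects differential model
#'
#' Fits a linear mixed model to the log2 responses of all analytes jointly.
#' The global model has three fixed main effects (analyte, tissue, condition)
#' plus the analyte:tissue and analyte:condition first-order interactions; the
#' reduced model omits condition and its interaction. Both carry the same two
#' crossed random intercepts: one on the Plate:Condition:Tissue group (tissues
#' and conditions associating across plates) and one on the patient
#' (patient-to-patient variation). The three-way analyte:tissue:condition
#' interaction is deliberately excluded: the design is sparse and higher-order
#' fixed interactions would overfit it.
#'
#' @param ds Plate table. Only sample wells are modelled; duplicate wells are
#'   averaged first unless `aggregate = FALSE`.
#' @param response `"fluorescence"` (complete by construction) or
#'   `"concentration"` (rows censored out of range are dropped; run
#'   [filter_estimable_analytes()] first so no design cell is emptied).
#' @param model `"global"` or `"reduced"`.
#' @param method `"reml"` (default, for variance components and Wald
#'   contrasts) or `"ml"` (for likelihood-ratio model comparison).
#' @param aggregate Average duplicate wells first (default TRUE).
#' @return An `lmm_fit` object: list with `beta` (fixed effects, log2 scale),
#'   `vcov_beta`, `sigma2` (residual variance), `varcomps` (named variances of
#'   the random intercepts), `loglik`, `aic`, `bic`, `n_obs`, `fixed_df`,
#'   `method`, `response`, `model_name`, the fitted [lme4::lmer] object in
#'   `$fit`, and the prepared model data in `$data`.
#' @export
fit_lmm <- function(ds,
                    response = c("fluorescence", "concentration"),
                    model = c("global", "reduced"),
                    method = c("reml", "ml"),
                    aggregate = TRUE) {
  response <- match.arg(response)
  model <- match.arg(model)
  method <- match.arg(method)
  dat <- prepare_model_data(ds, response = response, aggregate = aggregate)
  fixed_formula <- if (model == "global") {
    log2_response ~ analyte + tissue + condition +
      analyte:tissue + analyte:condition
  } else {
    log2_response ~ analyte + tissue + analyte:tissue
  }
  full_formula <- as.formula(paste(
    deparse1(fixed_formula), "+ (1 | plate_group) + (1 | patient_id)"
  ))

  mm <- model.matrix(fixed_formula, data = dat)
  if (qr(mm)$rank < ncol(mm)) {
    bad <- colnames(mm)[-seq_len(qr(mm)$rank)]
    stop("singular fixed-effect design; aliased term(s): ",
         paste(utils::head(bad, 8L), collapse = ", "),
         ". Run filter_estimable_analytes() first.", call. = FALSE)
  }

  fit <- lme4::lmer(full_formula, data = dat, REML = (method == "reml"),
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomps <- setNames(vc$vcov[vc$grp != "Residual"], vc$grp[vc$grp != "Residual"])
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  if (any(varcomps < 1e-10)) {
    warning("variance component pinned at 0 for: ",
            paste(names(varcomps)[varcomps < 1e-10], collapse = ", "),
            call. = FALSE)
  }
  beta <- lme4::fixef(fit)
  structure(
    list(
      fit = fit,
      beta = beta,
      vcov_beta = as.matrix(vcov(fit)),
      sigma2 = sigma2,
      varcomps = varcomps,
      loglik = as.numeric(logLik(fit)),
      aic = AIC(fit),
      bic = BIC(fit),
      n_obs = nrow(dat),
      fixed_df = length(beta),
      method = method,
      response = response,
      model_name = model,
      fixed_formula = fixed_formula,
      xlevels = lapply(dat[c("analyte", "tissue", "condition")], levels),
      data = dat
    ),
    class = "lmm_fit"
  )
}

#' Prepare sample-well model data
#'
#' Internal-facing helper (exported for scripting): filters to sample wells,
#' averages duplicates, builds the log2 response and the
#' Plate:Condition:Tissue grouping factor, and drops rows without a response
#' (censored concentrations).
#'
#' @inheritParams fit_lmm
#' @return Tibble with `log2_response`, factor columns `analyte`, `tissue`,
#'   `condition`, `plate_group`, `patient_id`.
#' @export
prepare_model_data <- function(ds,
                               response = c("fluorescence", "concentration"),
                               aggregate = TRUE) {
  response <- match.arg(response)
  ds <- tibble::as_tibble(ds)
  samples <- dplyr::filter(ds, .data$well_role == "sample")
  if (nrow(samples) == 0L) stop("no sample wells in dataset", call. = FALSE)
  if (aggregate) samples <- aggregate_duplicates(samples)
  samples <- dplyr::mutate(
    samples,
    log2_response = log2(.data[[response]]),
    plate_group = interaction(.data$plate, .data$condition, .data$tissue,
                              drop = TRUE, sep = ":")
  )
  samples <- samples[is.finite(samples$log2_response), ]
  dplyr::mutate(
    samples,
    analyte = factor(.data$analyte),
    tissue = factor(.data$tissue),
    condition = factor(.data$condition),
    patient_id = factor(.data$patient_id)
  )[c("log2_response", "analyte", "tissue", "condition", "plate_group",
      "patient_id")]
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s, %s response, %s)\n",
              x$model_name, x$response, toupper(x$method)))
  cat(sprintf("  n = %d observations, %d fixed-effect coefficients\n",
              x$n_obs, x$fixed_df))
  cat(sprintf("  logLik = %.2f  AIC = %.1f  BIC = %.1f\n",
              x$loglik, x$aic, x$bic))
  cat("  variance components (log2 scale):\n")
  for (nm in names(x$varcomps)) {
    cat(sprintf("    %-14s %.4f\n", nm, x$varcomps[[nm]]))
  }
  cat(sprintf("    %-14s %.4f\n", "residual", x$sigma2))
  invisible(x)
}

#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov_beta))
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = se,
    statistic = unname(x$beta) / se
  )
}

#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model_name, response = x$response, method = x$method,
    nobs = x$n_obs, fixed_df = x$fixed_df, logLik = x$loglik,
    AIC = x$aic, BIC = x$bic, sigma2 = x$sigma2,
    var_plate_group = unname(x$varcomps[["plate_group"]] %||% NA_real_),
    var_patient = unname(x$varcomps[["patient_id"]] %||% NA_real_)
  )
}

# Equal-weight reference-grid rows: one averaged model-matrix row per level of
# `factor`, holding `analyte` fixed and averaging over the other fixed factors.
.ref_grid_rows <- function(fit, analyte, factor) {
  stopifnot(inherits(fit, "lmm_fit"))
  vars <- all.vars(fit$fixed_formula)[-1L]
  if (!factor %in% vars) {
    stop("factor '", factor, "' is not in the fitted model", call. = FALSE)
  }
  if (!analyte %in% fit$xlevels$analyte) {
    stop("analyte '", analyte, "' was not in the fitted model ",
         "(dropped by the estimability filter?)", call. = FALSE)
  }
  levels_f <- fit$xlevels[[factor]]
  others <- setdiff(vars, c("analyte", factor))
  grid_other <- if (length(others)) {
    expand.grid(lapply(fit$xlevels[others], identity),
                stringsAsFactors = FALSE)
  } else {
    data.frame(row.names = 1L)
  }
  tt <- delete.response(terms(fit$fixed_formula))
  rows <- matrix(0, nrow = length(levels_f), ncol = length(fit$beta),
                 dimnames = list(levels_f, names(fit$beta)))
  for (i in seq_along(levels_f)) {
    nd <- grid_other[rep(seq_len(max(1L, nrow(grid_other))), 1L), , drop = FALSE]
    nd$analyte <- analyte
    nd[[factor]] <- levels_f[i]
    mm <- model.matrix(tt, data = nd, xlev = fit$xlevels)
    rows[i, colnames(mm)] <- colMeans(mm)
  }
  rows
}

.wald_quadform <- function(L, beta, vcov_beta) {
  est <- drop(L %*% beta)
  v <- L %*% vcov_beta %*% t(L)
  qr_v <- qr(v)
  if (qr_v$rank < nrow(v)) {
    stop("rank-deficient contrast matrix", call. = FALSE)
  }
  drop(t(est) %*% solve(v, est))
}

#' Omnibus Wald test of a factor within one analyte
#'
#' Tests whether any level of `factor` (tissue or condition) differs from any
#' other for the given analyte, combining the factor's main effect with its
#' analyte interaction: the Wald chi-square \eqn{(L\beta)^T (L V L^T)^{-1}
#' (L\beta)} where the rows of L are the adjusted-mean differences of each
#' level against the first. df = levels - 1 (3 for four tissues). The
#' statistic is invariant to the choice of reference level.
#'
#' @param fit An `lmm_fit`.
#' @param analyte Analyte label.
#' @param factor `"tissue"` or `"condition"`.
#' @return Tibble with `analyte`, `factor`, `chisq`, `df`, `p_raw`.
#' @export
omnibus_factor_test <- function(fit, analyte, factor = c("tissue", "condition")) {
  factor <- match.arg(factor)
  rows <- .ref_grid_rows(fit, analyte, factor)
  L <- rows[-1L, , drop = FALSE] - rep(1, nrow(rows) - 1L) %o% rows[1L, ]
  chisq <- .wald_quadform(L, fit$beta, fit$vcov_beta)
  df <- nrow(L)
  tibble::tibble(
    analyte = analyte, factor = factor, chisq = chisq, df = df,
    p_raw = pchisq(chisq, df, lower.tail = FALSE)
  )
}

#' Omnibus table across all analytes with Holm correction
#'
#' One omnibus Wald test per retained analyte (the Table-2-style output), with
#' Holm adjustment over the whole emitted table.
#'
#' @inheritParams omnibus_factor_test
#' @param analytes Analytes to test (default: all in the fit).
#' @return Tibble `analyte`, `factor`, `chisq`, `df`, `p_raw`, `p_holm`.
#' @export
omnibus_table <- function(fit, factor = c("tissue", "condition"),
                          analytes = NULL) {
  factor <- match.arg(factor)
  analytes <- analytes %||% fit$xlevels$analyte
  out <- purrr::map(analytes, function(a) omnibus_factor_test(fit, a, factor)) |>
    dplyr::bind_rows()
  out$p_holm <- holm_adjust(out$p_raw)
  out
}

#' Pairwise condition contrasts against a reference
#'
#' One single-df Wald test per analyte and non-reference condition, on the
#' adjusted-mean difference reference minus other (so "Normal-Mono" < 0 means
#' higher in mononucleosis). Holm adjustment spans the whole emitted table.
#' Analytes absent from the fit (dropped by the estimability filter) are
#' reported as missing rows via the `missing_analytes` attribute.
#'
#' @param fit An `lmm_fit` including `condition` among its fixed effects.
#' @param reference Reference condition level (default `"Normal"`).
#' @param analytes Analytes to test; defaults to all in the fit. Requested
#'   analytes not in the fit are recorded as missing.
#' @return Tibble `analyte`, `contrast`, `value`, `chisq`, `df`, `p_raw`,
#'   `p_holm`, with attribute `missing_analytes`.
#' @export
pairwise_condition_contrasts <- function(fit, reference = "Normal",
                                         analytes = NULL) {
  if (!"condition" %in% all.vars(fit$fixed_formula)) {
    stop("fit has no condition fixed effect (reduced model?)", call. = FALSE)
  }
  requested <- analytes %||% fit$xlevels$analyte
  present <- intersect(requested, fit$xlevels$analyte)
  missing_analytes <- setdiff(requested, present)
  conditions <- fit$xlevels$condition
  if (!reference %in% conditions) {
    stop("reference level '", reference, "' not among conditions", call. = FALSE)
  }
  others <- setdiff(conditions, reference)
  out <- purrr::map(present, function(a) {
    rows <- .ref_grid_rows(fit, a, "condition")
    purrr::map(others, function(cond) {
      L <- rows[reference, , drop = FALSE] - rows[cond, , drop = FALSE]
      value <- drop(L %*% fit$beta)
      v <- drop(L %*% fit$vcov_beta %*% t(L))
      chisq <- value^2 / v
      tibble::tibble(
        analyte = a, contrast = paste(reference, cond, sep = "-"),
        value = value, se = sqrt(v), chisq = chisq, df = 1L,
        p_raw = pchisq(chisq, 1L, lower.tail = FALSE)
      )
    }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
  out$p_holm <- holm_adjust(out$p_raw)
  attr(out, "missing_analytes") <- missing_analytes
  out
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down Holm correction with monotonicity enforcement, capped at 1; the
#' family is whatever vector is passed, i.e. all rows of the emitted table.
#'
#' @param p_raw Raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.04 0.04
holm_adjust <- function(p_raw) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1, na.rm = TRUE))
  p.adjust(p_raw, method = "holm")
}

#' Adjusted (marginal) factor-level means for one analyte
#'
#' Model-based mean of each level of `factor` for the given analyte, averaging
#' the other fixed factors with equal level weights, with normal-quantile 95%
#' intervals from the fixed-effect covariance. The difference of two adjusted
#' means equals the corresponding pairwise contrast value exactly.
#'
#' @inheritParams omnibus_factor_test
#' @param level Confidence level (default 0.95).
#' @return Tibble `analyte`, `factor`, `level`, `estimate`, `se`, `conf_low`,
#'   `conf_high` (log2 scale).
#' @export
adjusted_means <- function(fit, analyte, factor = c("tissue", "condition"),
                           level = 0.95) {
  factor <- match.arg(factor)
  rows <- .ref_grid_rows(fit, analyte, factor)
  est <- drop(rows %*% fit$beta)
  se <- sqrt(diag(rows %*% fit$vcov_beta %*% t(rows)))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    analyte = analyte, factor = factor, level = rownames(rows),
    estimate = est, se = se,
    conf_low = est - z * se, conf_high = est + z * se
  )
}

#' Compare nested mixed models by likelihood ratio
#'
#' Refits both models by full maximum likelihood (REML likelihoods are not
#' comparable across fixed-effect structures) and reports the likelihood-ratio
#' chi-square for the global model against the reduced one, with AIC/BIC from
#' the ML fits. The models must be nested and fitted to the same rows.
#'
#' @param reduced,global `lmm_fit` objects from [fit_lmm()] on the same data
#'   and response.
#' @return Tibble with `aic_reduced`, `aic_global`, `bic_reduced`,
#'   `bic_global`, `chisq`, `df_diff`, `p`.
#' @export
compare_models <- function(reduced, global) {
  stopifnot(inherits(reduced, "lmm_fit"), inherits(global, "lmm_fit"))
  terms_r <- attr(terms(reduced$fixed_formula), "term.labels")
  terms_g <- attr(terms(global$fixed_formula), "term.labels")
  if (!all(terms_r %in% terms_g)) {
    stop("models are not nested: reduced fixed terms must be a subset of ",
         "the global model's", call. = FALSE)
  }
  if (reduced$n_obs != global$n_obs || reduced$response != global$response) {
    stop("models must be fitted to the same rows and response", call. = FALSE)
  }
  ml_r <- if (reduced$method == "ml") reduced$fit else lme4::refitML(reduced$fit)
  ml_g <- if (global$method == "ml") global$fit else lme4::refitML(global$fit)
  ll_r <- as.numeric(logLik(ml_r))
  ll_g <- as.numeric(logLik(ml_g))
  df_diff <- global$fixed_df - reduced$fixed_df
  chisq <- max(0, 2 * (ll_g - ll_r))
  tibble::tibble(
    aic_reduced = AIC(ml_r), aic_global = AIC(ml_g),
    bic_reduced = BIC(ml_r), bic_global = BIC(ml_g),
    loglik_reduced = ll_r, loglik_global = ll_g,
    chisq = chisq, df_diff = df_diff,
    p = if (df_diff > 0) pchisq(chisq, df_diff, lower.tail = FALSE) else 1
  )
}
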