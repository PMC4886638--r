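#' Five-parameter logistic response curve
#'
#' The 5PL curve used throughout immunoassay standard-curve fitting,
#' parameterised as
#' \deqn{f(x) = bottom + \frac{top - bottom}{(1 + (x/ec50)^{-hill})^{asym}}}
#' with `hill > 0` giving a strictly increasing response in concentration `x`.
#' `f(0) = bottom`, `f(Inf) = top`, and with `asym = 1` the curve is the
#' symmetric 4PL with `f(ec50)` at the midpoint.
#'
#' @param conc Concentration(s), pg/ml, `>= 0`.
#' @param bottom,top Lower/upper fluorescence asymptotes (`bottom < top`).
#' @param ec50 Concentration of half-maximal response (pg/ml, `> 0`).
#' @param hill Slope factor (`> 0`).
#' @param asym Asymmetry exponent (`> 0`; 1 recovers the 4PL).
#' @return Fluorescence value(s).
#' @export
#' @examples
#' fivepl(100, bottom = 50, top = 20000, ec50 = 100, hill = 1.2, asym = 1)
fivepl <- function(conc, bottom, top, ec50, hill, asym = 1) {
  stopifnot(bottom < top, ec50 > 0, hill > 0, asym > 0)
  if (any(conc < 0, na.rm = TRUE)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  u <- (conc / ec50)^(-hill)          # Inf at conc = 0 -> f = bottom
  bottom + (top - bottom) / (1 + u)^asym
}

#' Invert the 5PL curve
#'
#' Closed-form inverse of [fivepl()]:
#' `x = ec50 * (((top - bottom)/(fl - bottom))^(1/asym) - 1)^(-1/hill)`.
#' Defined for fluorescence strictly between the asymptotes.
#'
#' @inheritParams fivepl
#' @param fl Fluorescence value(s).
#' @return Concentration(s); `NA` where `fl` is at or outside the asymptotes.
#' @export
fivepl_inverse <- function(fl, bottom, top, ec50, hill, asym = 1) {
  stopifnot(bottom < top, ec50 > 0, hill > 0, asym > 0)
  out <- rep(NA_real_, length(fl))
  ok <- is.finite(fl) & fl > bottom & fl < top
  r <- ((top - bottom) / (fl[ok] - bottom))^(1 / asym) - 1
  out[ok] <- ec50 * r^(-1 / hill)
  out
}

.fivepl_rss <- function(par, conc, fl, weights) {
  pred <- fivepl(conc, par[1L], par[2L], exp(par[3L]), exp(par[4L]), exp(par[5L]))
  sum(weights * (fl - pred)^2)
}

#' Fit a weighted 5PL standard curve
#'
#' Weighted least-squares fit of the five-parameter logistic to a standard
#' series. The default weighting, `1/response^2`, equalises the relative
#' (percent-CV) error across the curve, which is how multiplex kit software
#' weights its standard fits; `replicate_variance` weights each concentration
#' level by the inverse of its replicate variance, and `none` is ordinary
#' least squares.
#'
#' Optimisation is multi-start Levenberg-Marquardt ([minpack.lm::nlsLM]) with
#' `ec50`, `hill` and `asym` log-parameterised (the 5PL is ill-conditioned for
#' extreme asymmetry). Starts combine a heuristic 4PL-style initialisation
#' (`asym = 1`) with a small grid of asymmetry values; the best converged
#' candidate by weighted RSS is kept.
#'
#' @param standards Data frame with columns `conc` (pg/ml, `> 0`) and
#'   `fluorescence`; replicate rows per level are expected.
#' @param weight_mode `"inverse_response_squared"` (default),
#'   `"replicate_variance"` or `"none"`.
#' @param blank_fl Optional blank fluorescence readings; when supplied the
#'   fit's LOD fields are filled via [lod_from_blanks()].
#' @param lod_k Blank-sd multiplier passed to [lod_from_blanks()].
#' @return A `fivepl_fit` object: list with `bottom`, `top`, `ec50`, `hill`,
#'   `asym`, `weight_mode`, `standards_fl_range`, `lod_fl`, `lod_conc`, `rss`,
#'   `convergence` and a `recovery` tibble of back-calculated standards
#'   (back-calculated conc / nominal conc per level).
#' @export
fit_5pl <- function(standards,
                    weight_mode = c("inverse_response_squared",
                                    "replicate_variance", "none"),
                    blank_fl = NULL, lod_k = 2) {
  weight_mode <- match.arg(weight_mode)
  standards <- tibble::as_tibble(standards)
  stopifnot(all(c("conc", "fluorescence") %in% names(standards)))
  conc <- standards$conc
  fl <- standards$fluorescence
  if (any(conc <= 0)) stop("standard concentrations must be strictly positive",
                           call. = FALSE)
  if (length(unique(conc)) < 5L) {
    stop("need at least 5 distinct concentration levels to fit a 5PL",
         call. = FALSE)
  }
  weights <- switch(
    weight_mode,
    none = rep(1, length(fl)),
    inverse_response_squared = 1 / fl^2,
    replicate_variance = {
      v <- tapply(fl, conc, function(x) if (length(x) > 1L) var(x) else NA_real_)
      v[!is.finite(v) | v <= 0] <- median(v[is.finite(v) & v > 0]) %||% 1
      1 / as.numeric(v[as.character(conc)])
    }
  )

  span <- max(fl) - min(fl)
  bottom0 <- min(fl) - 0.05 * span
  top0 <- max(fl) + 0.05 * span
  mid <- (min(fl) + max(fl)) / 2
  ec50_0 <- conc[which.min(abs(fl - mid))]
  starts <- expand.grid(asym = c(0.5, 1, 2), hill = c(0.7, 1, 1.5))

  dat <- data.frame(conc = conc, fl = fl, w = weights)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(bottom = bottom0, top = top0, lec50 = log(ec50_0),
               lhill = log(starts$hill[i]), lasym = log(starts$asym[i]))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fl ~ fivepl(conc, bottom, top, exp(lec50), exp(lhill), exp(lasym)),
        data = dat, start = st, weights = dat$w,
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(weights * resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("5PL fit failed to converge from any start", call. = FALSE)
  }
  p <- coef(best$fit)
  out <- structure(
    list(
      bottom = unname(p["bottom"]), top = unname(p["top"]),
      ec50 = exp(unname(p["lec50"])), hill = exp(unname(p["lhill"])),
      asym = exp(unname(p["lasym"])),
      weight_mode = weight_mode,
      standards_fl_range = range(fl),
      lod_fl = NA_real_, lod_conc = NA_real_, lod_k = lod_k,
      rss = best$rss, convergence = TRUE
    ),
    class = "fivepl_fit"
  )
  if (out$bottom >= out$top) stop("degenerate 5PL fit: bottom >= top", call. = FALSE)
  level_means <- tapply(fl, conc, mean)
  nominal <- as.numeric(names(level_means))
  back <- fivepl_inverse(as.numeric(level_means), out$bottom, out$top,
                         out$ec50, out$hill, out$asym)
  out$recovery <- tibble::tibble(
    conc = nominal,
    back_calculated = back,
    recovery = back / nominal
  )
  if (!is.null(blank_fl)) {
    lod <- lod_from_blanks(out, blank_fl, k = lod_k)
    out$lod_fl <- lod$lod_fl
    out$lod_conc <- lod$lod_conc
  }
  out
}

#' @export
print.fivepl_fit <- function(x, ...) {
  cat("5PL standard-curve fit (", x$weight_mode, " weighting)\n", sep = "")
  cat(sprintf("  bottom %.4g  top %.4g  ec50 %.4g  hill %.4g  asym %.4g\n",
              x$bottom, x$top, x$ec50, x$hill, x$asym))
  cat(sprintf("  standards fluorescence range: [%.4g, %.4g]\n",
              x$standards_fl_range[1L], x$standards_fl_range[2L]))
  if (is.finite(x$lod_fl)) {
    cat(sprintf("  LOD: %.4g fluorescence units (%s pg/ml)\n", x$lod_fl,
                if (is.finite(x$lod_conc)) sprintf("%.4g", x$lod_conc) else "censored"))
  }
  invisible(x)
}

#' Predict fluorescence from a fitted 5PL curve
#' @param object A `fivepl_fit`.
#' @param conc Concentrations, pg/ml.
#' @param ... Unused.
#' @return Fluorescence values.
#' @export
predict.fivepl_fit <- function(object, conc, ...) {
  fivepl(conc, object$bottom, object$top, object$ec50, object$hill, object$asym)
}

#' @method tidy fivepl_fit
#' @export
tidy.fivepl_fit <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "ec50", "hill", "asym"),
    estimate = c(x$bottom, x$top, x$ec50, x$hill, x$asym)
  )
}

#' @method glance fivepl_fit
#' @export
glance.fivepl_fit <- function(x, ...) {
  tibble::tibble(
    weight_mode = x$weight_mode, rss = x$rss,
    fl_min = x$standards_fl_range[1L], fl_max = x$standards_fl_range[2L],
    lod_fl = x$lod_fl, lod_conc = x$lod_conc
  )
}

#' Map fluorescence to concentration with censoring classification
#'
#' Inverts a fitted 5PL curve at each fluorescence value and classifies the
#' result: `in_range` when the fluorescence lies within the span of the fitted
#' standards, `extrapolated` when outside the standards' span but strictly
#' between the curve's asymptotes (the extrapolated values multiplex software
#' can still report), and `oor_low`/`oor_high` at or beyond the asymptotes,
#' where no concentration exists.
#'
#' @param fit A `fivepl_fit`.
#' @param fl Fluorescence values.
#' @return Tibble with columns `fluorescence`, `concentration` (`NA` when out
#'   of range) and `censor_status`.
#' @export
inverse_5pl <- function(fit, fl) {
  stopifnot(inherits(fit, "fivepl_fit"))
  conc <- fivepl_inverse(fl, fit$bottom, fit$top, fit$ec50, fit$hill, fit$asym)
  lo <- fit$standards_fl_range[1L]
  hi <- fit$standards_fl_range[2L]
  status <- dplyr::case_when(
    fl <= fit$bottom ~ "oor_low",
    fl >= fit$top ~ "oor_high",
    fl >= lo & fl <= hi ~ "in_range",
    .default = "extrapolated"
  )
  tibble::tibble(fluorescence = fl, concentration = conc, censor_status = status)
}

#' Limit of detection from blank wells
#'
#' The fluorescence LOD is `mean(blanks) + k * sd(blanks)`; its concentration
#' image is obtained through the inverse 5PL and is absent when the LOD
#' fluorescence itself falls below the curve's lower asymptote.
#'
#' @param fit A `fivepl_fit`.
#' @param blank_fl At least two blank fluorescence readings.
#' @param k Blank-sd multiplier (default 2).
#' @return List with `lod_fl`, `lod_conc` (`NA` when censored) and `status`.
#' @export
lod_from_blanks <- function(fit, blank_fl, k = 2) {
  if (length(blank_fl) < 2L) {
    stop("need at least 2 blank readings to estimate an LOD", call. = FALSE)
  }
  lod_fl <- mean(blank_fl) + k * sd(blank_fl)
  mapped <- inverse_5pl(fit, lod_fl)
  list(lod_fl = lod_fl, lod_conc = mapped$concentration[1L],
       status = mapped$censor_status[1L])
}

#' Fit standard curves for every analyte x plate
#'
#' Convenience wrapper that fits one weighted 5PL per (analyte, plate) from the
#' standard wells of a plate table, using that analyte/plate's blank wells for
#' the LOD.
#'
#' @param ds Plate table containing standard (and ideally blank) wells.
#' @inheritParams fit_5pl
#' @return Named list of `fivepl_fit` objects, names `"analyte|plate"`.
#' @export
fit_standard_curves <- function(ds,
                                weight_mode = c("inverse_response_squared",
                                                "replicate_variance", "none"),
                                lod_k = 2) {
  weight_mode <- match.arg(weight_mode)
  ds <- tibble::as_tibble(ds)
  std <- dplyr::filter(ds, .data$well_role == "standard")
  if (nrow(std) == 0L) stop("no standard wells in dataset", call. = FALSE)
  blanks <- dplyr::filter(ds, .data$well_role == "blank")
  keys <- dplyr::distinct(std, .data$analyte, .data$plate)
  fits <- purrr::pmap(keys, function(analyte, plate) {
    s <- std[std$analyte == analyte & std$plate == plate, ]
    b <- blanks$fluorescence[blanks$analyte == analyte & blanks$plate == plate]
    fit_5pl(
      tibble::tibble(conc = s$concentration, fluorescence = s$fluorescence),
      weight_mode = weight_mode,
      blank_fl = if (length(b) >= 2L) b else NULL,
      lod_k = lod_k
    )
  })
  names(fits) <- paste(keys$analyte, keys$plate, sep = "|")
  fits
}

#' Fill concentrations and censor statuses from fitted curves
#'
#' Applies [inverse_5pl()] to every sample well using that well's
#' (analyte, plate) curve. The fluorescence column is never altered, and every
#' sample record ends with a definite censor status; a concentration is
#' present exactly for `in_range` and `extrapolated` wells. Standards and
#' blanks pass through unchanged.
#'
#' @param ds Plate table.
#' @param fits Named list from [fit_standard_curves()] (names `"analyte|plate"`).
#' @return Plate table with `concentration` and `censor_status` filled on
#'   sample wells.
#' @export
map_dataset <- function(ds, fits) {
  ds <- tibble::as_tibble(ds)
  is_sample <- ds$well_role == "sample"
  keys <- unique(paste(ds$analyte[is_sample], ds$plate[is_sample], sep = "|"))
  missing_fits <- setdiff(keys, names(fits))
  if (length(missing_fits)) {
    stop("no standard-curve fit for: ", paste(missing_fits, collapse = ", "),
         call. = FALSE)
  }
  idx <- which(is_sample)
  key <- paste(ds$analyte[idx], ds$plate[idx], sep = "|")
  for (k in unique(key)) {
    rows <- idx[key == k]
    mapped <- inverse_5pl(fits[[k]], ds$fluorescence[rows])
    ds$concentration[rows] <- mapped$concentration
    ds$censor_status[rows] <- mapped$censor_status
  }
  ds
}
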