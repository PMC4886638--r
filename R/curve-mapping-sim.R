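#' Normalized sigmoid response curve and its inverse
#'
#' The simulation's concentration-response curve with the EC50 at 0 on the
#' log2 concentration axis: `f(x) = 1 / (1 + 2^(-slope * x))`, strictly
#' increasing from 0 to 1 with `f(0) = 0.5`. [inverse_sigmoid()] maps a
#' normalized fluorescence response in (0, 1) back to the log2 concentration
#' position, `x = log2(p / (1 - p)) / slope`; responses at or outside (0, 1)
#' are unmappable and return `NA` (the simulation's censoring).
#'
#' @param x Log2 concentration position(s).
#' @param slope Sigmoid steepness (default 1).
#' @return Response level(s) in (0, 1).
#' @export
#' @examples
#' normalized_sigmoid(0)          # 0.5
#' inverse_sigmoid(0.05)          # -log2(19)
normalized_sigmoid <- function(x, slope = 1) {
  1 / (1 + 2^(-slope * x))
}

#' @rdname normalized_sigmoid
#' @param p Normalized response level(s).
#' @export
inverse_sigmoid <- function(p, slope = 1) {
  out <- rep(NA_real_, length(p))
  ok <- is.finite(p) & p > 0 & p < 1
  out[ok] <- log2(p[ok] / (1 - p[ok])) / slope
  out
}

#' Draw from a centred skew-normal distribution
#'
#' Samples the skew-normal with shape `alpha` via the delta representation
#' (`Z = delta * |U0| + sqrt(1 - delta^2) * U1`, `delta =
#' alpha / sqrt(1 + alpha^2)`), then recentres and rescales so the population
#' mean is exactly `location` and the population sd exactly `scale` (the
#' centred parameterisation). `alpha = 0` reduces to the normal distribution.
#'
#' @param n Number of draws.
#' @param location Population mean of the output.
#' @param scale Population sd of the output (> 0).
#' @param alpha Shape: 0 symmetric, negative left-skewed, positive
#'   right-skewed.
#' @param seed Optional integer seed for reproducible draws.
#' @return Numeric vector of length `n`.
#' @export
sample_skew_normal <- function(n, location = 0, scale = 1, alpha = 0,
                               seed = NULL) {
  stopifnot(scale > 0)
  if (!is.null(seed)) set.seed(seed)
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n)
  u1 <- rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  mu_z <- delta * sqrt(2 / pi)
  sd_z <- sqrt(1 - 2 * delta^2 / pi)
  location + scale * (z - mu_z) / sd_z
}

#' Population skewness of the skew-normal
#' @param alpha Shape parameter.
#' @return The closed-form skewness.
#' @export
skew_normal_skewness <- function(alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  b <- delta * sqrt(2 / pi)
  (4 - pi) / 2 * b^3 / (1 - b^2)^1.5
}

#' Sample skewness (method-of-moments)
#' @param x Numeric vector (>= 3 values).
#' @return `m3 / m2^(3/2)` with central moments `m2`, `m3`.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  stopifnot(length(x) >= 3L)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

#' Group separation for a target Cohen's d
#'
#' With equal-sd groups, the mean separation achieving a standardized effect
#' size `cohen_d` is simply `cohen_d * sd_fl`.
#'
#' @param sd_fl Common group sd on the normalized fluorescence scale.
#' @param cohen_d Target effect size (default 0.8, the conventional "large"
#'   effect).
#' @return Separation of the group means, same units as `sd_fl`.
#' @export
calibrate_separation <- function(sd_fl, cohen_d = 0.8) {
  stopifnot(sd_fl > 0)
  cohen_d * sd_fl
}

#' Two-sample t-test
#'
#' Standard two-sided two-sample t-test, pooled-variance by default (the
#' simulator's groups share their sd by construction) with Welch available.
#' Exactly translation invariant: adding any constant to both groups leaves
#' (t, df, p) unchanged, which is why fluorescence-scale tests need no
#' background subtraction.
#'
#' @param x,y Numeric vectors (>= 3 values each).
#' @param variant `"pooled"` or `"welch"`.
#' @return Tibble with `t`, `df`, `p`, `degenerate` (TRUE when the pooled
#'   variance is zero and the statistic is undefined).
#' @export
two_sample_ttest <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 3L, length(y) >= 3L)
  res <- tryCatch(
    t.test(x, y, var.equal = (variant == "pooled")),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                          degenerate = TRUE))
  }
  tibble::tibble(t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, degenerate = FALSE)
}

#' Map normalized responses to the concentration scale
#'
#' Pushes normalized fluorescence responses through the inverse sigmoid to
#' log2 concentration positions; responses outside (0, 1) are unmappable and
#' dropped (censored). `conc_scale = "log2"` returns the log2 pg/ml positions
#' (the scale on which the package models responses); `"natural"` returns
#' `2^x` pg/ml.
#'
#' @param responses Normalized fluorescence responses.
#' @param slope Sigmoid steepness.
#' @param conc_scale `"log2"` or `"natural"`.
#' @return List with `conc` (mapped values) and `n_dropped`.
#' @export
map_to_concentration <- function(responses, slope = 1,
                                 conc_scale = c("log2", "natural")) {
  conc_scale <- match.arg(conc_scale)
  x <- inverse_sigmoid(responses, slope)
  dropped <- sum(is.na(x))
  x <- x[!is.na(x)]
  list(conc = if (conc_scale == "natural") 2^x else x, n_dropped = dropped)
}

#' Summarise a mapped concentration distribution
#'
#' Moments of the concentration image of a normalized response sample, plus
#' the image of the input mean ("expected mean"): the systematic gap between
#' the mapped mean and the image of the input mean is the mapping bias that
#' grows away from the EC50.
#'
#' @inheritParams map_to_concentration
#' @return Tibble with `mean`, `sd`, `skewness`, `n`, `n_dropped`,
#'   `expected_mean`.
#' @export
distribution_summary <- function(responses, slope = 1,
                                 conc_scale = c("log2", "natural")) {
  conc_scale <- match.arg(conc_scale)
  mapped <- map_to_concentration(responses, slope, conc_scale)
  stopifnot(length(mapped$conc) >= 3L)
  img <- inverse_sigmoid(mean(responses), slope)
  if (conc_scale == "natural" && is.finite(img)) img <- 2^img
  tibble::tibble(
    mean = mean(mapped$conc), sd = sd(mapped$conc),
    skewness = sample_skewness(mapped$conc),
    n = length(mapped$conc), n_dropped = mapped$n_dropped,
    expected_mean = img
  )
}

#' Translation scan of fluorescence- vs concentration-scale t-tests
#'
#' The package's core simulation. One seeded pair of group samples (A, B) is
#' drawn on the normalized fluorescence-response scale, separated by
#' `cohen_d * sd_fl`, and then *translated* so the pair's midpoint visits each
#' response level of `level_grid`. At every step a two-sample t-test is run on
#' the fluorescence responses (`p_fl`; exactly constant across the scan, the
#' translation-invariance identity) and on their concentration images after
#' the inverse-sigmoid mapping (`p_conc`; responses outside (0, 1) are
#' censored and reduce the test's df). Reusing one fixed draw across the scan
#' is what makes the fluorescence constancy exact rather than statistical;
#' `redraw = TRUE` instead draws fresh samples at every step.
#'
#' @param n_per_group Samples per group (default 100).
#' @param sd_fl Group sd in normalized response units (default 0.02: the input
#'   distributions are narrow relative to the curve's unit span, so that even
#'   at the extreme scan levels only an occasional draw is unmappable).
#' @param skew_alpha Skew-normal shape of the input distributions (0, -5, 5
#'   are the canonical settings).
#' @param cohen_d Target effect size (default 0.8).
#' @param level_grid Response levels to visit (default 0.05 to 0.95 by 0.01).
#' @param slope Sigmoid steepness (default 1).
#' @param seed Integer seed.
#' @param conc_scale Scale for the concentration t-test: `"log2"` (default)
#'   or `"natural"`.
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @param redraw Redraw the samples at every level instead of translating one
#'   fixed pair.
#' @return A `sim_scan` tibble: `level`, `p_fl`, `p_conc` (`NA` when fewer
#'   than 3 mappable values remain in a group), `n_dropped_a`, `n_dropped_b`,
#'   `sd_conc_a`, `sd_conc_b`, `skew_conc_a`, `skew_conc_b`.
#' @export
translation_scan <- function(n_per_group = 100L, sd_fl = 0.02, skew_alpha = 0,
                             cohen_d = 0.8,
                             level_grid = seq(0.05, 0.95, by = 0.01),
                             slope = 1, seed = 1L,
                             conc_scale = c("log2", "natural"),
                             variant = c("pooled", "welch"),
                             redraw = FALSE) {
  conc_scale <- match.arg(conc_scale)
  variant <- match.arg(variant)
  stopifnot(n_per_group >= 3L, sd_fl > 0,
            all(level_grid > 0 & level_grid < 1))
  delta <- calibrate_separation(sd_fl, cohen_d)
  set.seed(seed)
  draw_pair <- function() {
    list(
      a = sample_skew_normal(n_per_group, -delta / 2, sd_fl, skew_alpha),
      b = sample_skew_normal(n_per_group, +delta / 2, sd_fl, skew_alpha)
    )
  }
  base <- draw_pair()
  rows <- purrr::map(level_grid, function(lv) {
    pair <- if (redraw) draw_pair() else base
    ya <- pair$a + lv
    yb <- pair$b + lv
    p_fl <- two_sample_ttest(ya, yb, variant)$p
    ma <- map_to_concentration(ya, slope, conc_scale)
    mb <- map_to_concentration(yb, slope, conc_scale)
    enough <- length(ma$conc) >= 3L && length(mb$conc) >= 3L
    tibble::tibble(
      level = lv,
      p_fl = p_fl,
      p_conc = if (enough) two_sample_ttest(ma$conc, mb$conc, variant)$p
               else NA_real_,
      n_dropped_a = ma$n_dropped, n_dropped_b = mb$n_dropped,
      sd_conc_a = if (length(ma$conc) >= 2L) sd(ma$conc) else NA_real_,
      sd_conc_b = if (length(mb$conc) >= 2L) sd(mb$conc) else NA_real_,
      skew_conc_a = if (length(ma$conc) >= 3L) sample_skewness(ma$conc)
                    else NA_real_,
      skew_conc_b = if (length(mb$conc) >= 3L) sample_skewness(mb$conc)
                    else NA_real_
    )
  }) |>
    dplyr::bind_rows()
  structure(rows,
            class = c("sim_scan", class(rows)),
            skew_alpha = skew_alpha, n_per_group = n_per_group,
            sd_fl = sd_fl, cohen_d = cohen_d, conc_scale = conc_scale,
            seed = seed)
}
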