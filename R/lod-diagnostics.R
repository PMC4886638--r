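#' Balanced neighbourhood around a detection limit
#'
#' Selects the N nearest responses above and the N nearest below a
#' fluorescence LOD, where N is the smaller of the two side counts, so that
#' point scatter can be compared on equal sample sizes. Values exactly at the
#' LOD count as "above". Ties in distance are broken by the smaller value
#' first, then input order, making the selection deterministic and invariant
#' to input ordering.
#'
#' @param responses Fluorescence values.
#' @param lod_fl Fluorescence detection limit.
#' @return List with `above`, `below` (each length N, nearest first),
#'   `n_selected` (N), and the observed side counts `n_above`, `n_below`.
#' @export
balanced_neighborhood <- function(responses, lod_fl) {
  responses <- responses[is.finite(responses)]
  if (length(responses) == 0L) stop("no responses supplied", call. = FALSE)
  above <- responses[responses >= lod_fl]
  below <- responses[responses < lod_fl]
  n <- min(length(above), length(below))
  pick <- function(x) {
    if (n == 0L) return(numeric())
    ord <- order(abs(x - lod_fl), x)
    x[ord][seq_len(n)]
  }
  list(above = pick(above), below = pick(below), n_selected = n,
       n_above = length(above), n_below = length(below))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, on the
#' raw scale: the standardised point-scatter measure used for the
#' above/below-LOD comparison. Scale invariant: `cv(c * x) = cv(x)` for c > 0.
#'
#' @param values At least two values with a strictly positive mean.
#' @return The CV, dimensionless.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 0.5
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be strictly positive for a CV", call. = FALSE)
  sd(values) / m
}

#' Variance-ratio test for equality of two CVs
#'
#' Equality of two coefficients of variation is tested as equality of
#' variances of the log-transformed data: a two-sided F test on
#' `var(log2(above)) / var(log2(below))` with the p-value doubled from the
#' smaller tail (capped at 1). The p-value is invariant to rescaling either
#' side by a positive constant.
#'
#' @param above,below Fluorescence values on each side of the LOD (>= 2 each).
#' @return Tibble with `cv_above`, `cv_below`, `ratio`, `f_statistic`, `df1`,
#'   `df2`, `f_pvalue` (NA with a `degenerate` flag when either side has zero
#'   log-variance).
#' @export
cv_ratio_test <- function(above, below) {
  stopifnot(length(above) >= 2L, length(below) >= 2L)
  cv_a <- coefficient_of_variation(above)
  cv_b <- coefficient_of_variation(below)
  va <- var(log2(above))
  vb <- var(log2(below))
  degenerate <- va <= 0 || vb <= 0
  if (degenerate) {
    f <- NA_real_
    p <- NA_real_
  } else {
    f <- va / vb
    df1 <- length(above) - 1L
    df2 <- length(below) - 1L
    p <- min(1, 2 * min(pf(f, df1, df2), pf(f, df1, df2, lower.tail = FALSE)))
  }
  tibble::tibble(
    cv_above = cv_a, cv_below = cv_b, ratio = cv_a / cv_b,
    f_statistic = f, df1 = length(above) - 1L, df2 = length(below) - 1L,
    f_pvalue = p, degenerate = degenerate
  )
}

#' Above/below-LOD CV comparison table
#'
#' For each analyte x tissue with responses on both sides of its fluorescence
#' LOD, selects the balanced neighbourhood ([balanced_neighborhood()]),
#' computes the CV on each side and the variance-ratio test
#' ([cv_ratio_test()]). Combinations with fewer than `min_n` points per side
#' are excluded, mirroring the published comparison's "at least 5 responses
#' above and below" rule.
#'
#' @param ds Plate table (sample wells are used).
#' @param lods Tibble with columns `analyte` and `lod_fl` (one LOD per
#'   analyte), e.g. derived from [fit_standard_curves()] blanks.
#' @param min_n Minimum balanced N per side to keep a row (default 5).
#' @param aggregate Average duplicate wells first (default TRUE).
#' @return Tibble with one row per retained analyte x tissue: `analyte`,
#'   `tissue`, `lod_fl`, `n_selected`, `n_above`, `n_below`, `cv_above`,
#'   `cv_below`, `ratio`, `f_pvalue`.
#' @export
cv_comparison_table <- function(ds, lods, min_n = 5L, aggregate = TRUE) {
  ds <- tibble::as_tibble(ds)
  samples <- dplyr::filter(ds, .data$well_role == "sample")
  if (aggregate) samples <- aggregate_duplicates(samples)
  samples <- dplyr::inner_join(samples, tibble::as_tibble(lods), by = "analyte")
  rows <- samples |>
    dplyr::group_by(.data$analyte, .data$tissue) |>
    dplyr::group_map(function(g, key) {
      sel <- balanced_neighborhood(g$fluorescence, g$lod_fl[1L])
      if (sel$n_selected < min_n) return(NULL)
      test <- cv_ratio_test(sel$above, sel$below)
      dplyr::bind_cols(
        key,
        tibble::tibble(
          lod_fl = g$lod_fl[1L], n_selected = sel$n_selected,
          n_above = sel$n_above, n_below = sel$n_below
        ),
        test[c("cv_above", "cv_below", "ratio", "f_pvalue")]
      )
    }) |>
    purrr::compact() |>
    dplyr::bind_rows()
  rows
}

#' Aggregate an above/below-LOD CV table
#'
#' Tests whether, across the table's rows, CVs above the LOD differ
#' systematically from CVs below it: a Mann-Whitney rank-sum test treating the
#' two log2-CV columns as independent samples, and a paired two-sided t-test
#' on the row-wise log2 differences (df = rows - 1). If point scatter hit a
#' floor below the LOD, both tests would reject with CVs smaller below.
#'
#' @param rows Tibble with columns `cv_above` and `cv_below` (e.g. from
#'   [cv_comparison_table()] or the packaged printed table). Rows with a
#'   non-positive CV are excluded with a warning.
#' @return Tibble with `w_statistic`, `p_mw`, `t_statistic`, `df`, `p_t` and
#'   `n_rows`.
#' @export
aggregate_cv_comparison <- function(rows) {
  rows <- tibble::as_tibble(rows)
  stopifnot(all(c("cv_above", "cv_below") %in% names(rows)))
  ok <- is.finite(rows$cv_above) & is.finite(rows$cv_below) &
    rows$cv_above > 0 & rows$cv_below > 0
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with missing or non-positive CVs excluded",
            call. = FALSE)
    rows <- rows[ok, ]
  }
  if (nrow(rows) < 2L) stop("need at least 2 usable CV pairs", call. = FALSE)
  la <- log2(rows$cv_above)
  lb <- log2(rows$cv_below)
  mw <- suppressWarnings(wilcox.test(la, lb))
  if (all(la == lb)) {
    # no paired differences at all: t is 0 by convention
    t_stat <- 0
    t_df <- length(la) - 1L
    p_t <- 1
  } else {
    tt <- t.test(la, lb, paired = TRUE)
    t_stat <- unname(tt$statistic)
    t_df <- unname(tt$parameter)
    p_t <- tt$p.value
  }
  tibble::tibble(
    w_statistic = unname(mw$statistic), p_mw = mw$p.value,
    t_statistic = t_stat, df = t_df,
    p_t = p_t, n_rows = nrow(rows)
  )
}

#' Rank-difference profile of a response set
#'
#' Sorts the unique responses ascending, takes successive differences
#' `Fl(r + 1) - Fl(r)` over ranks r = 1..n-1 and logs them base 2. If a
#' detection floor existed, differences at the low ranks would shrink toward
#' zero (log2 toward -Inf); instrument quantisation at half-unit resolution
#' instead pins the low-rank differences at 0.5, i.e. log2 difference -1.
#' `head_mean` averages the profile over the first half of the ranks.
#'
#' @param responses Fluorescence values (>= 3 unique values required).
#' @return Object of class `rank_diff_profile`: tibble with `rank` and
#'   `log2_diff`, plus attributes `head_mean` and `n_unique`.
#' @export
rank_difference_profile <- function(responses) {
  u <- sort(unique(responses[is.finite(responses)]))
  n <- length(u)
  if (n < 3L) stop("need at least 3 unique responses", call. = FALSE)
  d <- diff(u)
  profile <- tibble::tibble(rank = seq_len(n - 1L), log2_diff = log2(d))
  head_n <- floor((n - 1L) / 2L)
  structure(
    profile,
    head_mean = mean(profile$log2_diff[seq_len(head_n)]),
    n_unique = n,
    class = c("rank_diff_profile", class(profile))
  )
}

#' Head mean of a rank-difference profile
#' @param profile A `rank_diff_profile`.
#' @return Mean log2 difference over the first half of the ranks.
#' @export
rank_diff_head_mean <- function(profile) {
  attr(profile, "head_mean")
}

#' P-value uniformity scan across tissue pairs
#'
#' For each requested analyte and each unordered tissue pair, runs a two-sided
#' Mann-Whitney test on the log2 fluorescence of sample wells. If low-abundance
#' responses were pure noise these p-values should be uniform on (0, 1); an
#' excess of small p-values indicates real structure below the nominal
#' detection limit. Uniformity is summarised by a one-sample
#' Kolmogorov-Smirnov statistic against Uniform(0,1) and the fraction of
#' p-values below 0.05.
#'
#' @param ds Plate table.
#' @param analytes Analytes to scan (default: all).
#' @param min_per_group Minimum samples per tissue to include a pair
#'   (default 3).
#' @param aggregate Average duplicate wells first (default TRUE).
#' @return List with `pvalues` (tibble analyte/tissue_a/tissue_b/n_a/n_b/p),
#'   `ks_statistic`, `ks_pvalue` and `prop_below_05`.
#' @export
pvalue_uniformity_scan <- function(ds, analytes = NULL, min_per_group = 3L,
                                   aggregate = TRUE) {
  ds <- tibble::as_tibble(ds)
  samples <- dplyr::filter(ds, .data$well_role == "sample")
  if (aggregate) samples <- aggregate_duplicates(samples)
  if (!is.null(analytes)) {
    samples <- dplyr::filter(samples, .data$analyte %in% analytes)
  }
  res <- samples |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_map(function(g, key) {
      tissues <- sort(unique(g$tissue))
      if (length(tissues) < 2L) return(NULL)
      pairs <- utils::combn(tissues, 2L, simplify = FALSE)
      purrr::map(pairs, function(pr) {
        xa <- log2(g$fluorescence[g$tissue == pr[1L]])
        xb <- log2(g$fluorescence[g$tissue == pr[2L]])
        if (length(xa) < min_per_group || length(xb) < min_per_group) return(NULL)
        p <- suppressWarnings(wilcox.test(xa, xb)$p.value)
        tibble::tibble(analyte = key$analyte, tissue_a = pr[1L],
                       tissue_b = pr[2L], n_a = length(xa), n_b = length(xb),
                       p = p)
      }) |>
        purrr::compact() |>
        dplyr::bind_rows()
    }) |>
    purrr::compact() |>
    dplyr::bind_rows()
  if (nrow(res) == 0L) stop("no tissue pair had enough samples", call. = FALSE)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  list(
    pvalues = res,
    ks_statistic = unname(ks$statistic),
    ks_pvalue = ks$p.value,
    prop_below_05 = mean(res$p < 0.05)
  )
}
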