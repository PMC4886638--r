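.panel_analytes <- c(
  "April (42)", "Baff (37)", "CD163 (46)", "CD30 (53)", "Chitinase (72)",
  "gp130 (14)", "IFN-a2 (20)", "IFN-b (44)", "IFN-g (21)", "IL-10 (56)",
  "IL-11 (39)", "IL-12p40 (28)", "IL-12p70 (75)", "IL-19 (29)", "IL-2 (38)",
  "IL-20 (30)", "IL-22 (18)", "IL-26 (22)", "IL-27 (13)", "IL-28 (66)",
  "IL-29 (33)", "IL-32 (35)", "IL-34 (15)", "IL-35 (34)", "IL-6RA (19)",
  "IL-8 (54)", "Light (51)", "MMP-1 (43)", "MMP-2 (26)", "MMP-3 (45)",
  "OCN (65)", "OPN (77)", "Pentraxin (48)", "TNFR1 (73)", "TNFR2 (67)",
  "TSLP (52)", "Tweak (62)"
)

#' Default study design allocation
#'
#' A fixed Plate:Condition:Tissue allocation emulating the 37-plex
#' inflammation panel study's layout: 169 patients contributing 191 samples
#' over 3 plates, 14 nonempty plate groups, with the 16 mononucleosis and 6
#' myeloma patients paired across plasma and serum (the `pair_group` column).
#' The exact published allocation is not available, so the patient counts are
#' the package's own stand-in, chosen to reproduce the design's totals.
#'
#' @return Tibble with `plate`, `condition`, `tissue`, `n_patients`,
#'   `pair_group` (`NA` for unpaired groups).
#' @export
default_design <- function() {
  tibble::tribble(
    ~plate,   ~condition,  ~tissue,  ~n_patients, ~pair_group,
    "plate1", "Normal",    "plasma", 25L,         NA_character_,
    "plate1", "Normal",    "serum",  18L,         NA_character_,
    "plate1", "Mono",      "plasma", 16L,         "mono",
    "plate1", "Mono",      "serum",  16L,         "mono",
    "plate2", "Myeloma",   "plasma",  6L,         "myeloma",
    "plate2", "Myeloma",   "serum",   6L,         "myeloma",
    "plate2", "COPD",      "plasma", 15L,         NA_character_,
    "plate2", "RA",        "plasma", 18L,         NA_character_,
    "plate2", "T2D",       "plasma", 15L,         NA_character_,
    "plate3", "Psoriasis", "plasma", 12L,         NA_character_,
    "plate3", "Sepsis",    "plasma", 12L,         NA_character_,
    "plate3", "Normal",    "saliva", 12L,         NA_character_,
    "plate3", "Normal",    "urine",  11L,         NA_character_,
    "plate3", "RA",        "urine",   9L,         NA_character_
  )
}

#' Balanced design helper for scaled-down experiments
#'
#' Fully crossed tissue x condition cells with a fixed number of patients per
#' cell, allocated to plates round-robin. Useful for parameter-recovery
#' studies where the study's sparse layout is not the point.
#'
#' @param tissues,conditions Level labels.
#' @param plates Plate labels.
#' @param patients_per_cell Patients in every tissue x condition cell (per
#'   plate when `replicate_across_plates` is set).
#' @param replicate_across_plates Put every tissue x condition cell on every
#'   plate (with fresh patients per plate) instead of on a single plate.
#'   Replicating cells across plates is what gives the plate-group variance
#'   component genuine replication free of the fixed effects.
#' @return Design tibble as in [default_design()].
#' @export
balanced_design <- function(tissues = c("plasma", "serum"),
                            conditions = c("Normal", "DiseaseA", "DiseaseB",
                                           "DiseaseC"),
                            plates = c("plate1", "plate2"),
                            patients_per_cell = 4L,
                            replicate_across_plates = FALSE) {
  if (replicate_across_plates) {
    grid <- tidyr::crossing(condition = conditions, tissue = tissues,
                            plate = plates)
  } else {
    grid <- tidyr::crossing(condition = conditions, tissue = tissues)
    grid$plate <- rep_len(plates, nrow(grid))
  }
  grid$n_patients <- patients_per_cell
  grid$pair_group <- NA_character_
  grid[c("plate", "condition", "tissue", "n_patients", "pair_group")]
}

#' Synthetic plate-data generator configuration
#'
#' Defaults emulate the study conditions the analysis assumes: 37 analytes
#' over 4 tissues, 8 conditions and 3 plates laid out per [default_design()];
#' variance components (0.25 patient, 0.09 plate-group, 0.04 residual, log2
#' scale); an 8-point standard series diluted 4-fold (borrowed from the stated
#' 4-fold sample dilution) run in duplicate with blanks; multiplicative
#' lognormal fluorescence noise (constant CV, matching the use of %CV as the
#' dispersion measure); and half-unit fluorescence quantisation. Analyte
#' baselines are spread so roughly nine low-abundance analytes sit below their
#' lowest standard.
#'
#' @param n_analytes Number of analytes (<= 37 uses the panel labels).
#' @param design Design tibble (see [default_design()]).
#' @param var_patient,var_plategroup,var_resid Log2-scale variances of the
#'   random effects and residual.
#' @param analyte_baselines Per-analyte latent log2 concentration means
#'   (default: spread from -4.5 to 11).
#' @param tissue_effects,condition_effects Optional effect matrices
#'   (analytes x levels, first column must be 0); drawn under the seed when
#'   `NULL`.
#' @param tissue_effect_sd,condition_effect_sd SDs for drawn effects.
#' @param curve_type `"fivepl"` (default) or `"identity"` (fluorescence =
#'   2^latent, for mapping-free recovery experiments).
#' @param curve_params Optional tibble of per-analyte 5PL truth (`analyte`,
#'   `bottom`, `top`, `ec50`, `hill`, `asym`); drawn under the seed when
#'   `NULL`.
#' @param n_standards,standard_dilution_factor,top_standard_conc Standard
#'   series: number of levels, fold dilution between levels, concentration of
#'   the top standard (pg/ml).
#' @param replicates Wells per sample (and per standard level / blank).
#' @param fl_noise_cv Coefficient of variation of the multiplicative
#'   fluorescence noise.
#' @param quantization_step Fluorescence quantisation step (0.5 units).
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_analytes = 37L,
                             design = default_design(),
                             var_patient = 0.25,
                             var_plategroup = 0.09,
                             var_resid = 0.04,
                             analyte_baselines = NULL,
                             tissue_effects = NULL,
                             condition_effects = NULL,
                             tissue_effect_sd = 1,
                             condition_effect_sd = 0.75,
                             curve_type = c("fivepl", "identity"),
                             curve_params = NULL,
                             n_standards = 8L,
                             standard_dilution_factor = 4,
                             top_standard_conc = 10000,
                             replicates = 2L,
                             fl_noise_cv = 0.03,
                             quantization_step = 0.5,
                             seed = 1L) {
  curve_type <- match.arg(curve_type)
  stopifnot(var_patient >= 0, var_plategroup >= 0, var_resid >= 0,
            n_standards >= 5L, replicates >= 1L, quantization_step > 0)
  analytes <- if (n_analytes <= length(.panel_analytes)) {
    .panel_analytes[seq_len(n_analytes)]
  } else {
    sprintf("ANL-%02d (%d)", seq_len(n_analytes), 10L + seq_len(n_analytes))
  }
  if (is.null(analyte_baselines)) {
    analyte_baselines <- seq(-4.5, 11, length.out = n_analytes)
  }
  stopifnot(length(analyte_baselines) == n_analytes)
  structure(
    list(
      n_analytes = n_analytes, analytes = analytes, design = design,
      var_patient = var_patient, var_plategroup = var_plategroup,
      var_resid = var_resid,
      analyte_baselines = setNames(analyte_baselines, analytes),
      tissue_effects = tissue_effects, condition_effects = condition_effects,
      tissue_effect_sd = tissue_effect_sd,
      condition_effect_sd = condition_effect_sd,
      curve_type = curve_type, curve_params = curve_params,
      n_standards = n_standards,
      standard_dilution_factor = standard_dilution_factor,
      top_standard_conc = top_standard_conc,
      replicates = replicates, fl_noise_cv = fl_noise_cv,
      quantization_step = quantization_step, seed = seed
    ),
    class = "generator_config"
  )
}

#' Quantize fluorescence to the instrument's resolution
#'
#' Rounds to the nearest multiple of `step` (default half a fluorescence
#' unit, the resolution that leaves the signature log2 rank difference of -1).
#' Idempotent.
#'
#' @param values Fluorescence values.
#' @param step Quantisation step (> 0).
#' @return Quantized values.
#' @export
quantize_fluorescence <- function(values, step = 0.5) {
  stopifnot(step > 0)
  round(values / step) * step
}

.draw_effect_matrix <- function(n_analytes, levels, sd, rownames) {
  m <- matrix(rnorm(n_analytes * length(levels), 0, sd),
              nrow = n_analytes,
              dimnames = list(rownames, levels))
  m[, 1L] <- 0
  m
}

#' Generate a synthetic plate dataset with ground truth
#'
#' Simulates the full data-generating model: latent log2 concentration =
#' analyte baseline + tissue effect + condition effect + patient random
#' intercept + plate-group random intercept + residual; fluorescence is the
#' 5PL image of the latent concentration under multiplicative lognormal noise,
#' quantized to the instrument step. Standards (a dilution series in replicate
#' wells, per analyte and plate), and blanks are generated alongside the
#' sample wells. Under the default configuration the design has 191 sample
#' entities from 169 patients in 14 plate groups over 37 analytes.
#'
#' @param config A [generator_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @return List with `data` (validated plate tibble) and `truth` (list:
#'   `samples` with per-sample random effects, `latent` tibble of
#'   sample x analyte latent log2 concentrations, `tissue_effects`,
#'   `condition_effects`, `baselines`, `curve_params`, `patient_effects`,
#'   `plategroup_effects`, `config`, `seed`).
#' @export
generate_dataset <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  design <- tibble::as_tibble(config$design)
  stopifnot(all(c("plate", "condition", "tissue", "n_patients", "pair_group")
                %in% names(design)))
  if (any(design$n_patients < 1L)) {
    stop("infeasible design: every group needs at least one patient",
         call. = FALSE)
  }
  pair_sizes <- design |>
    dplyr::filter(!is.na(.data$pair_group)) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$n_patients),
                     .by = "pair_group")
  if (any(pair_sizes$n != 1L)) {
    stop("infeasible pairing: groups sharing a pair_group must have the same ",
         "n_patients", call. = FALSE)
  }

  # --- patients and sample entities -----------------------------------------
  next_id <- 1L
  pair_patients <- list()
  samples <- purrr::pmap(design, function(plate, condition, tissue,
                                          n_patients, pair_group) {
    if (!is.na(pair_group)) {
      if (is.null(pair_patients[[pair_group]])) {
        ids <- sprintf("P%03d", next_id + seq_len(n_patients) - 1L)
        next_id <<- next_id + n_patients
        pair_patients[[pair_group]] <<- ids
      }
      ids <- pair_patients[[pair_group]]
    } else {
      ids <- sprintf("P%03d", next_id + seq_len(n_patients) - 1L)
      next_id <<- next_id + n_patients
    }
    tibble::tibble(patient_id = ids, plate = plate, condition = condition,
                   tissue = tissue)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      plate_group = paste(.data$plate, .data$condition, .data$tissue, sep = ":")
    )

  patients <- unique(samples$patient_id)
  patient_effects <- setNames(
    rnorm(length(patients), 0, sqrt(config$var_patient)), patients
  )
  plate_groups <- unique(samples$plate_group)
  plategroup_effects <- setNames(
    rnorm(length(plate_groups), 0, sqrt(config$var_plategroup)), plate_groups
  )

  analytes <- config$analytes
  n_a <- config$n_analytes
  tissues <- sort(unique(design$tissue))
  conditions <- unique(design$condition)
  conditions <- c(intersect("Normal", conditions),
                  sort(setdiff(conditions, "Normal")))

  tissue_effects <- config$tissue_effects %||%
    .draw_effect_matrix(n_a, tissues, config$tissue_effect_sd, analytes)
  condition_effects <- config$condition_effects %||%
    .draw_effect_matrix(n_a, conditions, config$condition_effect_sd, analytes)

  curve_params <- config$curve_params %||% tibble::tibble(
    analyte = analytes,
    bottom = runif(n_a, 20, 60),
    top = runif(n_a, 15000, 30000),
    ec50 = 2^runif(n_a, 4, 8),
    hill = runif(n_a, 0.9, 1.2),
    asym = runif(n_a, 0.8, 1.25)
  )
  blank_mean_fl <- setNames(curve_params$bottom * runif(n_a, 1.02, 1.15),
                            analytes)
  blank_sd_fl <- pmax(0.03 * blank_mean_fl, 0.5)

  # --- latent log2 concentrations (sample x analyte, long) -------------------
  grid <- tidyr::crossing(samples, analyte = analytes)
  grid <- dplyr::mutate(
    grid,
    latent = as.numeric(
      config$analyte_baselines[.data$analyte] +
        tissue_effects[cbind(.data$analyte, .data$tissue)] +
        condition_effects[cbind(.data$analyte, .data$condition)] +
        patient_effects[.data$patient_id] +
        plategroup_effects[.data$plate_group] +
        rnorm(dplyr::n(), 0, sqrt(config$var_resid))
    )
  )

  sdlog <- sqrt(log(1 + config$fl_noise_cv^2))
  curve_lookup <- split(curve_params, curve_params$analyte)
  true_fl <- function(analyte, conc) {
    if (config$curve_type == "identity") return(conc)
    cp <- curve_lookup[[analyte[1L]]]
    fivepl(conc, cp$bottom, cp$top, cp$ec50, cp$hill, cp$asym)
  }

  noisy_wells <- function(base, n_rep) {
    fl <- rep(base, each = n_rep) * exp(rnorm(length(base) * n_rep, 0, sdlog))
    pmax(config$quantization_step,
         quantize_fluorescence(fl, config$quantization_step))
  }

  sample_rows <- grid |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_map(function(g, key) {
      base <- true_fl(key$analyte, 2^g$latent)
      idx <- rep(seq_len(nrow(g)), each = config$replicates)
      tibble::tibble(
        patient_id = g$patient_id[idx], tissue = g$tissue[idx],
        condition = g$condition[idx], plate = g$plate[idx],
        analyte = key$analyte, well_role = "sample",
        standard_level = NA_integer_,
        fluorescence = noisy_wells(base, config$replicates),
        concentration = NA_real_, censor_status = "unset"
      )
    }) |>
    dplyr::bind_rows()

  # --- standards and blanks, per analyte x plate ----------------------------
  std_conc <- config$top_standard_conc /
    config$standard_dilution_factor^(seq_len(config$n_standards) - 1L)
  plates <- unique(design$plate)
  std_grid <- tidyr::crossing(analyte = analytes, plate = plates,
                              standard_level = seq_len(config$n_standards))
  std_grid$conc <- std_conc[std_grid$standard_level]
  std_rows <- std_grid |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_map(function(g, key) {
      base <- true_fl(key$analyte, g$conc)
      idx <- rep(seq_len(nrow(g)), each = config$replicates)
      tibble::tibble(
        patient_id = NA_character_, tissue = NA_character_,
        condition = NA_character_, plate = g$plate[idx],
        analyte = key$analyte, well_role = "standard",
        standard_level = as.integer(g$standard_level[idx]),
        fluorescence = noisy_wells(base, config$replicates),
        concentration = g$conc[idx], censor_status = "in_range"
      )
    }) |>
    dplyr::bind_rows()

  blank_grid <- tidyr::crossing(analyte = analytes, plate = plates)
  n_blank_wells <- nrow(blank_grid) * config$replicates
  bidx <- rep(seq_len(nrow(blank_grid)), each = config$replicates)
  blank_rows <- tibble::tibble(
    patient_id = NA_character_, tissue = NA_character_,
    condition = NA_character_, plate = blank_grid$plate[bidx],
    analyte = blank_grid$analyte[bidx], well_role = "blank",
    standard_level = NA_integer_,
    fluorescence = pmax(
      config$quantization_step,
      quantize_fluorescence(
        rnorm(n_blank_wells, blank_mean_fl[blank_grid$analyte[bidx]],
              blank_sd_fl[blank_grid$analyte[bidx]]),
        config$quantization_step
      )
    ),
    concentration = NA_real_, censor_status = "unset"
  )

  data <- dplyr::bind_rows(sample_rows, std_rows, blank_rows)
  data <- data[names(plate_schema())]
  validate_plate_data(data)

  list(
    data = tibble::as_tibble(data),
    truth = list(
      samples = samples,
      latent = grid,
      tissue_effects = tissue_effects,
      condition_effects = condition_effects,
      baselines = config$analyte_baselines,
      curve_params = curve_params,
      blank_mean_fl = blank_mean_fl,
      blank_sd_fl = blank_sd_fl,
      patient_effects = patient_effects,
      plategroup_effects = plategroup_effects,
      config = config,
      seed = seed
    )
  )
}

#' Push analytes below their blank level
#'
#' Multiplicatively shifts the sample fluorescence of selected analytes so
#' that each analyte's sample median sits `depth` log2 units below its blank
#' mean (low-abundance responses below blank, as seen for IL-11-like
#' analytes). Used to exercise the out-of-range censoring paths: after 5PL
#' mapping such analytes lose whole concentration design cells while the
#' fluorescence pipeline keeps every record.
#'
#' @param ds Plate table containing blank wells for the targeted analytes.
#' @param analytes Analytes to shift.
#' @param depth Log2 units below the blank mean (>= 0).
#' @param step Quantisation step to re-apply (default 0.5).
#' @return Plate table with shifted sample fluorescence.
#' @export
inject_low_abundance <- function(ds, analytes, depth = 1, step = 0.5) {
  ds <- tibble::as_tibble(ds)
  stopifnot(all(analytes %in% ds$analyte))
  for (a in analytes) {
    blanks <- ds$fluorescence[ds$well_role == "blank" & ds$analyte == a]
    if (length(blanks) == 0L) {
      stop("no blank wells for analyte ", a, call. = FALSE)
    }
    target <- mean(blanks) / 2^depth
    rows <- ds$well_role == "sample" & ds$analyte == a
    scale <- target / median(ds$fluorescence[rows])
    ds$fluorescence[rows] <- pmax(
      step, quantize_fluorescence(ds$fluorescence[rows] * scale, step)
    )
  }
  ds
}
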