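# Shared scaled-down generator configurations.

# Small balanced design with an identity response curve and baselines far above
# the quantization step, for model-recovery experiments where the standard
# curve is not the point.
recovery_config <- function(n_analytes = 10L, tissues = 4L, conditions = 4L,
                            patients_per_cell = 3L, seed = 1L,
                            n_plates = 2L, replicate_across_plates = FALSE,
                            ...) {
  generator_config(
    n_analytes = n_analytes,
    design = balanced_design(
      tissues = c("plasma", "saliva", "serum", "urine")[seq_len(tissues)],
      conditions = c("Normal", "DiseaseA", "DiseaseB", "DiseaseC",
                     "DiseaseD", "DiseaseE", "DiseaseF", "DiseaseG")[
                       seq_len(conditions)],
      plates = sprintf("plate%d", seq_len(n_plates)),
      patients_per_cell = patients_per_cell,
      replicate_across_plates = replicate_across_plates
    ),
    curve_type = "identity",
    analyte_baselines = seq(6, 12, length.out = n_analytes),
    seed = seed,
    ...
  )
}

# A minimal hand-built plate table: one analyte, one plate, standards + blanks
# + a few sample wells.
toy_plate_table <- function() {
  conc <- 10000 / 4^(0:7)
  fl <- fivepl(conc, 50, 20000, 100, 1.2, 1)
  dplyr::bind_rows(
    tibble::tibble(
      patient_id = NA_character_, tissue = NA_character_,
      condition = NA_character_, plate = "plate1", analyte = "IL-8 (54)",
      well_role = "standard", standard_level = 1:8,
      fluorescence = fl, concentration = conc, censor_status = "in_range"
    ),
    tibble::tibble(
      patient_id = NA_character_, tissue = NA_character_,
      condition = NA_character_, plate = "plate1", analyte = "IL-8 (54)",
      well_role = "blank", standard_level = NA_integer_,
      fluorescence = c(52, 54), concentration = NA_real_,
      censor_status = "unset"
    ),
    tibble::tibble(
      patient_id = c("P1", "P2", "P3"), tissue = "plasma",
      condition = "Normal", plate = "plate1", analyte = "IL-8 (54)",
      well_role = "sample", standard_level = NA_integer_,
      fluorescence = c(500, 1500, 9000), concentration = NA_real_,
      censor_status = "unset"
    )
  )
}
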