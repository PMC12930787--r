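# Builders for tiny hand-made cohorts. All defaults describe an eligible
# 900 g infant admitted at birth with a 30-day stay.

d0 <- as.Date("2025-01-01")

make_patient <- function(patient_id = "P1", birth_weight = 900L,
                         gestational_weeks = 27L, gestational_days = 3L,
                         birth_date = d0, admission_date = birth_date,
                         end_date = admission_date + 29L,
                         end_reason = "discharge_or_transfer",
                         admission_type = "delivery_room",
                         birth_time = NA_character_, live_born = TRUE) {
  tibble::tibble(
    patient_id = patient_id, gestational_weeks = gestational_weeks,
    gestational_days = gestational_days, birth_weight = birth_weight,
    sex = "female", delivery_mode = "vaginal", multiple_birth = 1L,
    birth_date = birth_date, birth_time = birth_time,
    admission_type = admission_type, admission_date = admission_date,
    end_date = end_date, end_reason = end_reason, live_born = live_born
  )
}

make_stay <- function(patient_id = "P1", start_date = d0,
                      end_date = d0 + 29L) {
  tibble::tibble(patient_id = patient_id, start_date = start_date,
                 end_date = end_date)
}

make_exposure <- function(patient_id = "P1", date = d0, cvc = 0, pvc = 0,
                          inv = 0, niv = 0, antibiotics = NA_character_,
                          feeding = "none", probiotic = FALSE, kangaroo = 0) {
  tibble::tibble(
    patient_id = patient_id, date = date, cvc_hours = cvc, pvc_hours = pvc,
    inv_hours = inv, niv_hours = niv, antibiotic_substances = antibiotics,
    enteral_feeding = feeding, probiotic_given = probiotic,
    kangaroo_hours = kangaroo
  )
}

make_finding <- function(patient_id = "P1", date = d0,
                         code = "CLIN_SEPSIS_SIGN",
                         definitions = default_definitions()) {
  cr <- definitions$criteria[[code]]
  tibble::tibble(patient_id = patient_id, date = date,
                 category = cr$category, criterion_code = code,
                 body_system = cr$body_system)
}

make_micro <- function(patient_id = "P1", date = d0, type = "blood",
                       organism = "escherichia_coli",
                       markers = NA_character_) {
  tibble::tibble(patient_id = patient_id, specimen_date = date,
                 specimen_type = type, organism = organism,
                 resistance_markers = markers)
}

make_surgery <- function(surgery_id = "S1", patient_id = "P1", date = d0,
                         implant = FALSE, code = "KDQ10") {
  tibble::tibble(
    surgery_id = surgery_id, patient_id = patient_id,
    description = "procedure", date = date, duration_minutes = 60L,
    main_procedure_code = code, side_procedure_codes = NA_character_,
    asa_score = 3L, wound_class = "clean", endoscopic = FALSE,
    emergency = FALSE, revision = FALSE, primary_wound_closure = TRUE,
    implant = implant, infection_signs_at_surgery = FALSE
  )
}

# A one-patient cohort with a 30-day window and the supplied event tables.
make_cohort <- function(patients = make_patient(), stays = NULL,
                        exposures = NULL, surgeries = NULL, findings = NULL,
                        microbiology = NULL) {
  neo_cohort(patients = patients, stays = stays, exposures = exposures,
             surgeries = surgeries, findings = findings,
             microbiology = microbiology)
}
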