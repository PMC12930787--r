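# Default surveillance definitions for the neonatal HAI core module.
#
# `parameters` holds every temporal threshold of the rule set; all are
# expressed in the unit given by the key suffix. `criteria` is the closed
# criterion-code vocabulary for findings; `types` gives, per infection type,
# the criterion sets and organism evidence required for classification.
# Types are tried in the listed order within a body system (first match
# wins), which encodes the precedence laboratory-confirmed > clinical.
parameters:
  eligibility_bw_grams: 1500        # include if birth weight strictly below
  eligibility_ga_weeks: 32          # include if completed weeks strictly below
  admission_window_days: 120        # admitted within this many days of birth
  absence_merge_hours: 48           # short absences up to this are bridged
  device_day_min_hours: 12          # device-day = cumulative device hours >= this
  kangaroo_min_hours: 2             # kangaroo-care day threshold
  late_onset_hours: 72              # HAI = onset at or beyond this after birth
  episode_max_span_days: 10         # all elements of one episode within this span
  episode_max_gap_days: 3           # max gap between consecutive elements
  repeat_min_days: 14               # days before same-type infection counts again
  symptom_free_min_days: 1          # required symptom-free days between episodes
  device_assoc_min_days: 3          # consecutive device-days ending on onset or onset-1
  ssi_window_days: 30               # SSI attribution window after surgery (all depths)
  ssi_implant_window_days: 90       # extension for deep/organ-space SSI with implant
  secondary_bsi_active_days: 14     # primary infection considered active this long
  secondary_bsi_require_organism_match: true
criteria:
  CLIN_SEPSIS_SIGN:     {category: clinical,          body_system: bloodstream}
  LAB_SEPSIS_MARKER:    {category: laboratory,        body_system: bloodstream}
  MENINGITIS_SIGN:      {category: clinical,          body_system: bloodstream}
  CLIN_RESP_SIGN:       {category: clinical,          body_system: respiratory}
  PNEU_IMAGING:         {category: imaging,           body_system: respiratory}
  LAB_INFECTION_MARKER: {category: laboratory,        body_system: respiratory}
  CLIN_NEC_SIGN:        {category: clinical,          body_system: gastrointestinal}
  NEC_RADIOLOGY:        {category: imaging,           body_system: gastrointestinal}
  NEC_SURGICAL:         {category: surgical_evidence, body_system: gastrointestinal}
  SSI_LOCAL_SIGN:       {category: clinical,          body_system: surgical_site, depth: superficial}
  SSI_DEEP_SIGN:        {category: clinical,          body_system: surgical_site, depth: deep}
  SSI_ORGAN_SIGN:       {category: clinical,          body_system: surgical_site, depth: organ_space}
types:
  lcbsi_pathogen:
    body_system: bloodstream
    organism: recognized_pathogen   # a positive primary-site culture alone suffices
  lcbsi_commensal:
    body_system: bloodstream
    organism: common_commensal      # commensal culture plus clinical AND laboratory findings
    requires:
      - [CLIN_SEPSIS_SIGN, MENINGITIS_SIGN]
      - [LAB_SEPSIS_MARKER]
  clinical_sepsis:
    body_system: bloodstream
    organism: none                  # infection without a detected organism
    requires:
      - [CLIN_SEPSIS_SIGN, MENINGITIS_SIGN]
      - [LAB_SEPSIS_MARKER]
  pneumonia:
    body_system: respiratory
    requires:
      - [CLIN_RESP_SIGN]
      - [PNEU_IMAGING]
      - [LAB_INFECTION_MARKER]
  nec:
    body_system: gastrointestinal
    any_of:
      - requires:
          - [CLIN_NEC_SIGN]
          - [NEC_RADIOLOGY]
      - requires:
          - [NEC_SURGICAL]
  ssi:
    body_system: surgical_site
    any_of:
      - requires:
          - [SSI_LOCAL_SIGN, SSI_DEEP_SIGN, SSI_ORGAN_SIGN]
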