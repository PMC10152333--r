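# Sentence banks used by the synthetic note generator.
#
# The neutral bank emulates routine home-health visit documentation
# (short telegraphic sentences, ~50 characters). It deliberately contains
# none of the default judgment-lexicon surface forms, so every judgment
# occurrence in a synthetic note is a planted one with a known span.

neutral_sentence_bank <- c(
  "wound care completed and dressing changed per plan.",
  "medication reconciliation reviewed with pt during the visit.",
  "vital signs within usual range for this pt today.",
  "pt ambulating with rolling walker in the hallway.",
  "home environment reviewed for fall hazards.",
  "pt reports pain level of three out of ten.",
  "education provided on low sodium diet choices.",
  "blood pressure recorded sitting and standing.",
  "pt demonstrated correct use of the glucometer.",
  "caregiver present and assisting with daily tasks.",
  "lower extremity edema unchanged from prior visit.",
  "skin intact with good color and warm to touch.",
  "pt tolerated all transfers with minimal assistance.",
  "breath sounds clear in all fields on exam.",
  "follow up visit scheduled for later this week.",
  "pt verbalized understanding of teaching provided.",
  "gait steady with supervision during ambulation.",
  "medications prefilled in weekly organizer box.",
  "dressing dry and intact over the incision site.",
  "pt resting comfortably in chair on arrival.",
  "range of motion exercises completed as tolerated.",
  "home exercise program reviewed and updated today.",
  "blood sugar log reviewed with pt and caregiver.",
  "appetite fair and fluid intake adequate today.",
  "incision healing well with edges well approximated.",
  "pt oriented to person place and time this visit.",
  "safety precautions reinforced with pt and family.",
  "supplies restocked and next delivery confirmed.",
  "pt using oxygen at two liters via nasal cannula.",
  "diet recall obtained and reviewed during visit.",
  "pedal pulses palpable and capillary refill brisk.",
  "pt performed wound care with verbal cueing only.",
  "emergency plan reviewed and posted by the phone.",
  "pain managed with current regimen per pt report."
)

# Patient-subject framing for planted judgment terms: the prefix ends with a
# patient cue token so the term's nearest preceding subject is the patient.
# Each entry: c(prefix, tail); sentence = paste0(prefix, surface, tail).
judgment_sentence_templates <- list(
  claims     = c("pt ",      " relief of symptoms since the last visit."),
  insists    = c("pt ",      " on completing all transfers alone."),
  states     = c("patient ", " the medications were taken as ordered."),
  adamant    = c("pt ",      " about keeping the current dressing routine."),
  apparently = c("pt ",      " missed the follow up appointment last week."),
  convinced  = c("patient ", " the swelling is from the new tablets."),
  vehemently = c("pt ",      " refused assistance with bathing today."),
  believes   = c("patient ", " the dizziness comes from the heat."),
  admits     = c("pt ",      " to skipping the evening dose on weekends.")
)

# Provider-subject confounders: judgment verbs attributed to a clinician,
# which the matcher's attribution rule must exclude.
confounder_sentence_bank <- c(
  "cardiologist stated the medication plan is unchanged.",
  "vn convinced pt to accept a home health aide.",
  "primary care insisted on repeat labs this week.",
  "md stated follow up in two weeks.",
  "pcp insisted on a medication change."
)

# Inflected (correctly spelled) surface forms the generator may plant,
# and known misspellings planted at `misspelling_rate`.
planting_surface_forms <- list(
  claims     = c("claims", "claimed"),
  insists    = c("insists", "insisted"),
  states     = c("states"),
  adamant    = c("adamant", "adamantly"),
  apparently = c("apparently"),
  convinced  = c("convinced"),
  vehemently = c("vehemently"),
  believes   = c("believes"),
  admits     = c("admits")
)

planting_misspellings <- list(
  claims     = c("claimes", "clamed", "clai med"),
  apparently = c("aparently")
)
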