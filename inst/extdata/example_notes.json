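[
  {"text": "…claims smoking cessation but ash tray still noted on night stand.",
   "annotated_terms": ["claims"], "canonical_terms": ["claims"], "n_occurrences": 1},
  {"text": "pt claims he had fever in past, but no thermometer in use.",
   "annotated_terms": ["claims"], "canonical_terms": ["claims"], "n_occurrences": 1},
  {"text": "He has a rw but pt only uses it to get up fr the bed. pt demoed another safe method of getting out of the bed, but pt insisted of doing it on his own manner.",
   "annotated_terms": ["insisted"], "canonical_terms": ["insists"], "n_occurrences": 1},
  {"text": "pt also insisted vn to remove left foot dressing however no wound order suggested to do so.",
   "annotated_terms": ["insists"], "canonical_terms": ["insists"], "n_occurrences": 1},
  {"text": "has a rollator but husband is so adamant for pt not to use it.",
   "annotated_terms": ["adamant"], "canonical_terms": ["adamant"], "n_occurrences": 1},
  {"text": "Patient has a straight cane but adamantly refused it in the apt and patient prefer holding on walls and furnitures.",
   "annotated_terms": ["adamantly"], "canonical_terms": ["adamant"], "n_occurrences": 1},
  {"text": "Patient states that she feels weak and dizzy patient admits to not testing blood sugars as ordered but states she takes her insulin.",
   "annotated_terms": ["states", "admits"], "canonical_terms": ["states", "admits"], "n_occurrences": 3},
  {"text": "patient refuses to wash legs and claims he is allergic to water. patient convinced genetic medicine is only solution for his wound care treatment.",
   "annotated_terms": ["convinced", "claims"], "canonical_terms": ["convinced", "claims"], "n_occurrences": 2},
  {"text": "pt has D.M. and H.F., but convinced they don't need to keep low sugar diet.",
   "annotated_terms": ["convinced"], "canonical_terms": ["convinced"], "n_occurrences": 1},
  {"text": "s/p hospital d/c where she was tx with hemodialysis after skipping 3 txs, as per d/c summary. pt vehemently denies this.",
   "annotated_terms": ["vehemently"], "canonical_terms": ["vehemently"], "n_occurrences": 1},
  {"text": "Patient admits to not testing blood sugars as ordered but states she takes her insulin.",
   "annotated_terms": ["admits", "states"], "canonical_terms": ["admits", "states"], "n_occurrences": 2}
]
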