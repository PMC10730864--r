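[
  {
    "pattern": "NORMAL",
    "juxtaposition": "*",
    "category": "NEGATIVE_WITH_FN_CAVEAT",
    "narrative": "No MYC rearrangement detected by break-apart FISH. Break-apart testing alone carries a false negative rate of at least 4%; IG/MYC dual-fusion probes reduce this rate.",
    "recommended_tests": []
  },
  {
    "pattern": "RGF",
    "juxtaposition": "*",
    "category": "POSITIVE_MYC_REARRANGEMENT",
    "narrative": "Balanced separation of red and green signals: positive for a MYC rearrangement.",
    "recommended_tests": []
  },
  {
    "pattern": "RF",
    "juxtaposition": "confirmed",
    "category": "POSITIVE_MYC_REARRANGEMENT",
    "narrative": "Unbalanced RF-type pattern with an orthogonally confirmed gene juxtaposition: positive for a MYC rearrangement.",
    "recommended_tests": []
  },
  {
    "pattern": "GF",
    "juxtaposition": "confirmed",
    "category": "POSITIVE_MYC_REARRANGEMENT",
    "narrative": "Unbalanced GF-type pattern with an orthogonally confirmed gene juxtaposition: positive for a MYC rearrangement.",
    "recommended_tests": []
  },
  {
    "pattern": "RF",
    "juxtaposition": "cn_only",
    "category": "CN_ALTERATION_NOT_CLASSIFIED_AS_R",
    "narrative": "Unbalanced RF-type pattern explained by a pure copy-number alteration (relative gain of material 5' of MYC); not classified as a MYC rearrangement under current DLBCL/HGBCL schemes.",
    "recommended_tests": []
  },
  {
    "pattern": "GF",
    "juxtaposition": "cn_only",
    "category": "CN_ALTERATION_NOT_CLASSIFIED_AS_R",
    "narrative": "Unbalanced GF-type pattern explained by a pure copy-number alteration (relative gain of material 3' of MYC); not classified as a MYC rearrangement under current DLBCL/HGBCL schemes.",
    "recommended_tests": []
  },
  {
    "pattern": "RF",
    "juxtaposition": "unknown",
    "category": "LIKELY_POSITIVE_RECOMMEND_TESTING",
    "narrative": "Unbalanced RF-type pattern: likely positive for a rearrangement at the MYC locus. Most such patterns reflect true structural variants juxtaposing MYC with a partner; confirmatory testing is recommended.",
    "recommended_tests": ["IG/MYC D-FISH", "MYC IHC", "WGS or RNAseq"]
  },
  {
    "pattern": "GF",
    "juxtaposition": "unknown",
    "category": "LIKELY_POSITIVE_RECOMMEND_TESTING",
    "narrative": "Unbalanced GF-type pattern: likely positive for a rearrangement at the MYC locus. Most such patterns reflect true structural variants juxtaposing MYC with a partner; confirmatory testing is recommended.",
    "recommended_tests": ["IG/MYC D-FISH", "MYC IHC", "WGS or RNAseq"]
  },
  {
    "pattern": "FUSION_CN",
    "juxtaposition": "*",
    "category": "CN_ALTERATION_NOT_CLASSIFIED_AS_R",
    "narrative": "Fusion signal copy-number change without isolated signals: copy-number alteration of the intact MYC locus, not classified as a MYC rearrangement.",
    "recommended_tests": []
  },
  {
    "pattern": "AMBIGUOUS",
    "juxtaposition": "*",
    "category": "AMBIGUOUS_RECOMMEND_TESTING",
    "narrative": "Signal-count ranges classify differently at their endpoints; the pattern is ambiguous. Confirmatory testing is recommended.",
    "recommended_tests": ["IG/MYC D-FISH", "MYC IHC", "WGS or RNAseq"]
  }
]
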