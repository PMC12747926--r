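# Diagnosis and drug code lists used to map raw claim codes to analytic groups.
#
# These lists are a documented stand-in assembled from the public ICD-9-CM /
# ICD-10-CM indices: the exact operational lists used against the source
# claims database are not public, so a plausible default is shipped here and
# can be replaced wholesale via `claims_config(code_lists = read_code_lists(...))`.
# Codes are matched by longest prefix (so "L40.5" wins over "L40").
version: 1
diagnoses:
  JIA:
    icd9: ["714.3"]                      # juvenile chronic polyarthritis (714.30-714.33)
    icd10: ["M08"]                       # juvenile arthritis
  SpA_feature:
    icd9: ["720.0", "720.2", "720.8", "720.9", "696.0"]
    icd10: ["M45", "M46.1", "M46.8", "M46.9", "L40.5"]
  uveitis:
    icd9: ["364.0", "364.3"]
    icd10: ["H20.0", "H20.9"]
  psoriasis:
    icd9: ["696.1"]
    icd10: ["L40"]
drugs:
  NSAID: [ibuprofen, naproxen, diclofenac, celecoxib, indomethacin, etoricoxib]
  steroid: [prednisolone, prednisone, methylprednisolone]
  csDMARD: [methotrexate, sulfasalazine, leflunomide, hydroxychloroquine, azathioprine]
  biologic: [etanercept, adalimumab, tocilizumab, abatacept]
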