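# Cerebrovascular DRG rule set without length of stay (8 groups).
# Secondary hospitals are merged; tertiary B and A are distinguished.
# Cerebral-infarction comorbidity groups are split by the principal-diagnosis
# blocks {I60,I63,I65,I66,I67,I69} and {I61,I62,I64,I68}. The residual
# comorbidity class "other" is carried with the non-infarction classes so the
# rule set is total.
name: without_los
uses_los: false
fallback: unassigned
rules:
- group: DRG 1
  all_of:
  - field: hospital_level
    op: in
    value: [secondary_B, secondary_A]
  - field: cc
    op: in
    value: [ischemic_supply, lacunar_infarction, chronic_ischemia, other]
- group: DRG 2
  all_of:
  - field: hospital_level
    op: in
    value: [secondary_B, secondary_A]
  - field: cc
    op: in
    value: [cerebral_infarction]
- group: DRG 3
  all_of:
  - field: hospital_level
    op: in
    value: [tertiary_B]
  - field: cc
    op: in
    value: [ischemic_supply, lacunar_infarction, chronic_ischemia, other]
- group: DRG 4
  all_of:
  - field: hospital_level
    op: in
    value: [tertiary_A]
  - field: cc
    op: in
    value: [ischemic_supply, lacunar_infarction, chronic_ischemia, other]
- group: DRG 5
  all_of:
  - field: hospital_level
    op: in
    value: [tertiary_B]
  - field: cc
    op: in
    value: [cerebral_infarction]
  - field: icd
    op: in
    value: [I60, I63, I65, I66, I67, I69]
- group: DRG 6
  all_of:
  - field: hospital_level
    op: in
    value: [tertiary_A]
  - field: cc
    op: in
    value: [cerebral_infarction]
  - field: icd
    op: in
    value: [I60, I63, I65, I66, I67, I69]
- group: DRG 7
  all_of:
  - field: hospital_level
    op: in
    value: [tertiary_B]
  - field: cc
    op: in
    value: [cerebral_infarction]
  - field: icd
    op: in
    value: [I61, I62, I64, I68]
- group: DRG 8
  all_of:
  - field: hospital_level
    op: in
    value: [tertiary_A]
  - field: cc
    op: in
    value: [cerebral_infarction]
  - field: icd
    op: in
    value: [I61, I62, I64, I68]
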