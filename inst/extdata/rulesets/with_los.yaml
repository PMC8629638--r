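# Cerebrovascular DRG rule set using length of stay (7 groups).
# First-match precedence: the hospital-by-LOS rules (DRG 1-4) are listed
# before the tertiary comorbidity/diagnosis rules (DRG 5-7), so DRG 5-7 apply
# to tertiary stays of 14+ days. The residual comorbidity class "other" is
# carried in DRG 5 so the rule set is total.
name: with_los
uses_los: true
fallback: unassigned
rules:
- group: DRG 1
  all_of:
  - field: hospital_level
    op: in
    value: [secondary_B, secondary_A]
  - field: los
    op: lt
    value: 13
- group: DRG 2
  all_of:
  - field: hospital_level
    op: in
    value: [tertiary_B, tertiary_A]
  - field: los
    op: lt
    value: 9
- group: DRG 3
  all_of:
  - field: hospital_level
    op: in
    value: [tertiary_B, tertiary_A]
  - field: los
    op: between
    value: [9, 13]
- group: DRG 4
  all_of:
  - field: hospital_level
    op: in
    value: [secondary_B, secondary_A]
  - field: los
    op: ge
    value: 13
- group: DRG 5
  all_of:
  - field: hospital_level
    op: in
    value: [tertiary_B, tertiary_A]
  - field: cc
    op: in
    value: [ischemic_supply, lacunar_infarction, chronic_ischemia, other]
- group: DRG 6
  all_of:
  - field: hospital_level
    op: in
    value: [tertiary_B, tertiary_A]
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
    value: [tertiary_B, tertiary_A]
  - field: cc
    op: in
    value: [cerebral_infarction]
  - field: icd
    op: in
    value: [I61, I62, I64, I68]
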