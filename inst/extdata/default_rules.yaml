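# Machine-readable data dictionary / ruleset for the depression-registry
# schema. Mirrors regforge::default_ruleset(); edit a copy to customise.
rules:
  - rule_id: phq9_item_domain
    family: attribute_domain
    dimension: validity
    table: questionnaires
    column: [item_1, item_2, item_3, item_4, item_5, item_6, item_7,
             item_8, item_9]
    params:
      domain: [0, 1, 2, 3]
      instrument: PHQ9
      repair: set_missing
  - rule_id: phq9_total_domain
    family: attribute_domain
    dimension: validity
    table: questionnaires
    column: total
    params:
      domain: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16,
               17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27]
      instrument: PHQ9
      repair: flag
  - rule_id: time_spent_domain
    family: attribute_domain
    dimension: validity
    table: contacts
    column: time_spent
    params:
      min: 0
      repair: set_missing
  - rule_id: employment_domain
    family: attribute_domain
    dimension: consistency
    table: demographics
    column: employment_status
    params:
      dictionary:
        "yes": "yes"
        "no": "no"
        "i am employed": "yes"
        "i am looking for a job": "no"
  - rule_id: episode_key_unique
    family: relational_integrity
    dimension: uniqueness
    table: episodes
    column: episode_key
  - rule_id: demographics_unique
    family: relational_integrity
    dimension: uniqueness
    table: demographics
    column: patient_id
  - rule_id: orphan_child_rows
    family: relational_integrity
    dimension: consistency
    table: [contacts, questionnaires]
    column: patient_id
  - rule_id: episode_has_patient
    family: relational_integrity
    dimension: completeness
    table: episodes
    column: patient_id
  - rule_id: birth_before_events
    family: historical_data
    dimension: accuracy
    table: demographics
    column: birth_date
  - rule_id: start_before_end
    family: historical_data
    dimension: consistency
    table: episodes
    column: [start_date, end_date]
  - rule_id: eligibility_before_end
    family: historical_data
    dimension: consistency
    table: episodes
    column: [eligibility_date, end_date]
  - rule_id: enrolled_has_contact
    family: historical_data
    dimension: completeness
    table: episodes
    column: episode_id
  - rule_id: end_requires_eligibility
    family: state_dependent
    dimension: completeness
    table: episodes
    column: eligibility_date
  - rule_id: baseline_before_enrollment
    family: state_dependent
    dimension: consistency
    table: questionnaires
    column: recording_date
  - rule_id: phq9_total_equals_items
    family: attribute_dependency
    dimension: accuracy
    table: questionnaires
    column: total
    params:
      repair: recompute
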