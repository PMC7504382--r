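site:
  name: Semi-detached single-family homes
  date: '2016-08-19'
  construction_system: Facade
  inspection_number: 10
risks:
- code: '010'
  probability: high
  consequence: extremely_damaging
- code: '020'
  probability: medium
  consequence: damaging
- code: '040'
  probability: high
  consequence: damaging
- code: '110'
  probability: medium
  consequence: slightly_damaging
- code: '350'
  probability: medium
  consequence: damaging
- code: '380'
  probability: high
  consequence: slightly_damaging
- code: '420'
  probability: medium
  consequence: damaging
- code: '440'
  probability: high
  consequence: slightly_damaging
- code: '560'
  probability: high
  consequence: slightly_damaging
- code: '570'
  probability: medium
  consequence: slightly_damaging
rubrics:
  relative_risk:
    graphics: 9.0
    setting_out: 5.0
    workers: 9.0
    qualification: 5.0
    auxiliary_systems_level: 15.0
    tools_machinery: 15.0
    material_weight: 3.0
    manageability: 5.0
  borderline:
    height_m: 4.0
    distance_cm: 0.0
  exposure:
    execution_intensity: 9.0
    environment_intensity: 15.0
  economic_capacity:
    individual_organization: 9.0
    team_organization: 5.0
    work_organization: 5.0
    individual_protection: 3.0
    collective_safeguards: 5.0
  participative_interest:
    worker_information: 5.0
    individual_participation: 5.0
    group_participation: 3.0
    external_appearance: 1.0
parameters: []
overrides:
  '010':
    r_r: 8.0
    b_r: 7.0
    e: 15.0
    e_c: 4.0
    p_i: 4.0
    l_s: 12.0
  '020':
    r_r: 10.0
    b_r: 5.0
    e: 12.0
    e_c: 4.0
    p_i: 4.0
    l_s: 12.0
  '040':
    r_r: 9.0
    b_r: 5.0
    e: 12.0
    e_c: 6.0
    p_i: 4.0
    l_s: 14.0
  '110':
    r_r: 10.0
    b_r: 5.0
    e: 12.0
    e_c: 5.0
    p_i: 4.0
    l_s: 15.0
  '350':
    r_r: 7.0
    b_r: 5.0
    e: 12.0
    e_c: 4.0
    p_i: 4.0
    l_s: 16.0
  '380':
    r_r: 8.0
    b_r: 5.0
    e: 13.0
    e_c: 4.0
    p_i: 4.0
    l_s: 13.0
  '420':
    r_r: 10.0
    b_r: 5.0
    e: 16.0
    e_c: 6.0
    p_i: 4.0
    l_s: 12.0
  '440':
    r_r: 9.0
    b_r: 5.0
    e: 15.0
    e_c: 4.0
    p_i: 4.0
    l_s: 12.0
  '560':
    r_r: 8.0
    b_r: 2.0
    e: 12.0
    e_c: 4.0
    p_i: 4.0
    l_s: 15.0
  '570':
    r_r: 10.0
    b_r: 2.0
    e: 14.0
    e_c: 6.0
    p_i: 4.0
    l_s: 16.0
survey:
  personal_cv: 13.0
  responses:
  - respondent: worker
    id: w1
    question: personal_1
    answer: 4
  - respondent: worker
    id: w1
    question: personal_2
    answer: 4
  - respondent: worker
    id: w1
    question: personal_3
    answer: 2
  - respondent: worker
    id: w1
    question: personal_4
    answer: 3
  - respondent: worker
    id: w1
    question: environment_1
    answer: 5
  - respondent: worker
    id: w1
    question: environment_2
    answer: 6
  - respondent: assessor
    id: a
    question: environment_1
    answer: 5
  - respondent: assessor
    id: a
    question: environment_2
    answer: 5
  - respondent: worker
    id: w1
    question: safety_1
    answer: 3
  - respondent: worker
    id: w1
    question: safety_2
    answer: 3
  - respondent: worker
    id: w1
    question: safety_3
    answer: 3
  - respondent: worker
    id: w1
    question: safety_4
    answer: 3
  - respondent: assessor
    id: a
    question: safety_1
    answer: 5
  - respondent: assessor
    id: a
    question: safety_2
    answer: 5
  - respondent: assessor
    id: a
    question: safety_3
    answer: 5
  - respondent: assessor
    id: a
    question: safety_4
    answer: 5
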