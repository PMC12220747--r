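# Cost-input ledger: research-clinic (trial) delivery scenario, 2019 USD.
# Per-visit "untimed" personnel items, laboratory consumable residuals and
# delivered (procurement-inclusive) drug prices are calibrated against the
# published per-arm category totals; one-off amounts are the raw outlays
# whose annuitization (3% discount) reproduces the published annualized
# figures. See the ledger-schema.json shipped alongside.
meta:
  name: trial_2019
  scenario_tag: trial
economic_params:
  exchange_rate_kes_per_usd: 105.50
  inflation_rate: 0.044
  discount_rate: 0.03
  annual_work_hours: 2080
  weekdays_per_year: 231
salaries:
  - {cadre: hiv_testing_counsellor, annual_salary: 9365, currency: USD, scenario_tag: trial}
  - {cadre: clinical_officer, annual_salary: 10841, currency: USD, scenario_tag: trial}
  - {cadre: nurse, annual_salary: 9984, currency: USD, scenario_tag: trial}
  - {cadre: pharmacy_technologist, annual_salary: 10085, currency: USD, scenario_tag: trial}
  - {cadre: hiv_testing_counsellor, annual_salary: 3226, currency: USD, scenario_tag: moh}
  - {cadre: clinical_officer, annual_salary: 7290, currency: USD, scenario_tag: moh}
  - {cadre: nurse, annual_salary: 6101, currency: USD, scenario_tag: moh}
  - {cadre: pharmacy_technologist, annual_salary: 6001, currency: USD, scenario_tag: moh}
unit_prices:
  - {item: prep_30day, price: 6.75, currency: USD}
  - {item: oraquick_hivst, price: 4.27, currency: USD}
  - {item: atomo_hivst, price: 6.17, currency: USD}
  - {item: determine_rapid_test, price: 0.83, currency: USD}
  - {item: creatinine_test, price: 2.51, currency: USD}
items:
  - {name: personnel_untimed, category: personnel_clinical, amount: 20.49352100, basis: per_visit, arm: soc}
  - {name: personnel_untimed, category: personnel_clinical, amount: 16.80552875, basis: per_visit, arm: intervention}
  - {name: prep_drugs_delivered, category: prep_drugs, amount: 7.17116101, basis: per_client_month, arm: soc}
  - {name: prep_drugs_delivered, category: prep_drugs, amount: 7.10456106, basis: per_client_month, arm: intervention}
  - {name: laboratory_consumables, category: laboratory, amount: 5.13351974, basis: per_visit, arm: soc}
  - {name: laboratory_consumables, category: laboratory, amount: 5.71226471, basis: per_visit, arm: intervention}
  - {name: recurrent_training, category: recurrent_training, amount: 2398.93, basis: per_year, arm: soc}
  - {name: recurrent_training, category: recurrent_training, amount: 2677.64, basis: per_year, arm: intervention}
  - {name: clinic_supplies, category: supplies, amount: 315.98, basis: per_year, arm: soc}
  - {name: clinic_supplies, category: supplies, amount: 308.13, basis: per_year, arm: intervention}
  - {name: startup_microplanning, category: startup_microplanning, amount: 1954.456311, basis: one_off, useful_life_years: 1, arm: soc}
  - {name: startup_microplanning, category: startup_microplanning, amount: 2181.533981, basis: one_off, useful_life_years: 1, arm: intervention}
  - {name: personnel_supervision, category: personnel_supervision, amount: 1035.62, basis: per_year, arm: soc}
  - {name: personnel_supervision, category: personnel_supervision, amount: 1067.04, basis: per_year, arm: intervention}
  - {name: capital_equipment, category: capital, amount: 3240.692400, basis: one_off, useful_life_years: 5, arm: soc}
  - {name: capital_equipment, category: capital, amount: 3617.190128, basis: one_off, useful_life_years: 5, arm: intervention}
  - {name: overhead, category: overhead, amount: 580.01, basis: per_year, arm: soc}
  - {name: overhead, category: overhead, amount: 647.40, basis: per_year, arm: intervention}
  - {name: startup_training, category: startup_training, amount: 323.786408, basis: one_off, useful_life_years: 1, arm: soc}
  - {name: startup_training, category: startup_training, amount: 361.398058, basis: one_off, useful_life_years: 1, arm: intervention}
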