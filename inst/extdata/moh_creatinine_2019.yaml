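# Cost-input ledger: public-clinic (Ministry of Health) delivery scenario
# WITH twice-yearly creatinine monitoring, 2019 USD. Equals moh_2019.yaml
# plus the creatinine test kits (2.51 per test, two tests per client-year,
# entered per client-month) and a calibrated per-client-month personnel &
# equipment support item. Calibration conventions as in trial_2019.yaml.
meta:
  name: moh_creatinine_2019
  scenario_tag: moh
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
  - {name: personnel_untimed, category: personnel_clinical, amount: 10.16795083, basis: per_visit, arm: soc}
  - {name: personnel_untimed, category: personnel_clinical, amount: 6.04596248, basis: per_visit, arm: intervention}
  - {name: prep_drugs_delivered, category: prep_drugs, amount: 7.17116101, basis: per_client_month, arm: soc}
  - {name: prep_drugs_delivered, category: prep_drugs, amount: 7.10456106, basis: per_client_month, arm: intervention}
  - {name: laboratory_consumables, category: laboratory, amount: 3.36417763, basis: per_visit, arm: soc}
  - {name: laboratory_consumables, category: laboratory, amount: 2.69155882, basis: per_visit, arm: intervention}
  - {name: recurrent_training, category: recurrent_training, amount: 89.24, basis: per_year, arm: soc}
  - {name: recurrent_training, category: recurrent_training, amount: 99.60, basis: per_year, arm: intervention}
  - {name: clinic_supplies, category: supplies, amount: 376.32, basis: per_year, arm: soc}
  - {name: clinic_supplies, category: supplies, amount: 324.26, basis: per_year, arm: intervention}
  - {name: startup_microplanning, category: startup_microplanning, amount: 77.000000, basis: one_off, useful_life_years: 1, arm: soc}
  - {name: startup_microplanning, category: startup_microplanning, amount: 85.951456, basis: one_off, useful_life_years: 1, arm: intervention}
  - {name: personnel_supervision, category: personnel_supervision, amount: 277.32, basis: per_year, arm: soc}
  - {name: personnel_supervision, category: personnel_supervision, amount: 274.56, basis: per_year, arm: intervention}
  - {name: capital_equipment, category: capital, amount: 1717.664978, basis: one_off, useful_life_years: 5, arm: soc}
  - {name: capital_equipment, category: capital, amount: 1917.248617, basis: one_off, useful_life_years: 5, arm: intervention}
  - {name: overhead, category: overhead, amount: 468.96, basis: per_year, arm: soc}
  - {name: overhead, category: overhead, amount: 523.45, basis: per_year, arm: intervention}
  - {name: startup_training, category: startup_training, amount: 228.495146, basis: one_off, useful_life_years: 1, arm: soc}
  - {name: startup_training, category: startup_training, amount: 255.048544, basis: one_off, useful_life_years: 1, arm: intervention}
  - {name: creatinine_tests, category: laboratory, amount: 0.41833333, basis: per_client_month}
  - {name: creatinine_support, category: personnel_clinical, amount: 0.99174334, basis: per_client_month, arm: soc}
  - {name: creatinine_support, category: personnel_clinical, amount: 0.52248079, basis: per_client_month, arm: intervention}
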