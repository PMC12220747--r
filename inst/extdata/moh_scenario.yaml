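# Scenario: project delivery at public Ministry of Health clinics.
# Research-site salaries are replaced by public-sector salaries and
# allowances (salary_table: moh) and the trial's start-up, supervision,
# capital, overhead, training, supplies and calibrated per-visit items are
# overridden by their public-clinic counterparts. Applying this scenario to
# trial_2019.yaml yields the moh_2019.yaml ledger.
name: moh
salary_table: moh
startup_overrides:
  - {name: personnel_untimed, category: personnel_clinical, amount: 10.16795083, basis: per_visit, arm: soc}
  - {name: personnel_untimed, category: personnel_clinical, amount: 6.04596248, basis: per_visit, arm: intervention}
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
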