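# Scenario add-on: twice-yearly serum creatinine monitoring at public
# clinics. Adds the test kits (2.51 USD per test, two tests per
# client-year, entered per client-month: 2.51 * 2 / 12) and a calibrated
# per-client-month personnel & equipment support item per arm. Salaries
# are untouched, so this add-on commutes with the salary-substitution
# scenario.
name: moh_creatinine
add_items:
  - {name: creatinine_tests, category: laboratory, amount: 0.41833333, basis: per_client_month}
  - {name: creatinine_support, category: personnel_clinical, amount: 0.99174334, basis: per_client_month, arm: soc}
  - {name: creatinine_support, category: personnel_clinical, amount: 0.52248079, basis: per_client_month, arm: intervention}
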