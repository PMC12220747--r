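{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "prepcost cost-input ledger",
  "description": "Structured cost-input document for activity-based micro-costing of PrEP delivery. Amounts are exact decimals in USD or KES; one-off amounts carry a useful life in years and are annuitized by the engine.",
  "type": "object",
  "required": ["meta", "economic_params", "salaries", "unit_prices", "items"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["scenario_tag"],
      "properties": {
        "name": {"type": "string"},
        "scenario_tag": {"type": "string", "description": "Active salary table, e.g. trial or moh"},
        "applied_scenarios": {"type": "array", "items": {"type": "string"}}
      }
    },
    "economic_params": {
      "type": "object",
      "properties": {
        "exchange_rate_kes_per_usd": {"type": "number", "exclusiveMinimum": 0},
        "inflation_rate": {"type": "number", "minimum": 0, "exclusiveMaximum": 1},
        "discount_rate": {"type": "number", "minimum": 0, "exclusiveMaximum": 1},
        "annual_work_hours": {"type": "number", "exclusiveMinimum": 0},
        "weekdays_per_year": {"type": "integer", "exclusiveMinimum": 0}
      }
    },
    "salaries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["cadre", "annual_salary", "scenario_tag"],
        "properties": {
          "cadre": {"enum": ["hiv_testing_counsellor", "clinical_officer", "nurse", "pharmacy_technologist"]},
          "annual_salary": {"type": "number", "exclusiveMinimum": 0},
          "currency": {"enum": ["USD", "KES"], "default": "USD"},
          "scenario_tag": {"type": "string"}
        }
      }
    },
    "unit_prices": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["item", "price"],
        "properties": {
          "item": {"enum": ["prep_30day", "oraquick_hivst", "atomo_hivst", "determine_rapid_test", "creatinine_test"]},
          "price": {"type": "number", "exclusiveMinimum": 0},
          "currency": {"enum": ["USD", "KES"], "default": "USD"}
        }
      }
    },
    "items": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "category", "amount"],
        "properties": {
          "name": {"type": "string"},
          "category": {"enum": ["personnel_clinical", "prep_drugs", "laboratory", "recurrent_training", "supplies", "startup_microplanning", "personnel_supervision", "capital", "overhead", "startup_training"]},
          "amount": {"type": "number", "minimum": 0},
          "basis": {"enum": ["per_year", "per_visit", "per_client_month", "one_off"], "default": "per_year"},
          "currency": {"enum": ["USD", "KES"], "default": "USD"},
          "useful_life_years": {"type": "integer", "minimum": 1, "maximum": 5, "description": "Required iff basis is one_off"},
          "arm": {"enum": ["soc", "intervention"], "description": "Omit for items shared by both arms; untagged fixed items are allocated by visit share"},
          "base_year": {"type": "integer", "description": "Year the amount was priced in; pre-2019 amounts are inflated forward"}
        }
      }
    }
  }
}
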