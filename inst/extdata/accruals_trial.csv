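arm,annual_visits,prep_client_months,visits_per_client_year,bottles_per_visit
soc,304,913,4,3
intervention,340,2039,2,6
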