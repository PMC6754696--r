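emergency_visit: 189.0
outpatient_visit: 40.02
hospital_day: 310.17
surgical_hospital_day: 378.0
phone_call_nurse: 15.0
phone_call_physician: 21.47
contact_minutes: 8.0
nurse_salary_per_min: 0.21
physician_salary_per_min: 0.38
tm_rental_per_patient_month: 3.99
horizon_months: 6.0
leisure_hour: 9.18
visit_absence_hours: 3.3
call_minutes: 10.0
tm_patient_minutes: 5.0
leisure_hours_base: 0.0
inflation_multiplier: 1.0
eur_to_usd: 1.09465
wage_table:
  age_bands:
  - 18.0
  - 30.0
  - 40.0
  - 50.0
  - 60.0
  M:
  - 13.5
  - 15.2
  - 16.8
  - 18.0
  - 18.5
  F:
  - 12.04
  - 13.4
  - 14.6
  - 15.8
  - 16.2
  min: 12.04
  max: 25.23
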