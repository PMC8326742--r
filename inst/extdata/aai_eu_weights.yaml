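# EU-scale Active Ageing Index: domains, indicators and weights.
# Indicator weights sum to 100 within each domain; domain weights sum to 100.
domains:
  - name: employment
    domain_weight: 35
    indicators:
      - {name: employment_rate_55_59, weight: 25, source: BDHS}
      - {name: employment_rate_60_64, weight: 25, source: BDHS}
      - {name: employment_rate_65_69, weight: 25, source: BDHS}
      - {name: employment_rate_70_74, weight: 25, source: BDHS}
  - name: participation_in_society
    domain_weight: 35
    indicators:
      - {name: voluntary_activities, weight: 25, source: primary}
      - {name: care_to_children_grandchildren, weight: 25, source: primary}
      - {name: care_to_older_adults, weight: 30, source: primary}
      - {name: political_participation, weight: 20, source: primary}
  - name: independent_healthy_secure_living
    domain_weight: 10
    indicators:
      - {name: physical_exercise, weight: 10, source: HMSS}
      - {name: access_to_health_dental_care, weight: 20, source: HMSS}
      - {name: independent_living, weight: 20, source: BDHS}
      - {name: relative_median_income, weight: 10, source: HIES}
      - {name: no_poverty_risk, weight: 10, source: HIES}
      - {name: no_material_deprivation, weight: 10, source: primary}
      - {name: physical_safety, weight: 10, source: primary}
      - {name: lifelong_learning, weight: 10, source: primary}
  - name: capacity_enabling_environment
    domain_weight: 20
    indicators:
      - {name: remaining_life_expectancy_50_at_55, weight: 33, source: calculated}
      - {name: share_healthy_life_expectancy_at_55, weight: 23, source: calculated}
      - {name: mental_wellbeing, weight: 17, source: HMSS}
      - {name: use_of_ict, weight: 7, source: HIES}
      - {name: social_connectedness, weight: 13, source: primary}
      - {name: educational_attainment, weight: 7, source: BDHS}
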