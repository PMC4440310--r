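# quotasim default configuration: survey marginals and policy scenario.
# Counts are the published survey table for the French- and Italian-speaking
# cantons (416 usable responses of 506 listed anaesthetists); category totals
# differ because of item non-response.
schema: quotasim-params-v1
survey:
  listed_n: 506
  responded_n: 416
  age_bands:
    "<=35": 97
    "36-55": 254
    ">=56": 56
  gender:
    female: 171
    male: 239
  employment:
    part_time: 97
    full_time: 315
  nationality:
    swiss: 338
    european: 69
    other: 6
  position_by_nationality:
    swiss:
      fixed: 218
      transition: 80
      training: 42
    foreign:
      fixed: 31
      transition: 20
      training: 24
  hospital_by_nationality:
    swiss:
      university: 133
      district: 119
      private: 82
      office: 2
    foreign:
      university: 28
      district: 36
      private: 10
      office: 0
  retirement_age:
    male:
      mean: 62.0
      sd: 3.1
    female:
      mean: 60.0
      sd: 2.8
  training_duration:
    "5": 10
    "6": 32
    "7": 42
    "8": 36
    "9": 31
    "10": 36
    "11": 24
    "12": 15
    "13": 10
    "14": 7
    "15+": 25
scenario:
  start_year: 2014
  horizon_year: 2024
  quota: 66
  fixed_capacity: 244
  training_state_years: 5
  return_policy: true
  # calibrated against the published projection endpoints; see the vignette
  foreign_departure_hazard: 0.39
  legal_retirement_age:
    male: 65
    female: 64
# printed annual medical graduates (Swiss universities), 2000 and 2010
graduates:
  before: 756
  after: 813
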