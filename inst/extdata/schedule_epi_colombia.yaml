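name: EPI-colombia
source_note: >
  Classic EPI infant calendar, Colombia profile: identical to the Nigeria
  profile except the first measles-containing dose is MMR given at 12
  months. Pentavalent doses alias onto the DPT series.
doses:
  - dose: BCG
    series: null
    number: 1
    min_age_days: 0
    min_interval_days: 0
    max_age_days: null
    summarized: true
  - dose: OPV0
    series: null
    number: 1
    min_age_days: 0
    min_interval_days: 0
    max_age_days: 13
    summarized: false
  - dose: OPV1
    series: OPV
    number: 1
    min_age_days: 42
    min_interval_days: 0
    max_age_days: null
    summarized: true
  - dose: OPV2
    series: OPV
    number: 2
    min_age_days: 70
    min_interval_days: 28
    max_age_days: null
    summarized: true
  - dose: OPV3
    series: OPV
    number: 3
    min_age_days: 98
    min_interval_days: 28
    max_age_days: null
    summarized: true
  - dose: DPT1
    series: DPT
    number: 1
    min_age_days: 42
    min_interval_days: 0
    max_age_days: null
    summarized: true
    aliases: [Penta1, PENTA1]
  - dose: DPT2
    series: DPT
    number: 2
    min_age_days: 70
    min_interval_days: 28
    max_age_days: null
    summarized: true
    aliases: [Penta2, PENTA2]
  - dose: DPT3
    series: DPT
    number: 3
    min_age_days: 98
    min_interval_days: 28
    max_age_days: null
    summarized: true
    aliases: [Penta3, PENTA3]
  - dose: MMR1
    series: null
    number: 1
    min_age_days: 365
    min_interval_days: 0
    max_age_days: null
    summarized: true
    aliases: [Measles1, MCV1]
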