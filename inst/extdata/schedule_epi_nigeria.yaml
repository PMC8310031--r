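name: EPI-nigeria
source_note: >
  Classic EPI infant calendar, Nigeria profile: BCG and OPV birth dose from
  birth (OPV0 creditable through 13 days), three-dose OPV and DPT series
  from 6 weeks at 4-week intervals, measles-containing vaccine at 9 months.
  Pentavalent doses alias onto the DPT series.
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
  - dose: MCV1
    series: null
    number: 1
    min_age_days: 270
    min_interval_days: 0
    max_age_days: null
    summarized: true
    aliases: [Measles1, MMR1]
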