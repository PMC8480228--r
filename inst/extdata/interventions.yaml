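# Adoption schedules for emerging livestock CH4 technologies.
# Potentials are illustrative: emissions_2010 x growth x efficacy x adoption
# summed over applicable (system, income group) cells.
inhibitor_tmr:
  systems: [tmr]
  income_groups: [high, upper_middle, lower_middle, low]
  efficacy: 0.30
  adoption: 1.0
inhibitor_grazing_low:
  systems: [intensive_grazing]
  income_groups: [high, upper_middle]
  efficacy: 0.20
  adoption: 0.5
inhibitor_grazing_high:
  systems: [intensive_grazing]
  income_groups: [high, upper_middle, lower_middle]
  efficacy: 0.30
  adoption: 0.5
vaccine_low:
  systems: [tmr, intensive_grazing, extensive]
  income_groups: [high, upper_middle]
  efficacy: 0.30
  adoption: 0.5
vaccine_high:
  systems: [tmr, intensive_grazing, extensive]
  income_groups: [high, upper_middle, lower_middle]
  efficacy: 0.30
  adoption:
    high: 1.0
    upper_middle: 1.0
    lower_middle: 0.5
breeding_low:
  systems: [tmr, intensive_grazing, extensive]
  income_groups: [high]
  efficacy: 0.15
  adoption: 0.5
breeding_high:
  systems: [tmr, intensive_grazing, extensive]
  income_groups: [high, upper_middle, lower_middle]
  efficacy: 0.15
  adoption: 0.5
seaweed_tmr_low:
  systems: [tmr]
  income_groups: [high, upper_middle, lower_middle, low]
  efficacy: 0.20
  adoption: 1.0
seaweed_tmr_high:
  systems: [tmr]
  income_groups: [high, upper_middle, lower_middle, low]
  efficacy: 0.50
  adoption: 1.0
seaweed_grazing_low:
  systems: [intensive_grazing]
  income_groups: [high]
  efficacy: 0.20
  adoption: 0.5
seaweed_grazing_high:
  systems: [intensive_grazing]
  income_groups: [high, upper_middle]
  efficacy: 0.50
  adoption: 0.5
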