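# Simulation presets for the six acclimation conditions (light level x
# growth temperature).  Dip/peak temperatures (deg C) and amplitudes
# (dimensionless NPQ / Y(II)) are the study's fitted values of interest for
# each condition; qe value_low/value_high (values at 10 / 45 deg C) and the
# bell shape parameters are generator realism choices documented in the
# methods vignette.  Copy and edit freely; preset_from_table1() reads this
# file.
presets:
  LL-19C:
    acclimation: {growth_temperature: 19, light_level: LL}
    qe:        {dip_temp: 26.1, dip_value: 0.190, value_low: 0.35, value_high: 0.80}
    slow:      {peak_temp: 40.5, amplitude: 1.347}
    qt2:       {peak_temp: 34.1, amplitude: 0.510}
    qt2_fr_on: {peak_temp: 34.1, amplitude: 0.353}
    y2:        {opt_temp: 28.5, amplitude: 0.292}
  LL-26C:
    acclimation: {growth_temperature: 26, light_level: LL}
    qe:        {dip_temp: 25.9, dip_value: 0.094, value_low: 0.35, value_high: 0.80}
    slow:      {peak_temp: 40.9, amplitude: 0.772}
    qt2:       {peak_temp: 34.6, amplitude: 0.355}
    qt2_fr_on: {peak_temp: 34.5, amplitude: 0.238}
    y2:        {opt_temp: 28.6, amplitude: 0.260}
  LL-29C:
    acclimation: {growth_temperature: 29, light_level: LL}
    qe:        {dip_temp: 26.0, dip_value: 0.073, value_low: 0.35, value_high: 0.80}
    slow:      {peak_temp: 41.1, amplitude: 1.092}
    qt2:       {peak_temp: 34.5, amplitude: 0.625}
    qt2_fr_on: {peak_temp: 35.3, amplitude: 0.384}
    y2:        {opt_temp: 30.4, amplitude: 0.333}
  HL-19C:
    acclimation: {growth_temperature: 19, light_level: HL}
    qe:        {dip_temp: 30.8, dip_value: -0.071, value_low: 0.50, value_high: 1.20}
    slow:      {peak_temp: 39.9, amplitude: 2.747}
    qt2:       {peak_temp: 34.6, amplitude: 0.722}
    qt2_fr_on: {peak_temp: 34.6, amplitude: 0.648}
    y2:        {opt_temp: 30.9, amplitude: 0.368, hi: 35}
  HL-26C:
    acclimation: {growth_temperature: 26, light_level: HL}
    qe:        {dip_temp: 30.4, dip_value: -0.019, value_low: 0.50, value_high: 1.20}
    slow:      {peak_temp: 40.5, amplitude: 1.598}
    qt2:       {peak_temp: 35.5, amplitude: 0.443}
    qt2_fr_on: {peak_temp: 35.2, amplitude: 0.325}
    y2:        {opt_temp: 30.1, amplitude: 0.320, hi: 35}
  HL-29C:
    acclimation: {growth_temperature: 29, light_level: HL}
    qe:        {dip_temp: 30.9, dip_value: -0.027, value_low: 0.50, value_high: 1.20}
    slow:      {peak_temp: 39.8, amplitude: 1.910}
    qt2:       {peak_temp: 36.2, amplitude: 0.738}
    qt2_fr_on: {peak_temp: 35.6, amplitude: 0.590}
    y2:        {opt_temp: 30.9, amplitude: 0.415, hi: 35}
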