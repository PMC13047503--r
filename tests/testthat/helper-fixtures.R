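# Shared fixtures built in code: the bundled extinction table, a short
# acquisition protocol for fast end-to-end tests, and reduced presets.

oxy_table <- builtin_extinction_table()

# compressed protocol: same structure as the default (terminal 50 s
# anoxia, ASL-aligned averaging window), shorter baseline
short_protocol <- function(rate = 6) {
  nirs_protocol(sampling_rate = rate, total_duration = 300,
                anoxia_window = c(240, 290), averaging_window = c(10, 230))
}

tiny_presets <- function(n = 2) {
  p <- builtin_presets()
  for (g in names(p)) p[[g]]$n <- n
  p
}

# a mid-scale tissue state used across forward-model tests
ref_state <- function(baseline = c(0.3, 2e-4), pathlength = 1.8) {
  tissue_state(c(dHb = 17.3, HbO2 = 82.7, oxCCO = 3.404, reCCO = 1.196),
               water_fraction = 0.80, pathlength_cm = pathlength,
               baseline = baseline)
}
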