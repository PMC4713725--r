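# Demo study design for spinedyn::run_report().
#
# Each entry under `groups` is either the name of a shipped preset
# (see ?cohort_presets) or a table of sim_params() arguments.
groups:
  control-EE: control-EE          # elimination declines weekly under EE
  deltaE9-EE: deltaE9-EE          # amyloid model: no EE response
  deltaE9-EE-rescued: deltaE9-EE-rescued  # anti-inflammatory rescue
# Sessions 1 and 2 (days 1 and 8) precede the manipulation and form the
# density baseline; gained-spine survival indexes spines first seen at
# session 3 (formed during the first week under the manipulation).
baseline_sessions: [1, 2]
index_session: 3
tolerance_um: 0.5
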