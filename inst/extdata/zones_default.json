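{
  "comment": "Mechanical-property zone boundaries in the (G%, P%) plane. Each boundary is a list of [g_pct, p_pct] vertices with increasing G% and non-increasing P%; between/beyond vertices the boundary is linear/flat. A point below the amyloid_intermediate curve is amyloid; at or above the intermediate_elastic curve, elastic; otherwise intermediate. Calibrated so exemplar repeat compositions classify as expected; replace to recalibrate.",
  "amyloid_intermediate": [[0, 25], [25, 0], [100, 0]],
  "intermediate_elastic": [[0, 39], [12.5, 26], [20, 19.5], [35, 15], [50, 12], [100, 12]]
}
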