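# Shared expensive runs, computed once per test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# short normoxic paced run (10 beats) at trace resolution
normoxic_run <- function() cached("normoxic10", {
  scn <- scenario("normoxic10", "0D", duration_min = 10 / 60,
                  normoxia_min = Inf,
                  capture_windows_ms = cbind(5000, 9000))
  run_single_cell(scn)
})

# the control ischemia experiment, shortened to 16 min post-occlusion
# (2 min normoxia) -- covers the primary rise, alternans and the plateau
ischemia_run <- function() cached("ischemia16", {
  scn <- scenario("ischemia16", "0D", duration_min = 18, normoxia_min = 2,
                  capture_windows_ms = cbind(2 * 60000 + c(0, 2.5, 5, 10) * 60000,
                                             2 * 60000 + c(0, 2.5, 5, 10) * 60000 + 4000))
  run_single_cell(scn)
})
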