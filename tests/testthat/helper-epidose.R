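# Shared zero-noise commissioning fixture, built once per test run.
# Everything downstream (round trips, acceptance checks) uses these tables.

ed_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (!exists("fx", envir = cache)) {
      truth <- truth_model()
      calib <- calibration_config()
      protocol <- default_commissioning_protocol()
      records <- simulate_measurement_set(truth, protocol)
      ftmr <- derive_ftmr(records)
      tmr <- truth_tmr_table(truth)
      tps <- simulate_tps_points(truth, protocol)
      fc <- build_fc_table(records, tps, calib, ftmr, tmr)
      assign("fx", list(truth = truth, calib = calib, protocol = protocol,
                        records = records, ftmr = ftmr, tmr = tmr,
                        tps = tps, fc = fc,
                        tables = list(ftmr = ftmr, tmr = tmr, fc = fc)),
             envir = cache)
    }
    get("fx", envir = cache)
  }
})

# reconstruct a delivery, keeping only genuine errors (edge-of-axis
# extrapolation on oblique beams is expected and logged as a warning)
ed_reconstruct <- function(delivery, fx = ed_fixture(), ...) {
  suppressWarnings(
    reconstruct_plan(delivery, tables = fx$tables, calib = fx$calib, ...),
    classes = "epidose_warning")
}
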