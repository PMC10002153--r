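# Shared seeded cohort and its measurements, computed once per test run and
# reused by the acceptance blocks (the heavy pieces are the 100 per-phantom
# measurements).

.cohort_env <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (is.null(.cohort_env[[name]])) .cohort_env[[name]] <- fn()
  .cohort_env[[name]]
}

acceptance_cohort <- function() {
  cached("cohort", function() generate_cohort(100, seed = 20230306))
}

acceptance_tda <- function() {
  cached("tda", function() measure_cohort(acceptance_cohort(), "tda"))
}

acceptance_tda_dl <- function() {
  cached("tda_dl", function() measure_cohort(acceptance_cohort(), "tda_dl"))
}

acceptance_severity <- function() {
  cached("severity", function() {
    calibrate_degrade_severity(acceptance_cohort()[1:20], target_iou = 0.9,
                               seed = 77)
  })
}

acceptance_degraded <- function() {
  cached("degraded", function() {
    sev <- acceptance_severity()
    measure_cohort(acceptance_cohort(), "tda", masks = function(ph, i) {
      list(apical = degrade_mask(ph$apical_mask, sev, seed = 5000 + 2 * i),
           coronal = degrade_mask(ph$coronal_mask, sev, seed = 5000 + 2 * i + 1))
    })
  })
}
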