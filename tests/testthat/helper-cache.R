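# Session-level cache so expensive scenario runs are simulated once and
# shared across acceptance blocks.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

subject_a_off <- function() cached("a_off", {
  run_pipeline("subject-A", duration = 90, controller = NULL,
               window = c(20, 80))
})
subject_a_on <- function() cached("a_on", {
  run_pipeline("subject-A", duration = 90, window = c(20, 80))
})
mech_vent_run <- function() cached("mv", {
  run_pipeline("mech-vent", duration = 60)
})
severed_run <- function() cached("sev", {
  run_pipeline("severed-phrenic", duration = 720)
})
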