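# Shared fixtures, built once per test run.  The cell and calibrated
# synapse set are comparatively expensive (the synapse calibration runs
# ~60 small clamp simulations), so tests share one instance.

.fixtures <- new.env(parent = emptyenv())

fixture_cell <- function() {
  if (is.null(.fixtures$cell)) .fixtures$cell <- cell_model()
  .fixtures$cell
}

fixture_synapses <- function() {
  if (is.null(.fixtures$syn)) {
    .fixtures$syn <- configure_synapses(fixture_cell(), seed = 42)
  }
  .fixtures$syn
}

fixture_background <- function() {
  if (is.null(.fixtures$bg)) {
    .fixtures$bg <- background_rates(fixture_synapses(), e_hz = 4.5)
  }
  .fixtures$bg
}

# A one-synapse synapse_set preserving attributes (for unitary-event
# tests).
single_synapse <- function(synapses, which = 1L) {
  out <- synapses[which, ]
  for (a in c("kinetics", "reversals")) attr(out, a) <- attr(synapses, a)
  class(out) <- class(synapses)
  out
}

# Schedule with explicitly given event times.
manual_schedule <- function(times, syn_ids, duration) {
  structure(list(events = tibble::tibble(time = times, syn_id = syn_ids),
                 duration = duration),
            class = "activation_schedule")
}
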