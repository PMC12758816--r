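# Steady-state cycles are expensive (burn-in plus control replay); cache
# them across test files.
.cycle_cache <- new.env(parent = emptyenv())

cached_cycle <- function(preset, ...) {
  key <- paste(preset, paste(c(...), collapse = "_"), sep = "_")
  if (is.null(.cycle_cache[[key]])) {
    p <- slice_preset(preset, ...)
    .cycle_cache[[key]] <- steady_state_cycle(p)
  }
  .cycle_cache[[key]]
}

# Short alias used throughout: the reference parameter set.
p_ref <- function() slice_preset("slice0")

# Fresh scratch directory per call, cleaned up by the session.
withr_like_tempdir <- function() {
  d <- tempfile("epistim-test-")
  dir.create(d)
  d
}
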