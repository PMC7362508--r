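# Shared fixtures: compact phantoms that exercise every pipeline stage.

toySpec <- function(...) {
  args <- list(gridShape = c(40L, 32L, 20L),
               voxelSpacingMm = c(1.5, 1.5, 3.0),
               nFrames = 4L,
               bloodRadiiMm = c(8, 8, 10),
               wallThicknessMm = 3, fatThicknessMm = 2.5,
               pericardiumThicknessMm = 1.5,
               motionAmplitudeMm = 3, contractionFraction = 0.05,
               seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(PhantomSpec, args)
}

toyPhantom <- function(...) {
  spec <- toySpec(...)
  list(spec = spec, data = renderDixon(buildAnatomy(spec), spec))
}

# Default-geometry phantom (acquired grid, 15 frames); built once per run.
defaultPhantomCache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- PhantomSpec()
      cache <<- list(spec = spec, data = renderDixon(buildAnatomy(spec), spec))
    }
    cache
  }
})
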