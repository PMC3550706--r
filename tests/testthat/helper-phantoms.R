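# Shared small fixtures, built in code.

# A tiny deterministic frame with one bright reflector and its trailing
# shadow on a flat dim background; returns the frame plus the reflector
# geometry used by edge and candidate tests.
toy_strut_frame <- function(n_alines = 40, n_depth = 120, rows = 18:22,
                            front = 30, thickness = 4,
                            tissue = 800, strut = 9000, shadow = 20) {
  M <- matrix(tissue, n_alines, n_depth)
  for (a in rows) {
    M[a, front:(front + thickness - 1)] <- strut
    M[a, (front + thickness):n_depth] <- shadow
  }
  list(frame = M, rows = rows, front = front,
       shadow_start = front + thickness)
}

# Cached small suite phantoms (generation is deterministic, so caching
# only saves time within one test run).
local({
  cache <- new.env(parent = emptyenv())
  suite_phantom <<- function(name, n_frames = 16) {
    key <- paste(name, n_frames, sep = "_")
    if (is.null(cache[[key]])) {
      spec <- standard_phantom_suite(n_frames = n_frames)[[name]]
      cache[[key]] <- generate_phantom(spec)
    }
    cache[[key]]
  }
})

scaled_params <- function() scale_parameters(detection_parameters(), 128, 256)
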