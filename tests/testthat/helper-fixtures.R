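# Shared fixtures, all generated in code.

# Small phantom for fast unit tests (~16k lung voxels); cached per session.
small_phantom <- local({
  cache <- new.env(parent = emptyenv())
  function(lesion_fraction = 0.2, seed = 11L) {
    key <- sprintf("lf%.3f_s%d", lesion_fraction, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_scan_pair(phantom_params(
        grid_shape = c(48L, 48L, 48L), lesion_fraction = lesion_fraction,
        seed = seed))
    }
    cache[[key]]
  }
})

# Uniform calibrated volume + full mask on a small grid.
uniform_volume <- function(hu, dims = c(10L, 10L, 10L),
                           spacing = c(0.1, 0.1, 0.1), phase = "P02") {
  scan_volume(array(hu, dim = dims), spacing, phase = phase, calibrated = TRUE)
}

full_mask <- function(volume) {
  voxel_mask(array(TRUE, dim = dim(volume$values)), volume$spacing, "lung")
}

# Random calibrated volume with HU spread over a given range.
random_volume <- function(n_side = 20L, lo = -1000, hi = 100, phase = "P02",
                          spacing = c(0.1, 0.1, 0.1)) {
  vals <- array(runif(n_side^3, lo, hi), dim = rep(n_side, 3))
  scan_volume(vals, spacing, phase = phase, calibrated = TRUE)
}
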