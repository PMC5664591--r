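# Small scene configurations for unit tests: same structure as the field
# defaults but desk-sized so each test runs in well under a second.

tiny_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_plants = 4L, spacing_px = 30L,
         vnir_height = 90L, vnir_bands = 60L,
         swir_height = 84L, swir_bands = 90L,
         noise_sd = 2, seed = seed),
    list(...))
  do.call(scene_config, args)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# Ground-truth plant mask restricted to the region the detector can see
# (above the grass boundary for VNIR, above the bottom crop for SWIR).
truth_above <- function(mask, last_row) {
  if (last_row < nrow(mask)) mask[(last_row + 1L):nrow(mask), ] <- FALSE
  mask
}
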