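# Shared small fixtures, built in code at test time.

# Tiny textured image with structure for registration tests.
helper_texture <- function(seed = 11, dims = c(96L, 96L)) {
  luminance(make_slice_pair(seed, dims = dims,
                            block_dims = c(32L, 32L))$intact_photo)
}

# Smooth displacement field with a given maximum magnitude.
helper_smooth_disp <- function(dims, amplitude, seed) {
  ur <- smooth_noise_field(dims, dims[1] / 10, seed)
  uc <- smooth_noise_field(dims, dims[1] / 10, seed + 100L)
  mx <- max(sqrt(ur^2 + uc^2))
  list(r = ur * amplitude / mx, c = uc * amplitude / mx)
}

# Interior mask eroded by `m` pixels from a logical matrix.
helper_erode <- function(mask, m) {
  sh <- histomri:::shift_edge
  out <- mask
  for (d in seq_len(m)) {
    out <- out & sh(out, 1, 0) & sh(out, -1, 0) &
      sh(out, 0, 1) & sh(out, 0, -1)
  }
  out
}

# Published Table-style ROI summaries used by the comparison tests:
# lateral corticospinal tract (n = 276) vs normal-appearing white
# matter (n = 269).
helper_cst_summaries <- function() list(
  fa = list(a = c(0.17, 0.03), b = c(0.19, 0.07)),
  md = list(a = c(11.23, 1.19), b = c(7.95, 2.52)),   # x1e-5 mm^2/s
  t1 = list(a = c(714.8, 31.4), b = c(672.1, 23.6)),  # ms
  t2 = list(a = c(34.2, 2.11), b = c(30.9, 1.31)))    # ms

helper_cst_n <- function() c(a = 276L, b = 269L)
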