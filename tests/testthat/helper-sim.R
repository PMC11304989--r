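# A one-nodule phantom layout at the default benchmark geometry.
with_seed_layout <- function(seed, density) {
  grid_dim <- c(40, 64, 64)
  spacing <- c(3, 1.875, 1.875)
  ext <- grid_dim * spacing
  nod <- tibble::tibble(
    shape = "spherical", diameter_mm = 12, density_hu = density,
    x = 0.29 * ext[3], y = 0.48 * ext[2], z = 0.5 * ext[1]
  )
  scan_layout("dens", nod, grid_dim = grid_dim, spacing = spacing,
              noise_hu = 10, seed = seed)
}
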