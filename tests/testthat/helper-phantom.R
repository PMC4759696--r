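# Small phantom configurations shared across tests. All fixtures are built in
# code; nothing is read from disk.

# A quick phantom: one lymph lumen and one blood vessel in a 96 x 48 x 48
# grid, 4 repeats. Grid extents: z 0..760 um, x/y 0..940 um.
small_spec <- function(...) {
  args <- list(
    nz = 96L, nx = 48L, ny = 48L, n_repeats = 4L,
    lymph_tubes = list(phantom_tube(rbind(c(460, 470, 70), c(460, 470, 870)),
                                    60, 0.1)),
    blood_tubes = list(phantom_tube(rbind(c(600, 50, 300), c(600, 890, 300)),
                                    40, 1.0)),
    topography_amplitude_um = 0
  )
  over <- list(...)
  args[names(over)] <- over    # plain replacement; list-valued args included
  do.call(phantom_spec, args)
}

# Homogeneous block: flat surface at the top, no epidermis contrast, no tubes.
homogeneous_spec <- function(mu = 1.5, sigma = 0, nz = 96L, nx = 48L, ny = 48L,
                             n_repeats = 2L) {
  phantom_spec(nz = nz, nx = nx, ny = ny, n_repeats = n_repeats,
               lymph_tubes = list(), blood_tubes = list(),
               epidermis_multiplier = 1, epidermis_thickness_um = 0,
               mu_per_mm = mu, surface_depth_um = 0,
               topography_amplitude_um = 0, noise_sigma = sigma)
}

# Ground-truth en-face projection of a 3D mask within a slab below the EDJ.
gt_slab_projection <- function(truth, slab_um, axial_pitch_um) {
  nz <- dim(truth$lymph_mask)[1]
  nx <- dim(truth$lymph_mask)[2]; ny <- dim(truth$lymph_mask)[3]
  gt <- matrix(FALSE, nx, ny)
  z0_off <- floor(slab_um[1] / axial_pitch_um)
  z1_off <- ceiling(slab_um[2] / axial_pitch_um) - 1L
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    z0 <- truth$edj_vox[ix, iy] + z0_off
    z1 <- min(truth$edj_vox[ix, iy] + z1_off, nz)
    if (z0 <= z1) gt[ix, iy] <- any(truth$lymph_mask[z0:z1, ix, iy])
  }
  gt
}

blood_projection <- function(truth) apply(truth$blood_mask, c(2, 3), any)
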