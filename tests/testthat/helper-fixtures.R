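# Shared fixtures: a small array and grid keep per-frame cost low in the
# module tests; independent brute-force oracles for the beamformer and
# the morphology.

small_geom <- function() {
  transducer_geometry(n_elements = 32L, pitch = 0.3)
}

small_grid <- function(geom = small_geom(), sound_speed = 1540) {
  image_grid(geom, sound_speed, z_min = 6, z_max = 18,
             axial_spacing = 2 * sound_speed / 1000 /
               geom$sampling_frequency)
}

noise_free_medium <- function(sound_speed = 1540) {
  structure(list(name = "noise_free", sound_speed = sound_speed,
                 amplitude_scale = 1, noise_sigma = 0, clutter_level = 0,
                 attenuation = 0, deflection_sigma = 0),
            class = "medium_preset")
}

# naive triple-loop delay-and-sum, independent of the compiled kernel
das_oracle <- function(frame, geom, grid, sound_speed, f_number,
                       apodization = "hann") {
  ex <- element_positions(geom)
  px <- grid_lateral(grid)
  pz <- grid_axial(grid)
  c_mm_us <- sound_speed / 1000
  fs <- frame$sampling_frequency
  ns <- nrow(frame$samples)
  out <- matrix(0, length(pz), length(px))
  for (ix in seq_along(px)) {
    for (iz in seq_along(pz)) {
      half_ap <- if (f_number > 0) pz[iz] / (2 * f_number) else Inf
      acc <- 0
      wsum <- 0
      for (ie in seq_along(ex)) {
        dx <- ex[ie] - px[ix]
        if (is.finite(half_ap) && abs(dx) > half_ap) next
        w <- if (apodization == "hann" && is.finite(half_ap))
          0.5 * (1 + cos(pi * dx / half_ap)) else 1
        s <- sqrt(dx^2 + pz[iz]^2) / c_mm_us * fs
        s0 <- floor(s)
        if (s0 < 0 || s0 + 2 > ns) next
        frac <- s - s0
        acc <- acc + w * ((1 - frac) * frame$samples[s0 + 1, ie] +
                            frac * frame$samples[s0 + 2, ie])
        wsum <- wsum + w
      }
      out[iz, ix] <- if (wsum > 0) acc / wsum else 0
    }
  }
  out
}

# brute-force binary opening with a diamond (disk) structuring element
morph_open_oracle <- function(mask, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[abs(offs$dr) + abs(offs$dc) <= radius, ]
  nr <- nrow(mask)
  nc <- ncol(mask)
  get <- function(m, r, c) {
    if (r < 1 || r > nr || c < 1 || c > nc) FALSE else m[r, c]
  }
  er <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    er[r, c] <- all(mapply(function(dr, dc) get(mask, r + dr, c + dc),
                           offs$dr, offs$dc))
  }
  di <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    di[r, c] <- any(mapply(function(dr, dc) get(er, r + dr, c + dc),
                           offs$dr, offs$dc))
  }
  di
}

# synthetic envelope image: Gaussian blobs over a uniform noise floor
blob_image <- function(grid, blobs, floor_level = 0, seed = NULL) {
  lat <- grid_lateral(grid)
  ax <- grid_axial(grid)
  env <- matrix(floor_level, grid$n_axial, grid$n_lateral)
  if (!is.null(seed)) {
    set.seed(seed)
    env <- env * matrix(runif(length(env)), nrow(env))
  }
  for (b in blobs) {
    env <- env + b$amp *
      outer(exp(-(ax - b$axial)^2 / (2 * b$sigma_ax^2)),
            exp(-(lat - b$lateral)^2 / (2 * b$sigma_lat^2)))
  }
  pa_image(env, grid)
}

make_detection <- function(lateral, axial, found = TRUE, area = 50L) {
  structure(list(found = found,
                 tip_pixel = c(NA_real_, NA_real_),
                 tip_mm = c(lateral = lateral, axial = axial),
                 label_area = area),
            class = "tip_detection")
}
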