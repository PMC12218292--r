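# Shared fixtures: all synthetic, built in code at test time.

# noise-free acquisition with a flat nuclear field (isolates estimators);
# any default can be overridden
quiet_acq <- function(...) {
  args <- list(poisson = FALSE, read_noise_sd = 0, nucleus_level = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(acquisition_params, args)
}

# acquisition with noise but a flat nuclear field (median background exact)
flat_acq <- function(...) acquisition_params(nucleus_level = 0, ...)

# design planting a single straight filament of fixed length
straight_design <- function(L, photons = 25000) {
  strain_design("fix",
                filament_length_px = list(mean = L, sd = 1e-6,
                                          min = L - 0.1, max = L + 0.1),
                filament_photons = list(mean = photons, sd = 0.001),
                filament_curvature = 0)
}

# a smooth Gaussian ridge rendered through a pixel centre at a given angle
test_ridge <- function(theta, c0 = 25, fwhm = 2, L = 36, n = 50,
                       photons = 1e4) {
  s <- fwhm / 2.355
  u <- c(cos(theta), sin(theta))
  bb <- list(p0 = c(c0, c0) - u * L / 2, p1 = c(c0, c0),
             p2 = c(c0, c0) + u * L / 2)
  sp <- filamentr:::filament_splats(bb, photons, s, 1)
  filamentr:::render_splats(sp, c(n, n, 1), s, 0)[, , 1]
}

# hand-built cell-record table
make_records <- function(df) {
  need <- c("cell_id", "strain", "batch", "category", "has_filament",
            "filament_length_px", "filament_intensity", "spot_intensity")
  for (nm in setdiff(need, names(df))) {
    df[[nm]] <- switch(nm,
      cell_id = sprintf("c%03d", seq_len(nrow(df))),
      batch = 1L,
      has_filament = as.integer(df$category %in% c("Simple", "Complex")),
      NA_real_)
  }
  filamentr:::new_cell_records(tibble::as_tibble(df[, need]))
}

# brute-force Benjamini-Hochberg step-up (independent oracle)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, p[o[i]] * m / i)
    q[o[i]] <- min(run, 1)
  }
  q
}

# brute-force pixel-neighbourhood skeleton feature counts (oracle for
# skeleton_features on junction-free inputs uses graph tracing; this one
# only counts from local neighbourhoods)
neighborhood_counts <- function(skel) {
  ny <- nrow(skel); nx <- ncol(skel)
  deg <- matrix(0L, ny, nx)
  for (r in seq_len(ny)) for (cc in seq_len(nx)) {
    if (!skel[r, cc]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1 && rr <= ny && ccc >= 1 && ccc <= nx && skel[rr, ccc])
        deg[r, cc] <- deg[r, cc] + 1L
    }
  }
  list(endpoints = sum(deg == 1 & skel),
       junction_px = sum(deg >= 3 & skel))
}
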