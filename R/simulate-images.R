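#' @title Synthetic nucleus renderer
#' @description Internal helpers shared by [render_cell()] and
#'   [simulate_experiment()]. Images are arrays indexed `[row, col, slice]`
#'   with row = y, col = x; continuous coordinates are 1-based pixel centres.
#' @noRd
NULL

new_image_stack <- function(raw, deconv, acq) {
  structure(list(raw = raw, deconv = deconv,
                 pixel_nm = acq$pixel_nm, z_step_nm = acq$z_step_nm),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$raw)
  cat(sprintf("<image_stack> %d x %d px, %d slices (%g nm/px, %g nm z-step)\n",
              d[1], d[2], d[3], x$pixel_nm, x$z_step_nm))
  invisible(x)
}

# Gaussian density of each splat centre at integer pixel coordinates.
# Returns an n_splat x n_coord matrix; rows sum to ~1 for in-crop centres.
splat_profiles <- function(centers, sigma, n) {
  if (sigma <= 0) {
    # delta: all mass on the nearest pixel
    out <- matrix(0, length(centers), n)
    idx <- pmin(pmax(round(centers), 1), n)
    out[cbind(seq_along(centers), idx)] <- 1
    return(out)
  }
  d <- outer(centers, seq_len(n), "-")
  exp(-d^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
}

# Accumulate Gaussian splats onto a stack. splats: data.frame-like with
# x, y, z (pixel/slice coords) and photons (total per splat).
render_splats <- function(splats, dim_yxz, sigma_xy, sigma_z) {
  ny <- dim_yxz[1]; nx <- dim_yxz[2]; nz <- dim_yxz[3]
  out <- array(0, dim_yxz)
  if (NROW(splats$x) == 0) return(out)
  gx <- splat_profiles(splats$x, sigma_xy, nx)
  gy <- splat_profiles(splats$y, sigma_xy, ny)
  gz <- splat_profiles(splats$z, sigma_z, nz)
  for (k in seq_len(nz)) {
    w <- splats$photons * gz[, k]
    out[, , k] <- out[, , k] + crossprod(gy * w, gx)
  }
  out
}

# Quadratic Bezier backbone sampled densely; returns list with sample
# points (x, y), per-sample arc weights and total in-segment path length.
bezier_backbone <- function(p0, p1, p2, n_samp) {
  t <- seq(0, 1, length.out = n_samp)
  bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  seg <- sqrt(diff(bx)^2 + diff(by)^2)
  list(x = bx, y = by, length = sum(seg))
}

# Draw a truncated normal by resampling (bounds optional).
rtruncnorm1 <- function(n, mean, sd, min = 0, max = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- out < min | out > max
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < min | out > max
  }
  out
}

# Sample a filament backbone inside the crop: random centre near the
# nucleus middle, random orientation, bounded-curvature quadratic Bezier.
draw_backbone <- function(length_px, crop_px, center = NULL, theta = NULL,
                          curvature = 0.15) {
  ctr <- center %||% ((crop_px + 1) / 2 + runif(2, -4, 4))
  theta <- theta %||% runif(1, 0, pi)
  u <- c(cos(theta), sin(theta))
  half <- length_px / 2
  p0 <- ctr - half * u
  p2 <- ctr + half * u
  # curvature bound: control-point offset a bounded fraction of the chord
  perp <- c(-u[2], u[1])
  p1 <- (p0 + p2) / 2 + perp * runif(1, -curvature, curvature) * length_px
  # keep inside the crop with a 3-px margin where possible
  lo <- 3; hi <- crop_px - 2
  clampv <- function(p) pmin(pmax(p, lo), hi)
  list(p0 = clampv(p0), p1 = clampv(p1), p2 = clampv(p2))
}

filament_splats <- function(bb, photons, tube_sigma_px, z_center,
                            samples_per_px = 8) {
  # two passes: coarse arc length first, then dense resampling so the
  # splat spacing is fine enough for a smooth tube
  coarse <- bezier_backbone(bb$p0, bb$p1, bb$p2, 64)
  n_samp <- max(32L, ceiling(coarse$length * samples_per_px))
  b <- bezier_backbone(bb$p0, bb$p1, bb$p2, n_samp)
  list(x = b$x, y = b$y, z = rep(z_center, n_samp),
       photons = rep(photons / n_samp, n_samp),
       tube_sigma_px = tube_sigma_px, length = b$length)
}

render_channel <- function(struct_splats, tube_sigmas, acq, sigma_xy, sigma_z) {
  dim_yxz <- c(acq$crop_px, acq$crop_px, acq$n_slices)
  clean <- array(0, dim_yxz)
  for (i in seq_along(struct_splats)) {
    s <- struct_splats[[i]]
    eff_xy <- sqrt(sigma_xy^2 + tube_sigmas[i]^2)
    clean <- clean + render_splats(s, dim_yxz, eff_xy, sigma_z)
  }
  clean
}

render_background <- function(acq, nucleus_center, sigma_xy_extra = 0) {
  ny <- acq$crop_px; nx <- acq$crop_px; nz <- acq$n_slices
  # diffuse nuclear pool: unnormalised Gaussian of given peak height
  sx <- sqrt(acq$nucleus_sigma_px^2 + sigma_xy_extra^2)
  gx <- exp(-(seq_len(nx) - nucleus_center[1])^2 / (2 * sx^2))
  gy <- exp(-(seq_len(ny) - nucleus_center[2])^2 / (2 * sx^2))
  gz <- exp(-(seq_len(nz) - (nz + 1) / 2)^2 / (2 * acq$nucleus_sigma_z_slices^2))
  blob <- outer(gy, gx)
  out <- array(0, c(ny, nx, nz))
  for (k in seq_len(nz)) out[, , k] <- acq$background_level +
      acq$nucleus_level * gz[k] * blob
  out
}

apply_noise <- function(clean, acq) {
  noisy <- clean
  if (acq$poisson) noisy <- array(rpois(length(clean), lambda = clean),
                                  dim = dim(clean))
  if (acq$read_noise_sd > 0)
    noisy <- noisy + array(rnorm(length(clean), 0, acq$read_noise_sd),
                           dim = dim(clean))
  noisy
}

#' Render one synthetic nucleus crop
#'
#' Renders a single cell of the given archetype: a diffuse nuclear
#' background, plus curvilinear filament(s) with a Gaussian cross-section
#' (FWHM 2 px before the PSF, matching the pipeline's width parameter)
#' and/or diffraction-limited foci, convolved with a Gaussian PSF (the
#' convolution of Gaussian sources with a Gaussian PSF is carried out
#' analytically). Poisson shot noise and Gaussian read noise are applied
#' last. Two channels are rendered with independent noise: `raw` (full PSF,
#' used for quantification) and `deconv` (narrower PSF, used for
#' segmentation).
#'
#' @param design A [strain_design()].
#' @param archetype One of `"simple"`, `"complex"`, `"foci_only"`,
#'   `"nothing"`.
#' @param acq An [acquisition_params()].
#' @param seed Integer seed; identical inputs give identical output.
#' @param batch Batch index (applies the design's intensity factor).
#' @return List with `stack` (class `image_stack`) and `truth`: archetype,
#'   per-structure planted photons, realised (in-crop, pre-noise) photons,
#'   true backbone path length (px and nm), foci table, plus the noise-free
#'   `clean_structure`, `clean` and `background` arrays of the raw channel
#'   and their `deconv` counterparts.
#' @examples
#' cell <- render_cell(strain_design("WT"), "simple", acquisition_params(),
#'                     seed = 1)
#' cell$truth$true_length_px
#' @export
render_cell <- function(design, archetype, acq = acquisition_params(),
                        seed = 1L, batch = 1L) {
  stopifnot(inherits(design, "strain_design"),
            inherits(acq, "acquisition_params"))
  if (!archetype %in% cell_archetypes)
    abort(paste0("unknown archetype: ", archetype))
  set.seed(as.integer(seed))
  bfac <- design$batch_intensity_factor[
    ((as.integer(batch) - 1L) %% length(design$batch_intensity_factor)) + 1L]

  crop <- acq$crop_px
  zc <- (acq$n_slices + 1) / 2
  nucleus_center <- (crop + 1) / 2 + runif(2, -2, 2)
  tube_sigma <- 2 / (2 * sqrt(2 * log(2)))   # FWHM 2 px before the PSF

  struct <- list(); tube_sigmas <- numeric(0)
  backbones <- list(); planted <- numeric(0)
  foci <- tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                 photons = numeric(0))
  n_filaments <- switch(archetype, simple = 1L, complex = 2L, 0L)
  first_bb <- NULL
  first_theta <- NULL
  for (i in seq_len(n_filaments)) {
    len <- rtruncnorm1(1, design$filament_length_px$mean,
                       design$filament_length_px$sd,
                       design$filament_length_px$min,
                       design$filament_length_px$max)
    curv <- design$filament_curvature %||% 0.15
    if (i == 1L) {
      first_theta <- runif(1, 0, pi)
      bb <- draw_backbone(len, crop, theta = first_theta, curvature = curv)
      first_bb <- bb
    } else {
      # the second filament of a complex cell crosses or branches off the
      # first: its orientation differs by 30-150 degrees and its centre
      # sits close to the first backbone, so the pair reads as a crossed
      # or multi-component structure rather than one longer filament
      theta2 <- (first_theta + runif(1, pi / 6, 5 * pi / 6)) %% pi
      ctr2 <- (first_bb$p0 + first_bb$p2) / 2 + runif(2, -4, 4)
      bb <- draw_backbone(len, crop, center = ctr2, theta = theta2,
                          curvature = curv)
    }
    ph <- rtruncnorm1(1, design$filament_photons$mean,
                      design$filament_photons$sd) * bfac
    zf <- zc + runif(1, -0.5, 0.5)
    sp <- filament_splats(bb, ph, tube_sigma, zf)
    struct <- c(struct, list(sp))
    tube_sigmas <- c(tube_sigmas, tube_sigma)
    backbones <- c(backbones, list(bb))
    planted <- c(planted, ph)
  }
  if (archetype == "foci_only") {
    k <- sample(design$foci_count$min:design$foci_count$max, 1)
    for (i in seq_len(k)) {
      ph <- rtruncnorm1(1, design$focus_photons$mean,
                        design$focus_photons$sd) * bfac
      pos <- (crop + 1) / 2 + runif(2, -12, 12)
      sp <- list(x = pos[1], y = pos[2], z = zc + runif(1, -1, 1),
                 photons = ph)
      struct <- c(struct, list(sp))
      tube_sigmas <- c(tube_sigmas, 0)
      planted <- c(planted, ph)
      foci <- bind_rows(foci, tibble(x = pos[1], y = pos[2], z = sp$z,
                                     photons = ph))
    }
  }

  clean_struct_raw <- render_channel(struct, tube_sigmas, acq,
                                     acq$psf_sigma_xy_px,
                                     acq$psf_sigma_z_slices)
  clean_struct_dec <- render_channel(struct, tube_sigmas, acq,
                                     acq$deconv_psf_sigma_xy_px,
                                     acq$deconv_psf_sigma_z_slices)
  bg_raw <- render_background(acq, nucleus_center, acq$psf_sigma_xy_px)
  bg_dec <- render_background(acq, nucleus_center, acq$deconv_psf_sigma_xy_px)
  clean_raw <- bg_raw + clean_struct_raw
  clean_dec <- bg_dec + clean_struct_dec
  raw <- apply_noise(clean_raw, acq)
  dec <- apply_noise(clean_dec, acq)

  true_len <- if (n_filaments >= 1)
    sum(map_dbl(struct[seq_len(n_filaments)], "length")) else NA_real_
  truth <- list(
    archetype = archetype,
    batch_factor = bfac,
    n_filaments = n_filaments,
    backbones = backbones,
    true_length_px = true_len,
    true_length_nm = true_len * acq$pixel_nm,
    planted_photons = planted,
    total_planted_photons = sum(planted),
    realized_photons = sum(clean_struct_raw),
    clip_loss = sum(planted) - sum(clean_struct_raw),
    foci = foci,
    clean_structure = clean_struct_raw,
    clean = clean_raw,
    background = bg_raw,
    clean_structure_deconv = clean_struct_dec,
    background_deconv = bg_dec
  )
  list(stack = new_image_stack(raw, dec, acq), truth = truth)
}

#' Simulate a multi-strain imaging experiment
#'
#' Draws per-cell archetypes from each strain's category probabilities,
#' assigns cells to batches round-robin within strain, and renders every
#' cell with [render_cell()] using one child seed per cell (parallel-safe
#' determinism: the same master seed always yields the same dataset).
#'
#' @param designs List of [strain_design()] with unique names.
#' @param n_cells Cells per strain.
#' @param n_batches Number of batches.
#' @param acq An [acquisition_params()].
#' @param seed Master integer seed.
#' @return List with `cells` (list of `image_stack`), `metadata` tibble
#'   (`cell_id`, `strain`, `batch`) and `truth` tibble (one row per cell:
#'   archetype, true length, planted/realised photons, focus count and
#'   brightest-focus photons; rendering arrays are kept in `cells_truth`
#'   only if `keep_arrays = TRUE`).
#' @param keep_arrays Keep per-cell truth lists (with clean arrays) in the
#'   result as `cells_truth`? Default `FALSE` to stay lean.
#' @examples
#' sim <- simulate_experiment(default_strain_designs()[c("WT", "mutA")],
#'                            n_cells = 3, seed = 1)
#' sim$metadata
#' @export
simulate_experiment <- function(designs, n_cells, n_batches = 3,
                                acq = acquisition_params(), seed = 1L,
                                keep_arrays = FALSE) {
  stopifnot(n_cells >= 1)
  nms <- map_chr(designs, "name")
  if (anyDuplicated(nms)) abort("duplicate strain names in designs")
  set.seed(as.integer(seed))
  total <- length(designs) * n_cells
  child_seeds <- sample.int(.Machine$integer.max - 1L, total)
  meta <- tibble(
    cell_id = sprintf("cell_%04d", seq_len(total)),
    strain = rep(nms, each = n_cells),
    batch = rep_len(rep(seq_len(n_batches)), total)
  )
  # archetypes drawn from the master stream (before per-cell streams)
  meta$archetype <- unlist(map(designs, function(d)
    sample(cell_archetypes, n_cells, replace = TRUE, prob = d$category_probs)))
  cells <- vector("list", total)
  truths <- vector("list", total)
  for (i in seq_len(total)) {
    d <- designs[[match(meta$strain[i], nms)]]
    out <- render_cell(d, meta$archetype[i], acq,
                       seed = child_seeds[i], batch = meta$batch[i])
    cells[[i]] <- out$stack
    truths[[i]] <- out$truth
  }
  truth_tbl <- tibble(
    cell_id = meta$cell_id,
    strain = meta$strain,
    batch = meta$batch,
    archetype = meta$archetype,
    true_length_px = map_dbl(truths, "true_length_px"),
    total_planted_photons = map_dbl(truths, "total_planted_photons"),
    realized_photons = map_dbl(truths, "realized_photons"),
    n_foci = map_int(truths, ~ nrow(.x$foci)),
    brightest_focus_photons = map_dbl(truths, function(tr)
      if (nrow(tr$foci)) max(tr$foci$photons) else NA_real_),
    batch_factor = map_dbl(truths, "batch_factor")
  )
  out <- list(cells = cells, metadata = meta[, c("cell_id", "strain", "batch")],
              truth = truth_tbl, acq = acq)
  if (keep_arrays) out$cells_truth <- truths
  out
}

#' Simulate cell records directly (no rendering)
#'
#' Draws the per-cell feature table that the imaging pipeline would produce
#' — category, filament length/intensity for Simple cells, brightest-focus
#' intensity for Foci cells — straight from the strain-design distributions.
#' This record-level generator carries the same statistical structure as
#' the full image simulation (category probabilities, photon budgets,
#' multiplicative batch factors) and is what the statistical-calibration
#' studies run on, where rendering and re-measuring thousands of stacks
#' would add nothing but measurement noise.
#'
#' @inheritParams simulate_experiment
#' @return A `cell_record` tibble (see [build_cell_records()]).
#' @examples
#' simulate_cell_records(default_strain_designs()[1:2], n_cells = 5, seed = 1)
#' @export
simulate_cell_records <- function(designs, n_cells, n_batches = 3,
                                  seed = 1L) {
  stopifnot(n_cells >= 1)
  nms <- map_chr(designs, "name")
  if (anyDuplicated(nms)) abort("duplicate strain names in designs")
  set.seed(as.integer(seed))
  total <- length(designs) * n_cells
  strain <- rep(nms, each = n_cells)
  batch <- rep_len(seq_len(n_batches), total)
  cat_map <- c(simple = "Simple", complex = "Complex",
               foci_only = "Foci", nothing = "Nothing")
  arch <- character(total)
  len <- fint <- sint <- rep(NA_real_, total)
  for (j in seq_along(designs)) {
    d <- designs[[j]]
    rows <- which(strain == nms[j])
    arch[rows] <- sample(cell_archetypes, length(rows), replace = TRUE,
                         prob = d$category_probs)
    bfac <- d$batch_intensity_factor[
      ((batch[rows] - 1L) %% length(d$batch_intensity_factor)) + 1L]
    si <- rows[arch[rows] == "simple"]
    if (length(si)) {
      len[si] <- rtruncnorm1(length(si), d$filament_length_px$mean,
                             d$filament_length_px$sd,
                             d$filament_length_px$min,
                             d$filament_length_px$max)
      fint[si] <- rtruncnorm1(length(si), d$filament_photons$mean,
                              d$filament_photons$sd) *
        bfac[match(si, rows)]
    }
    fo <- rows[arch[rows] == "foci_only"]
    if (length(fo)) {
      kmax <- d$foci_count$max
      k <- sample(d$foci_count$min:kmax, length(fo), replace = TRUE)
      draws <- matrix(rtruncnorm1(length(fo) * kmax, d$focus_photons$mean,
                                  d$focus_photons$sd), nrow = length(fo))
      # brightest of the cell's k foci
      sint[fo] <- vapply(seq_along(fo), function(i)
        max(draws[i, seq_len(k[i])]), numeric(1)) * bfac[match(fo, rows)]
    }
  }
  new_cell_records(tibble(
    cell_id = sprintf("cell_%04d", seq_len(total)), strain = strain,
    batch = batch, category = unname(cat_map[arch]),
    has_filament = as.integer(arch %in% c("simple", "complex")),
    filament_length_px = len, filament_intensity = fint,
    spot_intensity = sint))
}
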