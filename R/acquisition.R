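#' Acquisition geometry and camera model
#'
#' Bundles the physical calibration of the microscope emulated by the
#' synthetic renderer: a wide-field system with a 6.5 µm camera pixel behind
#' a 100x objective (65 nm effective pixel), z-stacks with a 200 nm step,
#' nuclei cropped to 50 x 50 pixel tiles, a Gaussian PSF, and an sCMOS noise
#' model (Poisson shot noise plus additive Gaussian read noise).
#'
#' Two PSF widths are carried: `psf_sigma_xy_px` / `psf_sigma_z_slices` for
#' the raw channel used for intensity quantification, and the narrower
#' `deconv_psf_sigma_*` pair for the "deconvolved" channel that segmentation
#' runs on (deconvolution is emulated by rendering with a narrower PSF; no
#' iterative restoration is performed).
#'
#' @param pixel_nm Effective xy pixel size in nm (default 65, i.e. a 6.5 µm
#'   camera pixel at 100x; see [pixel_size_nm()]).
#' @param z_step_nm Axial step between slices in nm.
#' @param crop_px Side of the square nucleus crop in pixels (>= 16).
#' @param n_slices Number of z-slices in a stack.
#' @param psf_sigma_xy_px,psf_sigma_z_slices Gaussian PSF sigmas of the raw
#'   channel, in pixels / slices.
#' @param deconv_psf_sigma_xy_px,deconv_psf_sigma_z_slices PSF sigmas of the
#'   emulated deconvolved channel.
#' @param background_level Flat camera/cytoplasm offset, photons per voxel.
#' @param nucleus_level Peak height of the diffuse nuclear pool above the
#'   offset, photons per voxel.
#' @param nucleus_sigma_px,nucleus_sigma_z_slices Extent of the diffuse
#'   nuclear blob.
#' @param read_noise_sd Gaussian read noise standard deviation, photons.
#' @param poisson Apply Poisson shot noise?
#'
#' @return An object of class `acquisition_params` (a validated list).
#' @examples
#' acq <- acquisition_params()
#' acq$pixel_nm
#' @export
acquisition_params <- function(pixel_nm = 65,
                               z_step_nm = 200,
                               crop_px = 50L,
                               n_slices = 9L,
                               psf_sigma_xy_px = 1.3,
                               psf_sigma_z_slices = 1.3,
                               deconv_psf_sigma_xy_px = 0.7,
                               deconv_psf_sigma_z_slices = 0.8,
                               background_level = 100,
                               nucleus_level = 30,
                               nucleus_sigma_px = 18,
                               nucleus_sigma_z_slices = 4,
                               read_noise_sd = 2,
                               poisson = TRUE) {
  acq <- list(
    pixel_nm = pixel_nm, z_step_nm = z_step_nm,
    crop_px = as.integer(crop_px), n_slices = as.integer(n_slices),
    psf_sigma_xy_px = psf_sigma_xy_px,
    psf_sigma_z_slices = psf_sigma_z_slices,
    deconv_psf_sigma_xy_px = deconv_psf_sigma_xy_px,
    deconv_psf_sigma_z_slices = deconv_psf_sigma_z_slices,
    background_level = background_level,
    nucleus_level = nucleus_level,
    nucleus_sigma_px = nucleus_sigma_px,
    nucleus_sigma_z_slices = nucleus_sigma_z_slices,
    read_noise_sd = read_noise_sd,
    poisson = isTRUE(poisson)
  )
  if (acq$pixel_nm <= 0 || acq$z_step_nm <= 0)
    abort("pixel_nm and z_step_nm must be positive lengths")
  if (acq$crop_px < 16L)
    abort("crop_px must be at least 16")
  if (acq$n_slices < 1L)
    abort("n_slices must be at least 1")
  sig <- c(acq$psf_sigma_xy_px, acq$psf_sigma_z_slices,
           acq$deconv_psf_sigma_xy_px, acq$deconv_psf_sigma_z_slices)
  if (any(sig < 0)) abort("PSF sigmas must be >= 0")
  if (acq$background_level < 0 || acq$nucleus_level < 0 ||
      acq$read_noise_sd < 0)
    abort("photon levels and read noise must be >= 0")
  structure(acq, class = "acquisition_params")
}

#' Effective pixel size from camera pixel and magnification
#'
#' The effective sample-plane pixel is the physical camera pixel divided by
#' the total magnification. With the emulated system's 6.5 µm camera pixel
#' and 100x objective this is 65 nm, so a 2-pixel filament width corresponds
#' to 130 nm.
#'
#' @param camera_pixel_um Physical camera pixel size in µm.
#' @param magnification Total optical magnification.
#' @return Effective pixel size in nm.
#' @examples
#' pixel_size_nm(6.5, 100) # 65
#' 2 * pixel_size_nm(6.5, 100) # the 2-px width parameter in nm
#' @export
pixel_size_nm <- function(camera_pixel_um = 6.5, magnification = 100) {
  stopifnot(camera_pixel_um > 0, magnification > 0)
  camera_pixel_um * 1000 / magnification
}

cell_archetypes <- c("simple", "complex", "foci_only", "nothing")

#' Describe the structure statistics of one strain
#'
#' A strain design gives the probabilities of the four per-cell archetypes
#' (`simple` filament, `complex` multi/branched filaments, `foci_only`,
#' `nothing`) together with the distributions of filament geometry and
#' photon budgets, and per-batch multiplicative intensity factors emulating
#' session-to-session illumination drift.
#'
#' @param name Strain label.
#' @param category_probs Named numeric vector over
#'   `c("simple", "complex", "foci_only", "nothing")`; must sum to 1.
#' @param filament_length_px List with `mean`, `sd`, `min`, `max` of the true
#'   backbone path length in pixels (truncated normal).
#' @param filament_photons List with `mean`, `sd`: total integrated photons
#'   per filament (negative draws are resampled).
#' @param foci_count List with `min`, `max`: uniform integer count of foci in
#'   a `foci_only` cell.
#' @param focus_photons List with `mean`, `sd`: integrated photons per focus.
#' @param filament_curvature Maximum fractional offset of the backbone's
#'   Bezier control point (0 = straight filaments; the default 0.15 keeps
#'   tubes gently curved without self-intersection).
#' @param batch_intensity_factor Numeric vector, one multiplicative factor
#'   per batch.
#' @return An object of class `strain_design`.
#' @examples
#' d <- strain_design("WT")
#' d$category_probs
#' @export
strain_design <- function(name,
                          category_probs = c(simple = 0.55, complex = 0.15,
                                             foci_only = 0.20, nothing = 0.10),
                          filament_length_px = list(mean = 15, sd = 4,
                                                    min = 6, max = 30),
                          filament_photons = list(mean = 30000, sd = 8000),
                          foci_count = list(min = 1, max = 3),
                          focus_photons = list(mean = 8000, sd = 2000),
                          filament_curvature = 0.15,
                          batch_intensity_factor = c(1, 1.1, 0.9)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort("strain name must be a non-empty string")
  if (is.null(names(category_probs)) ||
      !setequal(names(category_probs), cell_archetypes))
    abort("category_probs must be named over simple/complex/foci_only/nothing")
  category_probs <- category_probs[cell_archetypes]
  if (any(category_probs < 0) || abs(sum(category_probs) - 1) > 1e-9)
    abort("category_probs must be non-negative and sum to 1 (tol 1e-9)")
  if (filament_photons$mean < 0 || focus_photons$mean < 0)
    abort("photon means must be >= 0")
  if (filament_length_px$min <= 0 ||
      filament_length_px$max < filament_length_px$min)
    abort("filament_length_px bounds must satisfy 0 < min <= max")
  if (any(batch_intensity_factor <= 0))
    abort("batch_intensity_factor must be positive")
  if (filament_curvature < 0 || filament_curvature > 0.2)
    abort("filament_curvature must lie in [0, 0.2] (self-intersection bound)")
  structure(list(
    name = name,
    category_probs = category_probs,
    filament_length_px = filament_length_px,
    filament_photons = filament_photons,
    foci_count = foci_count,
    focus_photons = focus_photons,
    filament_curvature = filament_curvature,
    batch_intensity_factor = batch_intensity_factor
  ), class = "strain_design")
}

#' Default four-strain experiment design
#'
#' A wild-type-like strain dominated by bright simple filaments, two
#' interaction-deficient mutants dominated by dim or intermediate foci with
#' a sizeable fraction of empty nuclei, and a helicase-deletion-like strain
#' with slightly weaker filaments. These emulate the qualitative strain
#' differences seen in recombinase-imaging screens and give every archetype
#' substantial support.
#'
#' @param n_batches Number of experimental batches (intensity factors are
#'   recycled or truncated to this length).
#' @return Named list of [strain_design()] objects.
#' @export
default_strain_designs <- function(n_batches = 3) {
  bf <- rep_len(c(1, 1.1, 0.9), n_batches)
  list(
    WT = strain_design(
      "WT",
      category_probs = c(simple = 0.55, complex = 0.15,
                         foci_only = 0.20, nothing = 0.10),
      filament_photons = list(mean = 30000, sd = 8000),
      focus_photons = list(mean = 8000, sd = 2000),
      batch_intensity_factor = bf),
    mutA = strain_design(
      "mutA",
      category_probs = c(simple = 0.05, complex = 0.03,
                         foci_only = 0.60, nothing = 0.32),
      filament_photons = list(mean = 12000, sd = 4000),
      focus_photons = list(mean = 1000, sd = 300),
      batch_intensity_factor = bf),
    mutB = strain_design(
      "mutB",
      category_probs = c(simple = 0.15, complex = 0.07,
                         foci_only = 0.55, nothing = 0.23),
      filament_photons = list(mean = 18000, sd = 5000),
      focus_photons = list(mean = 3000, sd = 800),
      batch_intensity_factor = bf),
    srs2d = strain_design(
      "srs2d",
      category_probs = c(simple = 0.45, complex = 0.25,
                         foci_only = 0.20, nothing = 0.10),
      filament_photons = list(mean = 22000, sd = 6000),
      focus_photons = list(mean = 7000, sd = 1800),
      batch_intensity_factor = bf)
  )
}
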