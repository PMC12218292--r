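test_that("parameter constructors validate their invariants", {
  expect_s3_class(acquisition_params(), "acquisition_params")
  expect_error(acquisition_params(crop_px = 8), "crop_px")
  expect_error(acquisition_params(pixel_nm = -1), "positive")
  expect_error(acquisition_params(psf_sigma_xy_px = -0.1), "sigmas")
  expect_error(strain_design("x", category_probs = c(simple = 0.5,
    complex = 0.5, foci_only = 0.1, nothing = 0)), "sum to 1")
  expect_error(strain_design(""), "non-empty")
  d <- strain_design("ok")
  expect_equal(sum(d$category_probs), 1)
})

test_that("a 'nothing' cell without noise is exactly the background field", {
  acq <- quiet_acq(nucleus_level = 30)
  cl <- render_cell(strain_design("W"), "nothing", acq, seed = 3)
  expect_equal(cl$stack$raw, cl$truth$background, tolerance = 1e-12)
  expect_equal(cl$truth$total_planted_photons, 0)
  expect_equal(nrow(cl$truth$foci), 0)
})

test_that("rendering conserves planted photons for an in-crop filament", {
  acq <- quiet_acq()
  cl <- render_cell(straight_design(10), "simple", acq, seed = 2)
  sig <- sum(cl$stack$raw - cl$truth$background)
  expect_lt(abs(sig - cl$truth$total_planted_photons) /
              cl$truth$total_planted_photons, 0.001)
  expect_lt(cl$truth$clip_loss / cl$truth$total_planted_photons, 0.01)
})

test_that("rendering is linear: doubling focus photons doubles the signal", {
  acq <- quiet_acq()
  d1 <- strain_design("a", focus_photons = list(mean = 4000, sd = 0.001),
                      foci_count = list(min = 1, max = 1))
  d2 <- strain_design("a", focus_photons = list(mean = 8000, sd = 0.001),
                      foci_count = list(min = 1, max = 1))
  c1 <- render_cell(d1, "foci_only", acq, seed = 5)
  c2 <- render_cell(d2, "foci_only", acq, seed = 5)
  s1 <- c1$stack$raw - c1$truth$background
  s2 <- c2$stack$raw - c2$truth$background
  expect_equal(2 * s1, s2, tolerance = 1e-6)
})

test_that("simulate_experiment is deterministic and rejects duplicates", {
  ds <- default_strain_designs()[c("WT", "mutA")]
  s1 <- simulate_experiment(ds, n_cells = 4, seed = 11)
  s2 <- simulate_experiment(ds, n_cells = 4, seed = 11)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$cells[[3]]$raw, s2$cells[[3]]$raw)
  expect_error(simulate_experiment(list(strain_design("A"),
                                        strain_design("A")), 2),
               "duplicate")
})

test_that("archetype draws follow the design probabilities", {
  d <- strain_design("p6", category_probs = c(simple = 0.6, complex = 0.1,
                                              foci_only = 0.2, nothing = 0.1))
  counts <- sapply(1:25, function(s) {
    r <- simulate_cell_records(list(d), n_cells = 100, seed = s)
    sum(r$category == "Simple")
  })
  # binomial check over seeds: the mean sits within 3 SE of n p, and
  # individual replicates stay within the 3 sigma band (allowing the
  # expected rare excursion)
  sdev <- sqrt(100 * 0.6 * 0.4)
  expect_lte(abs(mean(counts) - 60), 3 * sdev / sqrt(length(counts)))
  expect_lte(sum(abs(counts - 60) > 3 * sdev), 2)
})

test_that("equal batch factors give equal per-batch photon means", {
  d <- strain_design("flat", category_probs = c(simple = 1, complex = 0,
                                                foci_only = 0, nothing = 0),
                     batch_intensity_factor = c(1, 1, 1))
  r <- simulate_cell_records(list(d), n_cells = 900, n_batches = 3, seed = 8)
  mns <- tapply(r$filament_intensity, r$batch, mean)
  expect_lt(diff(range(mns)) / mean(mns), 0.05)
})

test_that("NMR titration plants the attenuation exactly at zero noise", {
  seqv <- simulate_protein_sequence(200, seed = 2, no_pro_at = c(50, 120))
  tt <- simulate_nmr_titration(seqv, c(50, 120), attenuation = 0.2,
                               noise_cv = 0, seed = 1)
  rat <- intensity_ratio(tt$bound, tt$free)
  inside <- rat$residue >= 50 & rat$residue <= 120
  expect_equal(rat$ratio[inside], rep(0.2, sum(inside)), tolerance = 1e-12)
  expect_equal(rat$ratio[!inside], rep(1, sum(!inside)), tolerance = 1e-12)
  # attenuation 1, zero noise: bound identical to free
  t1 <- simulate_nmr_titration(seqv, c(50, 120), attenuation = 1,
                               noise_cv = 0, seed = 1)
  expect_equal(t1$bound$intensity, t1$free$intensity, tolerance = 1e-12)
})

test_that("prolines carry no amide row in either peak table", {
  seqv <- paste0(strsplit(simulate_protein_sequence(99, seed = 3), "")[[1]],
                 collapse = "")
  seqv <- paste0(substr(seqv, 1, 49), "P", substr(seqv, 51, 99))
  tt <- simulate_nmr_titration(seqv, c(10, 30), 0.5, noise_cv = 0, seed = 1)
  expect_false(50 %in% tt$free$residue)
  expect_false(50 %in% tt$bound$residue)
  expect_false(any(tt$free$aa == "P"))
})

test_that("titration validates its inputs", {
  expect_error(simulate_nmr_titration("", c(1, 2)), "non-empty")
  expect_error(simulate_nmr_titration("ACDEF", c(2, 9)), "within")
  expect_error(simulate_nmr_titration("ACDEF", c(1, 3), attenuation = 1.5),
               "attenuation")
})
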