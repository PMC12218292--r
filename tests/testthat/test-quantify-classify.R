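test_that("the four categories are assigned per the skeleton/foci rules", {
  feats <- function(nc, nj) tibble::tibble(n_components = nc,
                                           n_junctions = nj)
  expect_equal(classify_cell(feats(1, 0), list()), "Simple")
  expect_equal(classify_cell(feats(2, 0), list()), "Complex")
  expect_equal(classify_cell(feats(1, 1), list()), "Complex")
  expect_equal(classify_cell(feats(0, 0), list(1, 2)), "Foci")
  expect_equal(classify_cell(feats(0, 0), list()), "Nothing")
  # exhaustive and mutually exclusive over a grid
  for (nc in 0:3) for (nj in 0:2) for (nf in 0:2) {
    cat <- classify_cell(feats(nc, nj), as.list(seq_len(nf)))
    expect_true(cat %in% c("Simple", "Complex", "Foci", "Nothing"))
  }
})

test_that("measure_intensity subtracts background and is additive", {
  img <- matrix(100, 30, 30)
  m1 <- matrix(FALSE, 30, 30); m1[5:10, 5:10] <- TRUE
  expect_equal(measure_intensity(img, m1, 100), 0)
  m2 <- matrix(FALSE, 30, 30); m2[20:25, 20:25] <- TRUE
  img[m1] <- 150; img[m2] <- 130
  expect_equal(measure_intensity(img, m1 | m2, 100),
               measure_intensity(img, m1, 100) +
                 measure_intensity(img, m2, 100))
  expect_error(measure_intensity(img, matrix(FALSE, 30, 30), 100), "empty")
})

test_that("mean measured intensity matches planted photons within 3 SE", {
  acq <- flat_acq()
  df <- straight_design(15, photons = 20000)
  vals <- sapply(1:40, function(s) {
    cl <- render_cell(df, "simple", acq, seed = s)
    p <- process_cell(cl$stack)
    if (p$category == "Simple")
      p$filament_intensity - cl$truth$realized_photons else NA
  })
  se <- sd(vals, na.rm = TRUE) / sqrt(sum(!is.na(vals)))
  expect_lt(abs(mean(vals, na.rm = TRUE)), 3 * se)
})

test_that("the brightest focus is selected with a documented tie-break", {
  foci <- list(list(center = c(5, 9), intensity = 5),
               list(center = c(2, 3), intensity = 9),
               list(center = c(8, 1), intensity = 2))
  expect_equal(select_brightest_focus(foci)$intensity, 9)
  expect_equal(select_brightest_focus(foci[1])$intensity, 5)
  tie <- list(list(center = c(7, 2), intensity = 4),
              list(center = c(3, 8), intensity = 4),
              list(center = c(3, 5), intensity = 4))
  expect_equal(select_brightest_focus(tie)$center, c(3, 5))
  expect_error(select_brightest_focus(list()), "no foci")
})

test_that("cell records enforce the per-category feature rules", {
  meta <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                         strain = "WT", batch = 1L)
  results <- list(
    a = list(category = "Complex", filament_length_px = 12,
             filament_intensity = 500, spot_intensity = 10),
    b = list(category = "Foci", spot_intensity = 77),
    c = list(category = "Nothing", filament_intensity = 3),
    d = list(category = "Simple", filament_length_px = 9,
             filament_intensity = 400))
  rec <- build_cell_records(results, meta)
  expect_equal(rec$has_filament, c(1L, 0L, 0L, 1L))
  expect_true(is.na(rec$filament_length_px[1]))    # Complex: no length
  expect_true(is.na(rec$filament_intensity[1]))
  expect_equal(rec$spot_intensity[2], 77)
  expect_true(all(is.na(unlist(rec[3, c("filament_length_px",
                                        "filament_intensity",
                                        "spot_intensity")]))))
  expect_equal(rec$filament_length_px[4], 9)
  expect_error(build_cell_records(results[1:3], meta), "mismatch")
})

test_that("normalization to WT is correct and scale-invariant", {
  rec <- make_records(data.frame(
    strain = c("WT", "WT", "mut", "mut"),
    category = c("Simple", "Simple", "Foci", "Simple"),
    filament_intensity = c(150, 250, NA, 100),
    spot_intensity = c(NA, NA, 20, NA)))
  nr <- normalize_to_wt(rec, "WT")
  expect_equal(nr$filament_intensity[1:2], c(0.75, 1.25))
  expect_equal(nr$spot_intensity[3], 0.10)
  # WT cell exactly at the WT mean maps to 1
  expect_equal(mean(nr$filament_intensity[1:2]), 1)
  # scale invariance
  rec2 <- rec
  rec2$filament_intensity <- rec2$filament_intensity * 7
  rec2$spot_intensity <- rec2$spot_intensity * 7
  nr2 <- normalize_to_wt(rec2, "WT")
  expect_equal(nr2$filament_intensity, nr$filament_intensity)
  expect_equal(nr2$spot_intensity, nr$spot_intensity)
  # no WT Simple cells: error
  expect_error(normalize_to_wt(rec[3, ], "mut", reference = "filament"),
               "reference")
})

test_that("brightness classes split at 20% and 80% of WT", {
  expect_equal(brightness_category(c(0.85, 0.5, 0.1)),
               c("bright", "intermediate", "dim"))
  # boundaries are inclusive to intermediate
  expect_equal(brightness_category(c(0.80, 0.20)),
               c("intermediate", "intermediate"))
  expect_error(brightness_thresholds(bright_cut = 0.1, dim_cut = 0.5),
               "dim_cut")
})

test_that("category recovery on a rendered experiment exceeds 90%", {
  sim <- simulate_experiment(default_strain_designs(), n_cells = 20,
                             seed = 42)
  res <- lapply(sim$cells, function(s)
    tryCatch(process_cell(s), error = function(e)
      list(error = conditionMessage(e))))
  names(res) <- sim$metadata$cell_id
  rec <- suppressMessages(build_cell_records(res, sim$metadata))
  acc <- mean(category_matches_archetype(rec$category, sim$truth$archetype),
              na.rm = TRUE)
  expect_gte(acc, 0.9)
  # exhaustiveness: every processed crop got exactly one category
  expect_true(all(!is.na(rec$category)))
})
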