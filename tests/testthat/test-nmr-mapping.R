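test_that("intensity ratios are I(bound)/I0(free) with NA for unshared rows", {
  seqv <- simulate_protein_sequence(80, seed = 6)
  tt <- simulate_nmr_titration(seqv, c(20, 50), 0.3, noise_cv = 0, seed = 2)
  rat <- intensity_ratio(tt$bound, tt$free)
  expect_equal(rat$ratio, tt$bound$intensity / tt$free$intensity)
  # identical tables give all ratios 1
  r1 <- intensity_ratio(tt$free, tt$free)
  expect_true(all(abs(r1$ratio - 1) < 1e-12))
  # residue absent from the bound table yields NA, not an error
  bound2 <- tt$bound[tt$bound$residue != 25, ]
  r2 <- intensity_ratio(bound2, tt$free)
  expect_true(is.na(r2$ratio[r2$residue == 25]))
  # zero free intensity errors, naming the residue
  free0 <- tt$free
  free0$intensity[free0$residue == 30] <- 0
  expect_error(intensity_ratio(tt$bound, free0), "30")
})

test_that("ratios and region calls are invariant to a common scale", {
  seqv <- simulate_protein_sequence(150, seed = 8, no_pro_at = c(40, 90))
  tt <- simulate_nmr_titration(seqv, c(40, 90), 0.2, noise_cv = 0.05,
                               seed = 3)
  r1 <- intensity_ratio(tt$bound, tt$free)
  b2 <- tt$bound; b2$intensity <- b2$intensity * 13.7
  f2 <- tt$free; f2$intensity <- f2$intensity * 13.7
  r2 <- intensity_ratio(b2, f2)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  expect_equal(call_interaction_region(r1), call_interaction_region(r2))
})

test_that("secondary shifts invert the generator's planting exactly", {
  seqv <- simulate_protein_sequence(120, seed = 11)
  dev <- rep(0, 120); dev[60:69] <- 2
  tt <- simulate_nmr_titration(seqv, c(30, 80), 0.5, noise_cv = 0, seed = 4,
                               ca_deviation = dev)
  ss <- secondary_shift(tt$free, seqv)
  expect_equal(ss$delta_ca,
               dev[ss$residue], tolerance = 1e-9)
  # random-coil input gives all-zero deltas
  tt0 <- simulate_nmr_titration(seqv, c(30, 80), 0.5, noise_cv = 0, seed = 4)
  ss0 <- secondary_shift(tt0$free, seqv)
  expect_true(all(abs(ss0$delta_ca) < 1e-9))
  # residue-type mismatch errors
  bad <- tt$free
  bad$aa[3] <- setdiff(c("A", "G"), bad$aa[3])[1]
  expect_error(secondary_shift(bad, seqv), "mismatch")
})

test_that("the pre-proline correction is applied to the preceding residue", {
  rc <- random_coil_model()
  pred <- predict_random_coil("AAPA", rc)
  # A before P vs A elsewhere differ by exactly the table correction
  expect_equal(pred$ca_shift[2] - pred$ca_shift[1],
               rc$pre_proline_correction)
  expect_equal(pred$ca_shift[4], pred$ca_shift[1])
  expect_match(rc$provenance, "Wishart")
})

test_that("disorder flags count near-zero secondary shifts", {
  prof <- tibble::tibble(residue = 1:100, aa = "A", delta_ca = 0)
  expect_equal(disorder_flag(prof)$fraction, 1)
  prof$delta_ca[11:20] <- 3
  expect_equal(disorder_flag(prof, cutoff = 0.5)$fraction, 0.9)
  # cutoff 0: only exact zeros count
  prof2 <- tibble::tibble(residue = 1:4, aa = "A",
                          delta_ca = c(0, 0.001, 0, -0.2))
  expect_equal(disorder_flag(prof2, cutoff = 0)$fraction, 0.5)
  expect_error(disorder_flag(prof[0, ]), "empty")
})

test_that("region calling finds planted segments and bridges gaps", {
  seqv <- simulate_protein_sequence(471, seed = 4, no_pro_at = c(310, 395))
  tt <- simulate_nmr_titration(seqv, c(310, 395), 0.2, noise_cv = 0,
                               seed = 1)
  rg <- call_interaction_region(intensity_ratio(tt$bound, tt$free))
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$start, 310L)
  expect_equal(rg$end, 395L)
  expect_equal(rg$mean_ratio, 0.2, tolerance = 1e-9)
  # all ratios 1: empty call list
  none <- call_interaction_region(intensity_ratio(tt$free, tt$free))
  expect_equal(nrow(none), 0L)
  # two separated segments give two calls with correct boundaries
  prof <- tibble::tibble(residue = 1:200, ratio = 1)
  prof$ratio[40:60] <- 0.1
  prof$ratio[100:130] <- 0.1
  two <- call_interaction_region(prof)
  expect_equal(two$start, c(40L, 100L))
  expect_equal(two$end, c(60L, 130L))
  # a gap of max_gap is bridged; a longer one splits the call
  gap <- tibble::tibble(residue = 1:60, ratio = 1)
  gap$ratio[10:20] <- 0.1; gap$ratio[24:40] <- 0.1
  expect_equal(nrow(call_interaction_region(gap, max_gap = 3)), 1L)
  expect_equal(nrow(call_interaction_region(gap, max_gap = 2)), 2L)
  expect_error(call_interaction_region(prof, threshold = 1.2), "threshold")
})

test_that("boundaries are recovered within 2 residues under noise", {
  seqv <- simulate_protein_sequence(471, seed = 4, no_pro_at = c(310, 395))
  ok <- 0
  for (s in 1:200) {
    tt <- simulate_nmr_titration(seqv, c(310, 395), 0.2, noise_cv = 0.10,
                                 seed = s)
    rg <- call_interaction_region(intensity_ratio(tt$bound, tt$free))
    if (nrow(rg) >= 1) {
      main <- rg[which.max(rg$n_obs), ]
      if (abs(main$start - 310) <= 2 && abs(main$end - 395) <= 2)
        ok <- ok + 1
    }
  }
  expect_gte(ok / 200, 0.95)
})

test_that("peak tables round-trip through TSV and validate on read", {
  seqv <- simulate_protein_sequence(60, seed = 1)
  tt <- simulate_nmr_titration(seqv, c(20, 40), 0.5, noise_cv = 0, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(tt$free, path)
  back <- read_peak_table(path)
  expect_equal(back$residue, tt$free$residue)
  expect_equal(back$intensity, tt$free$intensity, tolerance = 1e-9)
  expect_error(read_peak_table("no/such/file.tsv"), "no such")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue\taa", "1\tA"), bad)
  expect_error(read_peak_table(bad), "missing column")
})
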