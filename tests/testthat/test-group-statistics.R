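null_designs <- function() {
  d <- function(nm) strain_design(nm, category_probs = c(
    simple = 0.4, complex = 0.1, foci_only = 0.3, nothing = 0.2))
  list(d("A"), d("B"))
}

test_that("fdr_adjust matches the brute-force step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # NA entries propagate and are excluded from m
  p <- c(0.01, NA, 0.04)
  q <- fdr_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(p[c(1, 3)]))
})

test_that("q-values never fall below their p-values", {
  set.seed(5)
  p <- runif(30)
  expect_true(all(fdr_adjust(p) >= p))
})

test_that("model fits report Wald t tests and handle degenerate input", {
  rec <- simulate_cell_records(null_designs(), n_cells = 150, seed = 21)
  f1 <- fit_pair_model(rec, c("A", "B"), model_spec("M1"))
  td <- tidy(f1)
  expect_equal(td$term, "has_filament")
  expect_equal(td$t, td$estimate / td$se)
  expect_equal(td$p, 2 * pt(-abs(td$t), df = f1$fit$df.residual))
  expect_true(glance(f1)$converged)
  # M2 restricted to Simple cells; M3 to Foci cells
  f2 <- fit_pair_model(rec, c("A", "B"), model_spec("M2"))
  expect_equal(f2$n, sum(rec$category == "Simple"))
  f3 <- fit_pair_model(rec, c("A", "B"), model_spec("M3"))
  expect_equal(f3$n, sum(rec$category == "Foci"))
  # complete separation is flagged, never a silent NaN
  sep <- make_records(data.frame(
    strain = rep(c("A", "B"), each = 20),
    category = rep(c("Simple", "Nothing"), each = 20)))
  fs <- fit_pair_model(sep, c("A", "B"), model_spec("M1"))
  expect_true(all(!is.na(tidy(fs)$flag)))
  expect_true(all(is.na(tidy(fs)$p)))
  expect_error(fit_pair_model(rec, c("A", "Z")), "unknown strain")
})

test_that("single-batch data drops the batch term with a note", {
  rec <- simulate_cell_records(null_designs(), n_cells = 100, n_batches = 1,
                               seed = 3)
  expect_message(f <- fit_pair_model(rec, c("A", "B"), model_spec("M1")),
                 "batch term dropped")
  expect_false("batch" %in% all.vars(formula(f$fit)))
})

test_that("label swap flips coefficient signs and keeps p", {
  rec <- simulate_cell_records(null_designs(), n_cells = 200, seed = 9)
  a <- tidy(fit_pair_model(rec, c("A", "B"), model_spec("M1")))
  b <- tidy(fit_pair_model(rec, c("B", "A"), model_spec("M1")))
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-9)
})

test_that("compare_all lays out 4 tests per pair and adjusts jointly", {
  rec <- simulate_cell_records(null_designs(), n_cells = 150, seed = 14)
  out <- suppressMessages(compare_all(rec, list(c("A", "B"))))
  expect_equal(nrow(out), 4L)
  expect_setequal(out$term, c("has_filament", "filament_length_px",
                              "filament_intensity", "spot_intensity"))
  expect_equal(out$q, fdr_adjust(out$p))
  # 13 pairs x 4 terms give the 52-hypothesis layout
  many <- lapply(1:13, function(i) {
    d <- null_designs(); d[[1]]$name <- paste0("A", i)
    d[[2]]$name <- paste0("B", i); d
  })
  rec13 <- simulate_cell_records(unlist(many, recursive = FALSE),
                                 n_cells = 30, seed = 2)
  pairs13 <- lapply(1:13, function(i) c(paste0("A", i), paste0("B", i)))
  out13 <- suppressMessages(compare_all(rec13, pairs13))
  expect_equal(nrow(out13), 52L)
  expect_error(compare_all(rec, list(c("A", "nope"))), "invalid pair")
})

test_that("the null Wald test is calibrated and BH controls the FDR", {
  set.seed(123)
  rep_seeds <- sample.int(2^31 - 2, 400)
  hits <- any_disc <- logical(length(rep_seeds))
  for (r in seq_along(rep_seeds)) {
    rec <- simulate_cell_records(null_designs(), n_cells = 200,
                                 n_batches = 3, seed = rep_seeds[r])
    p4 <- c(tidy(fit_pair_model(rec, c("A", "B"), model_spec("M1")))$p,
            tidy(fit_pair_model(rec, c("A", "B"), model_spec("M2")))$p,
            tidy(fit_pair_model(rec, c("A", "B"), model_spec("M3")))$p)
    hits[r] <- p4[1] < 0.05
    any_disc[r] <- any(fdr_adjust(p4) < 0.05, na.rm = TRUE)
  }
  # binomial 99% envelope around 0.05 at 400 reps is about +-0.028
  expect_gte(mean(hits), 0.022)
  expect_lte(mean(hits), 0.078)
  # all-null: the false discovery proportion averages below the BH level
  # (with a matching Monte-Carlo allowance)
  expect_lte(mean(any_disc), 0.05 + 0.028)
})

test_that("a multiplicative batch effect does not inflate type-I error", {
  d <- function(nm) strain_design(nm, category_probs = c(
    simple = 0.4, complex = 0.1, foci_only = 0.3, nothing = 0.2),
    batch_intensity_factor = c(1, 1.5, 1))
  set.seed(321)
  rep_seeds <- sample.int(2^31 - 2, 300)
  hits <- sapply(rep_seeds, function(s) {
    rec <- simulate_cell_records(list(d("A"), d("B")), n_cells = 200,
                                 n_batches = 3, seed = s)
    tidy(fit_pair_model(rec, c("A", "B"), model_spec("M3")))$p < 0.05
  })
  expect_lte(mean(hits, na.rm = TRUE), 0.085)
})

test_that("a planted filament-probability shift is recovered", {
  # true log-odds of hasFilament = 1 between the two strains
  dA <- strain_design("A", category_probs = c(simple = 0.35, complex = 0.15,
                                              foci_only = 0.3, nothing = 0.2))
  # p_B chosen so logit(p_B) - logit(p_A) = 1
  pB <- plogis(qlogis(0.5) + 1)
  dB <- strain_design("B", category_probs = c(simple = pB * 0.7,
                                              complex = pB * 0.3,
                                              foci_only = (1 - pB) * 0.6,
                                              nothing = (1 - pB) * 0.4))
  set.seed(55)
  rep_seeds <- sample.int(2^31 - 2, 200)
  cover <- sapply(rep_seeds, function(s) {
    rec <- simulate_cell_records(list(dA, dB), n_cells = 500, seed = s)
    td <- tidy(fit_pair_model(rec, c("A", "B"), model_spec("M1")))
    abs(td$estimate - 1) <= qnorm(0.975) * td$se
  })
  expect_gte(mean(cover), 0.93)
})

test_that("category proportions sum to one and count cells", {
  rec <- make_records(data.frame(
    strain = c(rep("WT", 10), rep("m", 4)),
    category = c(rep("Simple", 10), rep(c("Simple", "Foci"), 2))))
  pr <- category_proportions(rec)
  expect_equal(sum(pr$fraction[pr$strain == "WT"]), 1)
  expect_equal(pr$fraction[pr$strain == "WT" & pr$category == "Simple"], 1)
  expect_equal(sort(pr$fraction[pr$strain == "m" & pr$n_cells > 0]),
               c(0.5, 0.5))
  expect_true(all(abs(pr$fraction * pr$n - round(pr$fraction * pr$n)) <
                    1e-9))
})
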