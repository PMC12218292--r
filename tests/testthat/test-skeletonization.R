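test_that("thinning reduces bars to centrelines and keeps trivial cases", {
  expect_equal(skeletonize_mask(matrix(FALSE, 10, 10)),
               matrix(FALSE, 10, 10))
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_equal(skeletonize_mask(one), one)
  bar <- matrix(FALSE, 11, 30)
  bar[5:7, 4:23] <- TRUE
  sk <- skeletonize_mask(bar)
  px <- which(sk, arr.ind = TRUE)
  expect_true(all(px[, 1] == 6))           # central row
  expect_lte(abs(min(px[, 2]) - 4), 1)     # ends within 1 px of bar ends
  expect_lte(abs(max(px[, 2]) - 23), 1)
})

test_that("features of simple shapes match hand counts", {
  # straight 10-pixel axial path: 1 component, 1 branch, length 9
  p <- matrix(FALSE, 15, 15); p[3, 3:12] <- TRUE
  f <- skeleton_features(skeleton_graph(p))
  expect_equal(f$n_components, 1L)
  expect_equal(f$n_branches, 1L)
  expect_equal(f$n_junctions, 0L)
  expect_equal(f$n_endpoints, 2L)
  expect_equal(f$total_length_px, 9)
  expect_equal(f$longest_path_px, 9)
  # Y: three 5-px arms from one junction
  y <- matrix(FALSE, 21, 21)
  y[10, 10] <- TRUE
  y[10, 5:9] <- TRUE                       # west arm
  y[5:9, 10] <- TRUE                       # north arm
  y[cbind(11:15, 11:15)] <- TRUE           # diagonal arm
  fy <- skeleton_features(skeleton_graph(y))
  expect_equal(fy$n_components, 1L)
  expect_equal(fy$n_branches, 3L)
  expect_equal(fy$n_junctions, 1L)
  expect_equal(fy$n_endpoints, 3L)
  # empty skeleton
  f0 <- skeleton_features(skeleton_graph(matrix(FALSE, 5, 5)))
  expect_equal(f0$n_components, 0L)
  expect_equal(f0$total_length_px, 0)
})

test_that("pruning removes spurs, keeps paths, and is idempotent", {
  m <- matrix(FALSE, 15, 30)
  m[8, 4:23] <- TRUE                 # 20-px path
  m[7, 10] <- TRUE; m[6, 10] <- TRUE # 2-px spur at a junction
  g <- skeleton_graph(m)
  expect_equal(skeleton_features(g)$n_junctions, 1L)
  gp <- prune_skeleton(g, 4)
  f <- skeleton_features(gp)
  expect_equal(f$n_junctions, 0L)
  expect_equal(f$n_branches, 1L)
  expect_equal(f$total_length_px, 19)
  # unbranched skeletons are untouched, even short ones
  short <- matrix(FALSE, 9, 9); short[5, 4:6] <- TRUE
  gs <- skeleton_graph(short)
  expect_equal(skeleton_features(prune_skeleton(gs, 10))$total_length_px,
               skeleton_features(gs)$total_length_px)
  # idempotence
  gpp <- prune_skeleton(gp, 4)
  expect_setequal(gpp$pixels, gp$pixels)
})

test_that("genuine short arms survive pruning (coverage test)", {
  # a 3-px arm extending away from the main path covers its own mask area
  m <- matrix(FALSE, 15, 30)
  m[8, 4:23] <- TRUE
  m[5:7, 14] <- TRUE                 # 3-px arm, farthest pixel 3 px away
  g <- prune_skeleton(skeleton_graph(m), 4)
  expect_equal(skeleton_features(g)$n_junctions, 1L)
  expect_equal(skeleton_features(g)$n_branches, 3L)
})

test_that("elongation fills the mask without changing topology", {
  mask <- matrix(FALSE, 11, 30)
  mask[5:7, 4:23] <- TRUE
  sk <- matrix(FALSE, 11, 30)
  sk[6, 7:20] <- TRUE                # centreline ending 3 px short
  g <- elongate_skeleton(skeleton_graph(sk), mask)
  cols <- range((g$pixels - 1L) %/% 11L + 1L)
  expect_lte(abs(cols[1] - 4), 1)
  expect_lte(abs(cols[2] - 23), 1)
  expect_true(all(mask[g$pixels]))   # containment contract
  f <- skeleton_features(g)
  expect_equal(f$n_components, 1L)
  expect_equal(f$n_junctions, 0L)
  # endpoint already on the mask boundary: unchanged
  sk2 <- matrix(FALSE, 11, 30); sk2[6, 4:23] <- TRUE
  g2 <- elongate_skeleton(skeleton_graph(sk2), mask)
  expect_setequal(g2$pixels, which(sk2))
  expect_error(elongate_skeleton(skeleton_graph(sk), mask * 0), "contained")
})

test_that("completion adds branches over uncovered mask lobes only", {
  mask <- matrix(FALSE, 21, 30)
  mask[10:12, 4:26] <- TRUE
  lobe <- matrix(FALSE, 21, 30); lobe[4:9, 15:17] <- TRUE
  sk <- matrix(FALSE, 21, 30); sk[11, 4:26] <- TRUE
  # no lobe: completion is a no-op
  g0 <- complete_skeleton(skeleton_graph(sk), mask)
  expect_setequal(g0$pixels, which(sk))
  # with an uncovered lobe a branch (and junction) appears
  g1 <- complete_skeleton(skeleton_graph(sk), mask | lobe)
  f1 <- skeleton_features(g1)
  expect_gte(f1$n_junctions, 1L)
  expect_true(all((mask | lobe)[g1$pixels]))
})

test_that("feature counts agree with a neighbourhood classifier on random masks", {
  set.seed(77)
  for (i in 1:120) {
    m <- matrix(runif(15 * 15) < 0.25, 15, 15)
    sk <- skeletonize_mask(m)
    g <- skeleton_graph(sk)
    f <- skeleton_features(g)
    nb <- neighborhood_counts(sk)
    expect_equal(f$n_endpoints, nb$endpoints)
    # junction nodes merge adjacent junction pixels, so node count is
    # bounded by the raw junction-pixel count
    expect_lte(f$n_junctions, nb$junction_px)
    expect_gte(f$n_junctions, as.integer(nb$junction_px > 0))
    expect_lte(f$longest_path_px, f$total_length_px + 1e-9)
    if (f$n_components == 0) expect_equal(f$n_branches, 0L)
  }
})

test_that("length of planted straight filaments is recovered within 15%", {
  acq <- quiet_acq()
  for (L in c(5, 10, 20, 30)) for (s in 1:3) {
    cl <- render_cell(straight_design(L), "simple", acq, seed = s)
    p <- process_cell(cl$stack)
    expect_equal(p$category, "Simple")
    expect_lte(abs(p$filament_length_px - cl$truth$true_length_px) /
                 cl$truth$true_length_px, 0.15)
  }
})

test_that("pruning and elongation preserve component counts", {
  acq <- flat_acq()
  for (s in 1:6) {
    cl <- render_cell(default_strain_designs()$WT,
                      sample(c("simple", "complex"), 1), acq, seed = s)
    m <- segment_structures(max_z_projection(cl$stack, "deconv"))
    if (!any(m$filament_mask)) next
    g0 <- skeleton_graph(skeletonize_mask(m$filament_mask))
    n0 <- skeleton_features(g0)$n_components
    g1 <- prune_skeleton(g0, 4)
    expect_equal(skeleton_features(g1)$n_components, n0)
    g2 <- elongate_skeleton(g1, m$filament_mask)
    expect_equal(skeleton_features(g2)$n_components, n0)
  }
})
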