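test_that("HU classification honours the printed bracket semantics", {
  expect_identical(as.character(classify_voxel(-600)), "Normo")
  expect_identical(as.character(classify_voxel(-435)), "Normo")
  expect_identical(as.character(classify_voxel(-121)), "Non")
  expect_identical(as.character(classify_voxel(-860)), "Normo")
  expect_identical(as.character(classify_voxel(121)), "Non")
  expect_identical(as.character(classify_voxel(-900)), "Unclassified")
  expect_identical(as.character(classify_voxel(500)), "Unclassified")
  expect_identical(as.character(classify_voxel(-300)), "Hypo")
  expect_error(classify_voxel(NaN), "finite")
})

test_that("classification is a total function partitioning the HU axis", {
  hu <- seq(-1200, 400, by = 0.5)
  cls <- classify_voxel(hu)
  expect_false(anyNA(cls))
  in_range <- hu >= -860 & hu <= 121
  expect_true(all(cls[in_range] != "Unclassified"))
  expect_true(all(cls[!in_range] == "Unclassified"))
})

test_that("readouts on a pure-air lung match the closed forms", {
  vol <- uniform_volume(-1000)  # 1000 voxels at 0.001 mm^3
  res <- compute_readouts(vol, full_mask(vol))
  expect_identical(res$N, 1000L)
  expect_equal(res$V, 1)
  expect_equal(res$MLA, -1000)
  expect_equal(res$Gas, 1)
  expect_equal(res$pct_normo, 0)   # -1000 HU is below the normo range
  expect_equal(res$pct_unclassified, 100)
})

test_that("gas content follows V x MLA / (-1000)", {
  vol <- uniform_volume(-500, dims = c(100L, 100L, 10L))  # V = 100 mm^3
  res <- compute_readouts(vol, full_mask(vol))
  expect_equal(res$V, 100)
  expect_equal(res$Gas, 50)
})

test_that("densitometry contracts: calibration, phase, congruence, empty mask", {
  grey <- scan_volume(array(500, c(5, 5, 5)), c(0.1, 0.1, 0.1), phase = "P01")
  expect_error(compute_readouts(grey, full_mask(grey)), "calibrated")
  nophase <- uniform_volume(-500); nophase$phase <- NA_character_
  expect_error(compute_readouts(nophase, full_mask(nophase)), "phase")
  vol <- uniform_volume(-500)
  empty <- voxel_mask(array(FALSE, dim(vol$values)), vol$spacing)
  expect_error(compute_readouts(vol, empty), "empty")
})

test_that("identities hold to 1e-9 on random masked volumes", {
  set.seed(17)
  for (i in 1:5) {
    vol <- random_volume(n_side = 25L, lo = -1000, hi = 0)
    mask <- voxel_mask(array(runif(25^3) < 0.4, dim(vol$values)), vol$spacing)
    res <- compute_readouts(vol, mask)
    # %Gas = -MLA/10 whenever MLA is in [-1000, 0]
    expect_lt(abs(res$Gas * 100 / res$V - (-res$MLA / 10)), 1e-9)
    # partition of percentages
    expect_lt(abs(res$pct_normo + res$pct_hypo + res$pct_non +
                    res$pct_unclassified - 100), 1e-9)
    # V = N x voxel volume
    expect_equal(res$V, res$N * voxel_volume(vol))
  }
})

test_that("tissue + Gas_P02 = V_P02 exactly and %Gas matches the formula", {
  ph <- small_phantom()
  r1 <- compute_readouts(ph$p01, ph$truth$lung_mask)
  r2 <- compute_readouts(ph$p02, ph$truth$lung_mask)
  bm <- compute_biomarkers(r1, r2)
  expect_equal(bm$tissue + r2$Gas, r2$V, tolerance = 1e-12)
  expect_equal(bm$pct_gas_P01, r1$Gas * 100 / r1$V)
  expect_equal(bm$pct_gas_P02, -r2$MLA / 10, tolerance = 1e-12)
  # order of arguments must not matter
  bm2 <- compute_biomarkers(r2, r1)
  expect_equal(bm, bm2)
  expect_error(compute_biomarkers(r1, r1), "exactly one P01 and one P02")
})

test_that("worked example: V_P02 = 100, MLA = -400 gives Gas 40 and tissue 60", {
  vol <- uniform_volume(-400, dims = c(100L, 100L, 10L), phase = "P02")
  r2 <- compute_readouts(vol, full_mask(vol))
  vol1 <- uniform_volume(-500, dims = c(100L, 100L, 10L), phase = "P01")
  r1 <- compute_readouts(vol1, full_mask(vol1))
  bm <- compute_biomarkers(r1, r2)
  expect_equal(r2$Gas, 40)
  expect_equal(bm$tissue, 60)
  expect_equal(bm$pct_gas_P01, 50)
})

test_that("positive MLA yields a flagged negative gas volume, unclamped", {
  vol <- uniform_volume(50)
  res <- compute_readouts(vol, full_mask(vol))
  expect_lt(res$Gas, 0)
  expect_true(res$gas_negative)
})

test_that("readouts are invariant under voxel permutation", {
  set.seed(23)
  vol <- random_volume(n_side = 12L)
  mask <- full_mask(vol)
  res <- compute_readouts(vol, mask)
  perm <- sample(length(vol$values))
  vol2 <- scan_volume(array(vol$values[perm], dim(vol$values)), vol$spacing,
                      phase = vol$phase, calibrated = TRUE)
  res2 <- compute_readouts(vol2, mask)
  for (f in c("N", "V", "MLA", "Gas", "pct_normo", "pct_hypo", "pct_non",
              "pct_unclassified"))
    expect_equal(res[[f]], res2[[f]])
})

test_that("moving k voxels from normo to hypo shifts percentages by 100k/N", {
  vals <- array(-600, c(10L, 10L, 10L))
  vol <- uniform_volume(-600)
  n <- length(vals)
  k <- 37L
  vals[seq_len(k)] <- -300  # hypo range
  vol2 <- scan_volume(vals, vol$spacing, phase = "P02", calibrated = TRUE)
  r1 <- compute_readouts(vol, full_mask(vol))
  r2 <- compute_readouts(vol2, full_mask(vol2))
  expect_equal(r1$pct_normo - r2$pct_normo, 100 * k / n)
  expect_equal(r2$pct_hypo - r1$pct_hypo, 100 * k / n)
})

test_that("recovered hypo+non burden is monotone in lesion fraction and near its expectation", {
  got <- expe <- numeric(0)
  for (f in c(0, 0.2, 0.5)) {
    ph <- small_phantom(lesion_fraction = f)
    res <- compute_readouts(ph$p02, ph$truth$lung_mask)
    got <- c(got, res$pct_hypo + res$pct_non)
    e <- ph$truth$expected_compartment_fractions["P02", ]
    expe <- c(expe, e[["pct_hypo"]] + e[["pct_non"]])
  }
  expect_true(all(diff(got) > 0))
  expect_true(all(abs(got - expe) < 3))
})

test_that("HU histogram conserves in-range counts with the display defaults", {
  ph <- small_phantom()
  h <- hu_histogram(ph$p02, ph$truth$lung_mask)
  expect_identical(nrow(h), 163L)
  hu <- ph$p02$values[ph$truth$lung_mask$values]
  expect_identical(sum(h$count), sum(hu >= -860 & hu <= 121))
  expect_identical(attr(h, "n_masked"), length(hu))
  expect_equal(diff(range(diff(h$bin_lo))), 0, tolerance = 1e-9)  # equal width
})

test_that("degenerate histogram cases behave", {
  vol <- uniform_volume(-500)
  h <- hu_histogram(vol, full_mask(vol))
  expect_identical(sum(h$count > 0), 1L)
  expect_identical(sum(h$count), 1000L)
  # value exactly at the max edge lands in the last bin
  vol2 <- uniform_volume(121)
  h2 <- hu_histogram(vol2, full_mask(vol2))
  expect_identical(h2$count[163], 1000L)
  expect_error(hu_histogram(vol, full_mask(vol), lo = 10, hi = -10), "lo < hi")
})

test_that("uniformly spread HU fills histogram bins evenly at large N", {
  set.seed(41)
  vol <- scan_volume(array(runif(1e6, -860, 121), c(100, 100, 100)),
                     c(0.1, 0.1, 0.1), phase = "P02", calibrated = TRUE)
  h <- hu_histogram(vol, full_mask(vol))
  expect_lte(max(h$count) / min(h$count), 1.1)
})

test_that("compartment overlay labels agree with the readout counts", {
  ph <- small_phantom(lesion_fraction = 0.3)
  lab <- render_compartment_overlay(ph$p02, ph$truth$lung_mask)
  res <- compute_readouts(ph$p02, ph$truth$lung_mask)
  counts <- tabulate(lab[lab > 0], nbins = 4)
  expect_equal(100 * counts / res$N,
               c(res$pct_normo, res$pct_hypo, res$pct_non,
                 res$pct_unclassified))
  expect_true(all(lab[!ph$truth$lung_mask$values] == 0))
  # single-voxel checks at the printed boundaries
  v <- uniform_volume(-435, dims = c(2L, 2L, 2L))
  l <- render_compartment_overlay(v, full_mask(v))
  expect_true(all(l == 1L))
})

test_that("an all-lesion lung near 0 HU is dominated by the Non label", {
  vol <- uniform_volume(0, dims = c(8L, 8L, 8L))
  lab <- render_compartment_overlay(vol, full_mask(vol))
  expect_true(all(lab == 3L))
})

test_that("densitometry_row assembles the flat reporting layout", {
  ph <- small_phantom()
  r1 <- compute_readouts(ph$p01, ph$truth$lung_mask)
  r2 <- compute_readouts(ph$p02, ph$truth$lung_mask)
  row <- densitometry_row(r2, r1, animal = "m1", day = 42)
  expect_identical(names(row),
    c("animal", "day", "N_P01", "V_P01", "MLA_P01", "Gas_P01",
      "N_P02", "V_P02", "MLA_P02", "Gas_P02", "pct_normo", "pct_hypo",
      "pct_non", "pct_unclassified", "tissue", "pct_gas_P01", "pct_gas_P02"))
  expect_equal(row$pct_normo, r2$pct_normo)  # P02 is the default pct phase
  row1 <- densitometry_row(r1, r2, pct_phase = "P01")
  expect_equal(row1$pct_normo, r1$pct_normo)
})
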