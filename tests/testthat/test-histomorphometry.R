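test_that("ashcroft records validate scores and average them", {
  r <- ashcroft_record("m1", c(1, 2, 3))
  expect_equal(r$mean_score, 2)
  expect_error(ashcroft_record("m1", c(1, 9)), "0..8")
  expect_error(ashcroft_record("m1", integer(0)), "at least one")
})

test_that("severity classification is exhaustive over all nine scores", {
  cls <- classify_severity(0:8)
  expect_identical(as.character(cls),
                   c(rep("mild", 4), "moderate", rep("severe", 4)))
  # every singleton score yields a 100% distribution in its own class
  for (s in 0:8) {
    d <- severity_distribution(s)
    expected <- c(mild = 0, moderate = 0, severe = 0)
    expected[as.character(classify_severity(s))] <- 100
    expect_equal(c(d$pct_mild, d$pct_moderate, d$pct_severe),
                 unname(expected))
  }
})

test_that("severity distributions match direct counts and sum to 100", {
  d <- severity_distribution(c(1, 2, 3, 4, 5))
  expect_equal(d$pct_mild, 60)
  expect_equal(d$pct_moderate, 20)
  expect_equal(d$pct_severe, 20)
  expect_equal(severity_distribution(rep(0, 7))$pct_mild, 100)
  expect_equal(severity_distribution(c(8, 8))$pct_severe, 100)
  set.seed(13)
  for (i in 1:10) {
    scores <- sample(0:8, sample(1:50, 1), replace = TRUE)
    d <- severity_distribution(scores)
    expect_lt(abs(d$pct_mild + d$pct_moderate + d$pct_severe - 100), 1e-9)
  }
})

test_that("per-animal-mean severity classification is available", {
  recs <- list(ashcroft_record("a", c(1, 1, 2)),   # mean 1.33 -> mild
               ashcroft_record("b", c(4, 4, 4)),   # mean 4    -> moderate
               ashcroft_record("c", c(6, 7, 8)))   # mean 7    -> severe
  d <- severity_distribution(recs, per_animal_mean = TRUE)
  expect_equal(c(d$pct_mild, d$pct_moderate, d$pct_severe),
               c(100, 100, 100) / 3)
  expect_identical(d$n, 3L)
  # default pools fields
  d2 <- severity_distribution(recs)
  expect_identical(d2$n, 9L)
})

test_that("stain fraction follows |positive & tissue| / |tissue|", {
  tissue <- matrix(TRUE, 100, 50)
  positive <- matrix(FALSE, 100, 50)
  positive[1:10, ] <- TRUE  # 500 of 5000
  q <- stain_fraction(positive, tissue)
  expect_equal(q$pct_occupied, 10)
  expect_equal(stain_fraction(tissue, tissue)$pct_occupied, 100)
  expect_error(stain_fraction(positive, matrix(FALSE, 100, 50)), "empty tissue")
  # positives outside the tissue warn and are not counted
  tissue2 <- tissue; tissue2[, 26:50] <- FALSE
  expect_warning(q2 <- stain_fraction(positive, tissue2), "outside")
  expect_equal(q2$pct_occupied, 100 * sum(positive & tissue2) / sum(tissue2))
})

test_that("stain fraction is invariant to translation and 90-degree rotation", {
  fx <- generate_histology_fixtures(1, c(1, 0, 0), seed = 6L,
                                    stain_target_fraction = 0.23)
  p <- fx$stain$positive_mask; t_ <- fx$stain$tissue_mask
  base <- stain_fraction(p, t_)$pct_occupied
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  expect_equal(stain_fraction(rot90(p), rot90(t_))$pct_occupied, base)
  shift <- function(m) rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE])
  expect_equal(stain_fraction(shift(p), shift(t_))$pct_occupied, base)
})

test_that("synthetic stain section is recovered at its target fraction", {
  fx <- generate_histology_fixtures(1, c(1, 0, 0), seed = 9L,
                                    stain_target_fraction = 0.23)
  q <- stain_fraction(fx$stain$positive_mask, fx$stain$tissue_mask)
  expect_lt(abs(q$pct_occupied - 23), 0.5)
})

test_that("layer thickness is exact on parallel boundaries and zero on identical ones", {
  x <- seq(0, 1000, by = 20)
  upper <- cbind(x, 0)
  lower <- cbind(x, 100)
  sec <- skin_section(epidermal_dermal = upper, dermal_subcutaneous = lower,
                      muscle = cbind(x, 350), pixel_size = 1)
  expect_equal(layer_thickness(sec, "dermal"), 100)
  expect_equal(layer_thickness(sec, "hypodermal"), 250)
  sec0 <- skin_section(epidermal_dermal = upper, dermal_subcutaneous = upper,
                       pixel_size = 1)
  expect_equal(layer_thickness(sec0, "dermal"), 0)
  # pixel size scales the result
  sec2 <- skin_section(epidermal_dermal = upper, dermal_subcutaneous = lower,
                       pixel_size = 2.5)
  expect_equal(layer_thickness(sec2, "dermal"), 250)
})

test_that("crossing boundaries raise a validation error", {
  x <- seq(0, 100, by = 10)
  up <- cbind(x, 50)
  down <- cbind(x, seq(3, 103, length.out = length(x)))  # crosses y = 50
  sec <- skin_section(epidermal_dermal = up, dermal_subcutaneous = down)
  expect_error(layer_thickness(sec, "dermal"), "cross")
})

test_that("curved boundaries agree with a dense brute-force distance oracle", {
  fx <- generate_histology_fixtures(1, c(1, 0, 0), seed = 12L,
                                    wave_amplitude_um = 40,
                                    dermal_um = 250, hypodermal_um = 400)
  sec <- fx$skin$section
  got <- layer_thickness(sec, "hypodermal", n_samples = 400L)
  # brute force: dense point sets on both polylines, exhaustive min distance
  dense <- function(poly, n = 4000L) {
    i <- seq(1, nrow(poly) - 1)
    out <- lapply(seq(0, 1, length.out = ceiling(n / length(i))), function(t)
      poly[i, , drop = FALSE] * (1 - t) + poly[i + 1, , drop = FALSE] * t)
    do.call(rbind, out)
  }
  lo <- dense(sec$muscle)
  # arc-length-uniform samples on the upper boundary, built independently
  upper <- sec$dermal_subcutaneous
  seg <- sqrt(rowSums(diff(upper)^2))
  cum <- c(0, cumsum(seg))
  s <- seq(0, max(cum), length.out = 400)
  samp <- cbind(approx(cum, upper[, 1], xout = s)$y,
                approx(cum, upper[, 2], xout = s)$y)
  oracle <- mean(vapply(seq_len(nrow(samp)), function(k) {
    sqrt(min((lo[, 1] - samp[k, 1])^2 + (lo[, 2] - samp[k, 2])^2))
  }, numeric(1))) * sec$pixel_size
  expect_lt(abs(got - oracle) / oracle, 0.01)
})

test_that("fold increase divides by the control mean", {
  expect_equal(fold_increase(4, c(2, 2)), 2)
  expect_equal(fold_increase(2, c(1, 3)), 1)
  expect_equal(fold_increase(c(2, 6), c(1, 3)), c(1, 3))
  expect_error(fold_increase(1, c(-2, 0)), "positive")
  expect_error(fold_increase(1, numeric(0)), "no control")
})
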