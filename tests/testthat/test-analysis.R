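test_that("strict peak detection: enumerable cases", {
  pk <- detect_peaks(c(0, 1, 0, 2, 0))
  expect_equal(pk$time, c(1, 3))
  expect_equal(pk$value, c(1, 2))
  expect_equal(nrow(detect_peaks(rep(0.3, 50))), 0)      # constants
  expect_equal(nrow(detect_peaks(c(0, 1, 1, 0))), 0)     # plateau is no peak
  expect_equal(nrow(detect_peaks(c(5, 1, 2))), 0)        # endpoints never peak
  expect_error(detect_peaks(c(1, 2, 1), times = c(0, 1, 2), transient = 5),
               "transient")
})

test_that("peak detection agrees with the exhaustive-scan oracle on random series", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    x <- switch(1 + i %% 3,
                rnorm(n),
                round(rnorm(n), 1),           # ties and plateaus
                sin(seq(0, 20, length.out = n)) + rnorm(n, sd = 0.2))
    got <- detect_peaks(x)
    want <- naive_peaks(x)
    expect_equal(got$time, want - 1)          # 0-based default times
    expect_equal(got$value, x[want])
  }
})

test_that("peak detection on sampled sin(t) finds one peak per period", {
  s <- make_fixtures("sine_series", size = 1000, n_periods = 4)
  pk <- detect_peaks(s$value, times = s$t)
  expect_equal(nrow(pk), 4)
  expect_equal(pk$value, rep(1, 4), tolerance = 1e-3)
  expect_true(all(diff(pk$time) > 0))
})

test_that("peak detection is shift-invariant and scale-equivariant", {
  set.seed(55)
  x <- cumsum(rnorm(300))
  base <- detect_peaks(x)
  shifted <- detect_peaks(x + 17.3)
  expect_equal(shifted$time, base$time)
  expect_equal(shifted$value, base$value + 17.3)
  scaled <- detect_peaks(2.5 * x)
  expect_equal(scaled$time, base$time)
  expect_equal(scaled$value, 2.5 * base$value)
})

test_that("transient discard restricts peaks to t >= transient", {
  t <- seq(0, 40, by = 0.1)
  x <- sin(t)
  pk <- detect_peaks(x, times = t, transient = 20)
  expect_true(all(pk$time >= 20))
  expect_equal(nrow(pk), sum(detect_peaks(x, times = t)$time >= 20))
})

test_that("activity classification covers the four labels", {
  empty <- detect_peaks(rep(0, 100))
  expect_equal(classify_activity(empty), "quiescent")
  # tiny-amplitude wiggle is quiescent despite many peaks
  t <- seq(0, 60, by = 0.05)
  wig <- 0.01 * sin(t)
  expect_equal(classify_activity(detect_peaks(wig, times = t), wig),
               "quiescent")
  # clean oscillation is periodic
  s <- sin(t)
  expect_equal(classify_activity(detect_peaks(s, times = t), s), "periodic")
  # alternating two-level peaks are multimodal
  two <- make_fixtures("two_cluster_peaks", size = 400)
  expect_equal(classify_activity(detect_peaks(two$value, times = two$t), two),
               "multimodal")
  # jittered intervals and values, one value cluster: irregular
  set.seed(8)
  gaps <- round(runif(40, 5, 15))
  xs <- unlist(lapply(gaps, function(g) c(numeric(g), 1 + runif(1, -0.3, 0.3))))
  expect_equal(classify_activity(detect_peaks(xs), xs), "irregular")
  # purity: same inputs, same answer
  pk <- detect_peaks(xs)
  expect_identical(classify_activity(pk, xs), classify_activity(pk, xs))
})

test_that("spatial dispersion: closed forms and brute force", {
  expect_equal(spatial_std(matrix(4.2, 7, 9)), 0)
  checker <- outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  expect_equal(spatial_std(checker), 1)
  set.seed(2)
  f <- matrix(rnorm(100), 10, 10)
  expect_equal(spatial_std(f), sqrt(mean((f - mean(f))^2)))
})

test_that("phase field recovers constructed angles", {
  # all u > u*, v = v*: angle identically zero
  ph0 <- phase_field(matrix(2, 5, 5), matrix(0.3, 5, 5), c(1, 0.3))
  expect_true(all(ph0 == 0))
  # synthetic rotation (u, v) = (cos theta, sin theta) about (0, 0)
  th <- make_fixtures("spiral_phase", size = 32)
  ph <- phase_field(cos(th), sin(th), c(0, 0))
  expect_equal(unclass(ph), unclass(th), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero vector flagged, angle defined as 0
  phz <- phase_field(matrix(0, 3, 3), matrix(0, 3, 3), c(0, 0))
  expect_equal(attr(phz, "n_zero"), 9L)
  expect_true(all(phz == 0))
})

test_that("phase singularities: constructed defects of known charge", {
  uniform <- matrix(0.5, 20, 20)
  expect_equal(count_phase_singularities(uniform)$count, 0)

  one <- make_fixtures("spiral_phase", size = 41, charge = 1L)
  res <- count_phase_singularities(one)
  expect_equal(res$count, 1)
  expect_equal(res$net_charge, 1)
  expect_lt(max(abs(c(res$locations$row, res$locations$col) - 21)), 1.1)

  neg <- make_fixtures("spiral_phase", size = 41, charge = -1L)
  resn <- count_phase_singularities(neg)
  expect_equal(resn$count, 1)
  expect_equal(resn$net_charge, -1)

  pair <- make_fixtures("defect_pair", size = 40)
  resp <- count_phase_singularities(pair)
  expect_equal(resp$count, 2)
  expect_equal(resp$net_charge, 0)
})

test_that("total charge is invariant under smooth defect motion", {
  # slide a defect around without letting it cross the boundary: every
  # placement keeps count 1, charge 1
  for (cx in c(10, 16, 22)) for (cy in c(12, 20)) {
    x <- matrix(seq_len(32), 32, 32) - cx
    y <- matrix(seq_len(32), 32, 32, byrow = TRUE) - cy
    th <- atan2(y, x)
    res <- count_phase_singularities(th)
    expect_equal(res$count, 1)
    expect_equal(res$net_charge, 1)
    expect_lt(abs(res$locations$row - cx), 1.1)
    expect_lt(abs(res$locations$col - cy), 1.1)
  }
})

test_that("bifurcation scan labels a driven-to-rest media as quiescent", {
  # strong feedback magnetizes the small media to homogeneity, the
  # monitored node goes quiescent; the scan survives a diverging value
  g <- fast_grid(24, duration = 40)
  scan <- bifurcation_scan("k0", c(0.9), grid = g, transient = 0.5)
  expect_s3_class(scan, "fhn_bifurcation")
  expect_false(scan$failed[1])
  expect_equal(scan$label[1], "quiescent")
  expect_equal(scan$n_peaks[1], 0)
})

test_that("bifurcation scan is deterministic and flags failed values", {
  g <- fast_grid(20, duration = 30)
  s1 <- bifurcation_scan("k2", c(0.5, 1.0), grid = g)
  s2 <- bifurcation_scan("k2", c(0.5, 1.0), grid = g)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  # an absurd gain diverges; the scan flags it and completes the rest
  s3 <- bifurcation_scan("k0", c(0.1, 500), grid = g)
  expect_false(s3$failed[1])
  expect_true(s3$failed[2])
  expect_true(is.na(s3$label[2]))
})

test_that("sustained activity at the monitored node in the spiral regime", {
  g <- fast_grid(40, duration = 60)
  scan <- bifurcation_scan("k0", 0.1, grid = g, transient = 0.3)
  expect_gt(scan$n_peaks[1], 0)
})

test_that("pattern metrics quantify the obvious cases", {
  st <- media_state(matrix(0.2, 30, 30), matrix(0.1, 30, 30),
                    matrix(0, 30, 30), t = 5)
  m <- pattern_metrics(st, reference = c(0, 0))
  expect_equal(m$spatial_std_u, 0)
  expect_equal(m$n_singularities, 0)
  expect_equal(m$t, 5)
  # a synthetic rotating field around the reference has one core
  th <- make_fixtures("spiral_phase", size = 31)
  st2 <- media_state(cos(th), sin(th), matrix(0, 31, 31))
  m2 <- pattern_metrics(st2, reference = c(0, 0))
  expect_equal(m2$n_singularities, 1)
})
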