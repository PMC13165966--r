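test_that("usaf_linewidth follows the chart law", {
  # printed chart values
  expect_equal(usaf_linewidth(5, 4), 11.05, tolerance = 0.001)
  expect_equal(usaf_linewidth(6, 6), 4.38, tolerance = 0.0015)
  expect_equal(usaf_linewidth(0, 1), 500)
  # successive elements shrink by exactly 2^(1/6)
  w <- c(vapply(1:6, function(e) usaf_linewidth(3, e), 0),
         vapply(1:6, function(e) usaf_linewidth(4, e), 0))
  expect_equal(w[-length(w)] / w[-1], rep(2^(1 / 6), 11), tolerance = 1e-12)
  expect_true(all(diff(w) < 0))
  expect_error(usaf_linewidth(5, 7), "1..6")
})

test_that("generate_bar_target draws the three-bar geometry", {
  # empty element list: all-ones map
  expect_equal(generate_bar_target(c(16L, 16L), 1e-6), matrix(1, 16, 16),
               ignore_attr = TRUE)

  # G5E4 at 1 um pitch: line width round(11.05) = 11 px
  tgt <- generate_bar_target(c(128L, 200L), 1e-6,
                             list(list(group = 5, element = 4,
                                       at = c(10L, 10L))))
  el <- attr(tgt, "elements")[[1]]
  expect_identical(el$linewidth_px, 11L)
  # a row through the vertical bars: three 11-px zero runs with 11-px gaps
  mid <- 10L + round(2.5 * 11)
  runs <- rle(tgt[mid, 10:(10 + 5 * 11 - 1)])
  expect_equal(runs$lengths, rep(11, 5))
  expect_equal(runs$values, c(0, 1, 0, 1, 0))
  # range invariant
  expect_gte(min(tgt), 0); expect_lte(max(tgt), 1)

  # unresolvable element names the offender
  expect_error(
    generate_bar_target(c(64L, 64L), 4e-6,
                        list(list(group = 7, element = 6, at = c(5L, 5L)))),
    "G7E6")
  # phase variant: unit modulus, bars carry the delay
  ph <- generate_bar_target(c(128L, 200L), 1e-6,
                            list(list(group = 5, element = 4,
                                      at = c(10L, 10L))),
                            phase_delay = 0.5)
  expect_equal(max(abs(Mod(ph) - 1)), 0)
  expect_equal(sort(unique(as.vector(round(Arg(ph), 6)))), c(0, 0.5))
})

test_that("simulate_hologram implements the forward model", {
  cfg <- optical_config(632.8e-9, 2e-6, 2e-3)
  # free space: plane wave stays a unit plane wave
  h <- simulate_hologram(matrix(1 + 0i, 64, 64), cfg, 2e-3)
  expect_equal(h$amplitude, matrix(1, 64, 64), tolerance = 1e-10)

  # Parseval: recorded energy equals object energy (no evanescent loss)
  blobs <- data.frame(row = 32, col = 32, sigma_px = 8,
                      absorption = 0.5, phase = 0.4)
  obj <- blob_phantom(c(64L, 64L), blobs)
  h2 <- simulate_hologram(obj, cfg, 5e-4)
  expect_equal(sum(h2$amplitude^2), sum(Mod(obj)^2), tolerance = 1e-8)

  # reproducibility: equal seeds agree bitwise, different seeds do not
  ha <- simulate_hologram(obj, cfg, 5e-4, noise_sigma = 0.05, seed = 7)
  hb <- simulate_hologram(obj, cfg, 5e-4, noise_sigma = 0.05, seed = 7)
  hc <- simulate_hologram(obj, cfg, 5e-4, noise_sigma = 0.05, seed = 8)
  expect_identical(ha$amplitude, hb$amplitude)
  expect_false(identical(ha$amplitude, hc$amplitude))
  expect_true(all(ha$amplitude >= 0))
})

test_that("double-slit hologram shows the lambda z / d fringe period", {
  # two line sources d = 80 um apart at z = 2 mm: period lambda z / d
  n <- 256L; p <- 2e-6; lambda <- 632.8e-9; z <- 2e-3
  obj <- matrix(0, n, n)
  obj[, n / 2 - 20] <- 1
  obj[, n / 2 + 20] <- 1   # separation 40 px = 80 um
  cfg <- optical_config(lambda, p, z)
  h <- simulate_hologram(obj, cfg, z)
  row <- h$amplitude[n / 2, ]^2
  spec <- Mod(stats::fft(row - mean(row)))[1:(n / 2)]
  k_peak <- which.max(spec) - 1
  period_meas <- n * p / k_peak
  period_theory <- lambda * z / 80e-6           # 15.82 um
  # peak-picking resolves the period to within one pixel
  expect_lt(abs(period_meas - period_theory), p)
})

test_that("scan_grid and serpentine order obey the scan topology", {
  expect_equal(serpentine_order(2, 2),
               matrix(c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L), 4, 2, byrow = TRUE),
               ignore_attr = TRUE)
  g <- scan_grid(3, 3, 115 * 2e-6, 256L, 2e-6)
  expect_equal(g$overlap, 1 - 115 / 256)
  expect_equal(nrow(g$order), 9)
  expect_false(any(duplicated(g$order)))
  expect_error(scan_grid(2, 2, 600e-6, 256L, 2e-6), "overlap")
})

test_that("simulate_scan: counts, manifest consistency, overlap exactness", {
  s <- small_scan()
  scan <- s$scan
  # rows x cols x K holograms
  expect_length(scan$holograms, 2 * 2 * 2)
  man <- scan$manifest
  # ground-truth shift and stage/grid consistency
  expect_true(all(man$shift_px == 32L))
  expect_equal(man$stage_x_mm, man$grid_col * s$grid$step * 1e3)
  expect_equal(man$stage_y_mm, man$grid_row * s$grid$step * 1e3)

  # adjacent tiles agree exactly on their geometric overlap
  h <- scan$holograms
  key <- vapply(h, function(x) paste(x$grid_row, x$grid_col, x$z_index), "")
  a <- h[[match("0 0 1", key)]]$amplitude
  b <- h[[match("0 1 1", key)]]$amplitude
  expect_identical(a[, 33:96], b[, 1:64])
  v <- h[[match("1 0 1", key)]]$amplitude
  expect_identical(a[33:96, ], v[1:64, ])

  # deterministic: rerun is bitwise identical
  scan2 <- simulate_scan(s$obj, s$grid, s$optics, noise_sigma = 0)
  expect_identical(scan$holograms[[1]]$amplitude,
                   scan2$holograms[[1]]$amplitude)

  # object too small
  expect_error(simulate_scan(s$obj[1:80, 1:80], s$grid, s$optics),
               "128 x 128")
})
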