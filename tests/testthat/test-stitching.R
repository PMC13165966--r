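test_that("build_topology enumerates 4-neighbour pairs", {
  mk <- function(rows, cols)
    expand.grid(grid_row = 0:(rows - 1), grid_col = 0:(cols - 1))
  expect_equal(nrow(build_topology(mk(1, 1))), 0)
  expect_equal(nrow(build_topology(mk(2, 2))), 4)
  # counting oracle: rows (cols-1) + cols (rows-1)
  for (d in list(c(7, 7), c(3, 5), c(1, 4))) {
    topo <- build_topology(mk(d[1], d[2]))
    expect_equal(nrow(topo), d[1] * (d[2] - 1) + d[2] * (d[1] - 1))
    expect_equal(sum(topo$direction == "h"), d[1] * (d[2] - 1))
  }
  # missing cell named in the error
  man <- mk(2, 2)[-3, ]
  expect_error(build_topology(man), "\\(0,1\\)")
})

test_that("extract_overlap_rois spans the strip plus margin", {
  # bench geometry: 3552 px tiles at 57.7% overlap -> 2050 px strip
  r <- extract_overlap_rois(c(3552L, 3552L), c(3552L, 3552L), "h",
                            0.577, margin = 0)
  expect_equal(r$a$cols, c(3552 - 2050 + 1, 3552))
  expect_equal(r$b$cols, c(1, 2050))
  r10 <- extract_overlap_rois(c(3552L, 3552L), c(3552L, 3552L), "h",
                              0.577, margin = 0.10)
  expect_equal(diff(r10$b$cols) + 1, 2050 + round(0.10 * 3552))
  expect_equal(diff(r10$a$cols), diff(r10$b$cols))  # equal sizes

  # margin 0 on a small tile: exactly the theoretical strip
  r0 <- extract_overlap_rois(c(64L, 64L), c(64L, 64L), "v", 0.5, margin = 0)
  expect_equal(r0$a$rows, c(33, 64))
  expect_equal(r0$b$rows, c(1, 32))
  expect_equal(r0$offset_a, c(32L, 0L))

  # full overlap clamps to the whole tile
  rf <- extract_overlap_rois(c(64L, 64L), c(64L, 64L), "h", 0.999)
  expect_equal(rf$a$cols, c(1, 64))

  expect_error(extract_overlap_rois(c(64L, 64L), c(64L, 64L), "h", 0.05),
               "16 px")
  expect_error(extract_overlap_rois(c(64L, 64L), c(32L, 64L), "h", 0.5),
               "equal dimensions")
})

test_that("NCC matcher: identity, constructed shift, noise rejection", {
  set.seed(21)
  base <- matrix(stats::rnorm(120 * 120), 120, 120)
  roi <- base[21:84, 21:84]

  # identical ROIs: every correspondence displaces by (0, 0), peak ~ 1
  ms <- match_patches_ncc(roi, roi, patch_px = 32L)
  cm <- ms$correspondences
  expect_gt(nrow(cm), 1)
  expect_true(all(cm$ay == cm$by & cm$ax == cm$bx))
  expect_true(all(cm$confidence > 0.99))

  # roiB cut 7 rows down / 3 cols left: content of B at p sits in A at
  # p + (7, -3), so the modal (A - B) displacement is (7, -3); small
  # templates keep most of the grid fully inside the shared region
  roib <- base[28:91, 18:81]
  ms2 <- match_patches_ncc(roi, roib, patch_px = 16L)
  est <- estimate_pair_shift(ms2)
  expect_identical(c(est$dy, est$dx), c(7L, -3L))

  # independent noise: all confidences below the acceptance threshold
  ms3 <- match_patches_ncc(matrix(stats::rnorm(64^2), 64),
                           matrix(stats::rnorm(64^2), 64))
  expect_true(all(ms3$correspondences$confidence < 0.2))

  # constant ROI: explicit empty match set
  ms4 <- match_patches_ncc(matrix(1, 64, 64), matrix(1, 64, 64))
  expect_equal(nrow(ms4$correspondences), 0)
})

test_that("estimate_pair_shift: median gate + histogram voting", {
  mk_matches <- function(va, vb = NULL) {
    # build a match set whose (A - B) displacement vectors are the rows
    n <- nrow(va)
    structure(list(correspondences = data.frame(
      ay = va[, 1] + 100, ax = va[, 2] + 100,
      by = rep(100, n), bx = rep(100, n),
      confidence = rep(1, n)), matcher_name = "synthetic"),
      class = "match_set")
  }
  # unanimity: the bench-scale example displacement
  u <- mk_matches(matrix(rep(c(37, 1505), 10), ncol = 2, byrow = TRUE))
  e <- estimate_pair_shift(u)
  expect_identical(c(e$dy, e$dx, e$votes), c(37L, 1505L, 10L))
  expect_equal(e$support_fraction, 1)

  # 6 inliers at (5, 3) + 4 far outliers: brute-force vote count oracle
  vecs <- rbind(matrix(rep(c(5, 3), 6), ncol = 2, byrow = TRUE),
                c(50, 60), c(-40, 70), c(5, 90), c(80, 3))
  e2 <- estimate_pair_shift(mk_matches(vecs))
  med <- apply(vecs, 2, stats::median)
  radius <- max(3 * stats::median(sqrt(colSums((t(vecs) - med)^2))), 5)
  kept <- vecs[sqrt(colSums((t(vecs) - med)^2)) <= radius, , drop = FALSE]
  votes_oracle <- max(table(paste(kept[, 1], kept[, 2])))
  expect_identical(c(e2$dy, e2$dx), c(5L, 3L))
  expect_identical(e2$votes, as.integer(votes_oracle))
  expect_identical(e2$votes, 6L)
  expect_equal(e2$support_fraction, 0.6)

  # singleton
  s <- estimate_pair_shift(mk_matches(matrix(c(0, 0), 1)))
  expect_identical(c(s$dy, s$dx, s$votes), c(0L, 0L, 1L))

  expect_error(estimate_pair_shift(
    structure(list(correspondences = data.frame(
      ay = numeric(), ax = numeric(), by = numeric(), bx = numeric(),
      confidence = numeric())), class = "match_set")), "empty")
})

test_that("global_align solves chains, loops and perturbed loops", {
  sh <- function(dy, dx) structure(
    list(dy = as.integer(dy), dx = as.integer(dx), votes = 1L,
         support_fraction = 1, n_total = 1L), class = "shift_estimate")
  topo2 <- data.frame(a = 1L, b = 2L, direction = "h")
  lay <- global_align(list(sh(0, 1500)), topo2, 2, c(64L, 64L))
  expect_equal(lay$positions, matrix(c(0L, 0L, 0L, 1500L), 2, 2,
                                     byrow = TRUE), ignore_attr = TRUE)
  expect_equal(lay$canvas, c(64L, 1564L))

  # consistent 2x2 loop: zero residual, exact grid positions
  topo4 <- data.frame(a = c(1L, 3L, 1L, 2L), b = c(2L, 4L, 3L, 4L),
                      direction = c("h", "h", "v", "v"))
  sh4 <- list(sh(0, 40), sh(0, 40), sh(40, 0), sh(40, 0))
  lay4 <- global_align(sh4, topo4, 4, c(64L, 64L))
  expect_equal(lay4$positions,
               matrix(c(0L, 0L, 0L, 40L, 40L, 0L, 40L, 40L), 4, 2,
                      byrow = TRUE), ignore_attr = TRUE)
  # coverage counts 4 contributors where all tiles overlap
  expect_equal(max(lay4$coverage), 4L)

  # one shift perturbed by +2 px: compare to a least-squares oracle
  sh4b <- list(sh(0, 102), sh(0, 100), sh(100, 0), sh(100, 0))
  lay4b <- global_align(sh4b, topo4, 4, c(64L, 64L))
  A <- matrix(0, 4, 3)  # unknowns: tiles 2..4
  rhs <- c(102, 100, 0, 0)
  A[1, 1] <- 1                 # p2 - p1 = 102
  A[2, 3] <- 1; A[2, 2] <- -1  # p4 - p3 = 100
  A[3, 2] <- 1                 # p3 - p1 = 0
  A[4, 3] <- 1; A[4, 1] <- -1  # p4 - p2 = 0
  oracle_x <- round(qr.solve(crossprod(A), crossprod(A, rhs)))
  expect_equal(lay4b$positions[-1, 2], as.integer(oracle_x),
               ignore_attr = TRUE)

  # disconnected graph
  expect_error(global_align(list(sh(0, 10)), topo2, 3, c(8L, 8L)),
               "disconnected")
})

test_that("auto_crop finds the maximal fully covered rectangle", {
  # full coverage: identity
  cv <- matrix(1L, 20, 30)
  r <- auto_crop(matrix(stats::runif(600), 20, 30), cv)
  expect_equal(r$bounds, c(1L, 20L, 1L, 30L))

  # 10-px uncovered band on the left is removed exactly
  cv2 <- cv; cv2[, 1:10] <- 0L
  r2 <- auto_crop(matrix(0, 20, 30), cv2)
  expect_equal(r2$bounds, c(1L, 20L, 11L, 30L))

  # brute-force oracle on random small masks
  brute <- function(mask) {
    best <- 0
    for (r0 in 1:nrow(mask)) for (r1 in r0:nrow(mask))
      for (c0 in 1:ncol(mask)) for (c1 in c0:ncol(mask))
        if (all(mask[r0:r1, c0:c1] >= 1))
          best <- max(best, (r1 - r0 + 1) * (c1 - c0 + 1))
    best
  }
  set.seed(31)
  for (i in 1:5) {
    mask <- matrix(rbinom(80, 1, 0.7), 8, 10)
    if (!any(mask == 1)) next
    b <- auto_crop(matrix(0, 8, 10), mask)$bounds
    expect_true(all(mask[b[1]:b[2], b[3]:b[4]] >= 1))
    expect_equal((b[2] - b[1] + 1) * (b[4] - b[3] + 1), brute(mask))
  }
  expect_error(auto_crop(matrix(0, 4, 4), matrix(0L, 4, 4)), "empty")
})

test_that("blend implements the weighted-accumulation formula", {
  sh <- function(dy, dx) structure(
    list(dy = as.integer(dy), dx = as.integer(dx), votes = 1L,
         support_fraction = 1, n_total = 1L), class = "shift_estimate")
  # single tile passes through bit-for-bit
  set.seed(41)
  tile <- matrix(stats::runif(64), 8, 8)
  lay1 <- global_align(list(), data.frame(a = integer(), b = integer(),
                                          direction = character()),
                       1, c(8L, 8L))
  expect_identical(blend(list(tile), lay1), tile)

  # two overlapping constant tiles stay constant (convexity)
  topo <- data.frame(a = 1L, b = 2L, direction = "h")
  lay2 <- global_align(list(sh(0, 4)), topo, 2, c(8L, 8L))
  out <- blend(list(matrix(3, 8, 8), matrix(3, 8, 8)), lay2)
  expect_equal(out[, 1:12], matrix(3, 8, 12))

  # the worked overlap pixel: values 2 & 4, weights 1 & 3 -> 3.5
  # canvas col 2 holds tile A col 2 (value 4, weight 3) over tile B col 1
  # (value 2, weight 1)
  wp <- function(dims) matrix(c(1, 3), dims[1], dims[2], byrow = TRUE)
  lay3 <- global_align(list(sh(0, 1)), topo, 2, c(1L, 2L))
  out3 <- blend(list(matrix(c(9, 4), 1), matrix(c(2, 9), 1)), lay3, wp)
  expect_equal(out3[1, 2], (4 * 3 + 2 * 1) / 4)

  # convex-combination bound on random overlapping tiles
  for (i in 1:5) {
    ta <- matrix(stats::runif(64), 8, 8); tb <- matrix(stats::runif(64), 8, 8)
    lay <- global_align(list(sh(0, 3)), topo, 2, c(8L, 8L))
    ov <- blend(list(ta, tb), lay)
    # overlap columns 4..8 of the canvas = tile A cols 4..8, tile B 1..5
    lo <- pmin(ta[, 4:8], tb[, 1:5]); hi <- pmax(ta[, 4:8], tb[, 1:5])
    expect_true(all(ov[, 4:8] >= lo - 1e-12 & ov[, 4:8] <= hi + 1e-12))
  }
})

test_that("stitch_plane recovers ground truth on a noiseless scan", {
  s <- small_scan()
  h <- s$scan$holograms
  zi <- vapply(h, function(x) x$z_index, integer(1))
  p1 <- h[zi == 1L]
  res <- stitch_plane(p1, matcher = s$matcher)
  # every estimated pair shift equals the manifest ground truth (32 px)
  topo <- res$shifts$topology
  for (k in seq_along(res$shifts$estimates)) {
    tru <- if (topo$direction[k] == "h") c(0L, 32L) else c(32L, 0L)
    expect_identical(c(res$shifts$estimates[[k]]$dy,
                       res$shifts$estimates[[k]]$dx), tru)
  }
  expect_equal(res$n_fallback, 0L)
  # stitched plane equals the directly simulated full-field hologram
  cb <- res$crop_bounds
  full <- s$scan$full_fields[[1]][cb[1]:cb[2], cb[3]:cb[4]]
  expect_lt(rms(res$hologram$amplitude - full), 1e-6)

  # 1x1 scan is the identity
  single <- hologram(p1[[1]]$amplitude, p1[[1]]$pitch, p1[[1]]$z)
  res1 <- stitch_plane(list(single))
  expect_identical(res1$hologram$amplitude, single$amplitude)
})

test_that("stitch_dataset co-registers planes via shared crop bounds", {
  s <- small_scan()
  st <- stitch_dataset(s$scan$holograms, reference_index = 1L,
                       matcher = s$matcher)
  expect_length(st$planes, 2)
  expect_identical(st$planes[[1]]$crop_bounds, st$planes[[2]]$crop_bounds)
  expect_identical(dim(st$planes[[1]]$hologram$amplitude),
                   dim(st$planes[[2]]$hologram$amplitude))
})
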