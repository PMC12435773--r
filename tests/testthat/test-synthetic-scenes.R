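test_that("scene generation is deterministic under a fixed seed", {
  pre <- preset("wt_cag130")
  s1 <- make_cell(pre, rng_seed = 42)
  s2 <- make_cell(pre, rng_seed = 42)
  expect_identical(s1, s2)
  t1 <- simulate_trajectory(0.5, rng_seed = 42)
  t2 <- simulate_trajectory(0.5, rng_seed = 42)
  expect_identical(t1, t2)
  f1 <- simulate_fluctuation(1, 30, rng_seed = 42)
  f2 <- simulate_fluctuation(1, 30, rng_seed = 42)
  expect_identical(f1, f2)
  st1 <- render(s1, pre, channels = "locus", rng_seed = 7)
  st2 <- render(s2, pre, channels = "locus", rng_seed = 7)
  expect_identical(st1, st2)
})

test_that("degenerate zone weights pin the planted zone", {
  pre1 <- scene_preset("all_z1", zone1_weight = 1)
  zones <- vapply(1:40, function(i) make_cell(pre1, rng_seed = i)$zone_true,
                  integer(1))
  expect_true(all(zones == 1L))
})

test_that("zone-weight mixtures produce the expected zone-1 marginal", {
  ## uniform placement: thirds, within 3 sigma binomial on 6000 draws
  n <- 6000
  u <- vapply(1:n, function(i) {
    make_cell(scene_preset("u", zone1_weight = 0), rng_seed = i)$zone_true
  }, integer(1))
  frac <- tabulate(u, 3) / n
  expect_true(all(abs(frac - 1 / 3) < 3 * sqrt(1 / 3 * 2 / 3 / n)))
  ## positive weight w: zone-1 fraction w + (1 - w)/3
  w <- 0.4
  zw <- vapply(1:n, function(i) {
    make_cell(scene_preset("w", zone1_weight = w), rng_seed = n + i)$zone_true
  }, integer(1))
  pexp <- w + (1 - w) / 3
  expect_lt(abs(mean(zw == 1) - pexp), 3 * sqrt(pexp * (1 - pexp) / n))
  ## negative weight: peripheral depletion to (1 - |w|)/3
  zn <- vapply(1:n, function(i) {
    make_cell(scene_preset("d", zone1_weight = -0.3), rng_seed = 2 * n + i)$zone_true
  }, integer(1))
  pdep <- (1 - 0.3) / 3
  expect_lt(abs(mean(zn == 1) - pdep), 3 * sqrt(pdep * (1 - pdep) / n))
})

test_that("scene invariants hold: locus inside nucleus, DIMs anchored at the SPB", {
  pre <- preset("mms_hu")
  for (i in 1:60) {
    sc <- make_cell(pre, rng_seed = i)
    expect_lt(sqrt(sum((sc$locus_true - sc$nucleus_centre)^2)),
              sc$nucleus_radius + 1e-9)
    ## SPB embedded in the envelope
    expect_equal(sqrt(sum((sc$spb_true - sc$nucleus_centre)^2)),
                 sc$nucleus_radius, tolerance = 1e-6)
    for (seg in sc$dim_segments) {
      expect_equal(seg[1, ], sc$spb_true, tolerance = 1e-9)
    }
  }
})

test_that("noise-free rendering puts the brightest voxel at the source", {
  pre <- scene_preset("clean", zone1_weight = 0, snr = Inf)
  sc <- make_cell(pre, rng_seed = 5)
  st <- render(sc, pre, channels = c("locus", "tubulin"))
  vx <- arrayInd(which.max(st$channels$locus), st$dim) - 1
  pos <- vx * c(pre$pixel_size, pre$pixel_size, pre$z_step)
  expect_true(all(abs(pos - sc$locus_true) <=
                    c(pre$pixel_size, pre$pixel_size, pre$z_step) + 1e-9))
  ## without a DIM the tubulin channel is a single point source: every
  ## above-background voxel lies within the SPB blob
  expect_length(sc$dim_segments, 0)
  hot <- arrayInd(which(st$channels$tubulin > 10 + 1), st$dim) - 1
  pos_hot <- hot * rep(c(pre$pixel_size, pre$pixel_size, pre$z_step),
                       each = nrow(hot))
  d <- sqrt(rowSums((pos_hot - matrix(sc$spb_true, nrow(hot), 3,
                                      byrow = TRUE))^2))
  expect_lt(max(d), 1.2)
})

test_that("trajectory simulator honours its degenerate limits", {
  ## no diffusion: locus static relative to the nucleus
  tr <- simulate_trajectory(0.5, diffusion = 0, n_frames = 50, rng_seed = 1)
  msd <- compute_msd(drift_correct(tr), 20)
  expect_true(all(msd$msd == 0))
  ## pure drift without correction is ballistic: MSD = (v dt)^2
  trd <- simulate_trajectory(0.5, diffusion = 0, n_frames = 50,
                             drift = 0.05, rng_seed = 2)
  msd_d <- compute_msd(trd, 20)
  v <- 0.05 / 1.5  # um per second
  expect_equal(msd_d$msd, (v * msd_d$lag_s)^2, tolerance = 1e-9)
})

test_that("equilibrated confined diffusion plateaus at 4/5 rc^2 in projection", {
  ## uniform-in-sphere second-moment oracle: E|dr_2D|^2 = 2 * 2/5 * rc^2
  rc <- 0.6
  trajs <- lapply(1:40, function(i) {
    simulate_trajectory(rc, diffusion = 0.01, n_frames = 400, rng_seed = 100 + i)
  })
  curve <- ensemble_msd(trajs, 200)
  tail_msd <- mean(curve$msd[curve$lag_s >= 150])
  expect_equal(tail_msd, 4 / 5 * rc^2, tolerance = 0.1)
})

test_that("fluctuation simulator matches the closed-form zero fraction", {
  expect_true(all(simulate_fluctuation(0, 50, rng_seed = 1)$counts == 0))
  sim <- simulate_fluctuation(1, 1e4, rng_seed = 2)
  p0 <- exp(-1)
  expect_lt(abs(mean(sim$counts == 0) - p0), 3 * sqrt(p0 * (1 - p0) / 1e4))
})

test_that("stacks round-trip through TIFF with ground-truth sidecar", {
  pre <- preset("wt_cag130")
  sc <- make_cell(pre, rng_seed = 9)
  st <- render(sc, pre, channels = c("ring", "locus"), rng_seed = 10)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path, scene = sc)
  back <- read_stack(path)
  expect_identical(back$dim, st$dim)
  expect_equal(back$pixel_size, st$pixel_size)
  ## 16-bit quantisation: relative error bounded by scale / 2^16
  scale <- max(vapply(st$channels, max, numeric(1)))
  expect_lt(max(abs(back$channels$ring - st$channels$ring)), scale / 2^15)
  gt <- attr(back, "ground_truth")
  expect_equal(gt$zone_true, sc$zone_true)
  expect_equal(unlist(gt$locus_true), sc$locus_true, tolerance = 1e-9)
})

test_that("presets round-trip through JSON and validate their fields", {
  pre <- preset("mms_hu")
  path <- withr::local_tempfile(fileext = ".json")
  write_preset(pre, path)
  expect_equal(unclass(read_preset(path)), unclass(pre))
  expect_error(scene_preset("bad", dim_prevalence = 1.5))
  expect_error(scene_preset("bad", nucleus_radius = -1))
  expect_error(scene_preset("bad", zone1_weight = 2))
})
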