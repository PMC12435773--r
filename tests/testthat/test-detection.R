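## helper: a bare ImageStack from raw channel arrays
stack_from <- function(channels, pixel_size = 0.065, z_step = 0.175) {
  structure(list(channels = channels, pixel_size = pixel_size,
                 z_step = z_step, dim = dim(channels[[1]])),
            class = "ImageStack")
}

test_that("periphery fit recovers a synthetic ring to sub-pixel accuracy", {
  pre <- scene_preset("clean", zone1_weight = 0, snr = Inf)
  sc <- make_cell(pre, rng_seed = 3)
  st <- render(sc, pre, channels = "ring")
  mid <- round(sc$nucleus_centre[3] / pre$z_step) + 1
  nuc <- fit_periphery(st$channels$ring[, , mid], pre$pixel_size)
  dz <- (mid - 1) * pre$z_step - sc$nucleus_centre[3]
  r_true <- sqrt(pre$nucleus_radius^2 - dz^2)
  expect_lt(abs(nuc$radius - r_true), 0.5 * pre$pixel_size)
  expect_lt(sqrt(sum((nuc$center - sc$nucleus_centre[1:2])^2)),
            0.5 * pre$pixel_size)
})

test_that("periphery fit rejects blank images and survives salt noise", {
  blank <- matrix(10, 51, 51)
  expect_error(fit_periphery(blank, 0.065), "ring signal")
  ## noisy ring with 10% salt pixels: centre still within 1 px
  pre <- scene_preset("noisy", zone1_weight = 0, snr = 10)
  sc <- make_cell(pre, rng_seed = 4)
  st <- render(sc, pre, channels = "ring", rng_seed = 5)
  mid <- round(sc$nucleus_centre[3] / pre$z_step) + 1
  plane <- st$channels$ring[, , mid]
  set.seed(6)
  salt <- sample(length(plane), round(0.1 * length(plane)))
  plane[salt] <- max(plane)
  nuc <- fit_periphery(plane, pre$pixel_size)
  expect_lt(sqrt(sum((nuc$center - sc$nucleus_centre[1:2])^2)),
            1 * pre$pixel_size)
})

test_that("focus detection finds planted spots and nothing in noise", {
  pre <- preset("wt_cag130")
  sc <- make_cell(pre, rng_seed = 21)
  st <- render(sc, pre, channels = "locus", rng_seed = 22)
  foci <- detect_foci(st, "locus")
  expect_length(foci, 1)
  expect_lt(sqrt(sum((foci[[1]]$position - sc$locus_true)^2)),
            sqrt(2 * pre$pixel_size^2 + pre$z_step^2))
  ## blank Poisson noise yields no detections at the default policy
  set.seed(23)
  noise <- array(rpois(51 * 51 * 25, 10), c(51, 51, 25))
  expect_length(detect_foci(stack_from(list(locus = noise)), "locus"), 0)
})

test_that("two spots five pixels apart are resolved as two foci", {
  pre <- scene_preset("pair", zone1_weight = 0, snr = Inf)
  sc1 <- make_cell(pre, rng_seed = 24)
  sc2 <- sc1
  sc2$locus_true <- sc1$locus_true + c(5 * pre$pixel_size, 0, 0)
  st1 <- render(sc1, pre, channels = "locus")
  st2 <- render(sc2, pre, channels = "locus")
  combined <- st1$channels$locus + st2$channels$locus - 10  # single background
  foci <- detect_foci(stack_from(list(locus = combined)), "locus")
  expect_length(foci, 2)
})

test_that("SPB detection returns the brightest focus and recovers the planted SPB", {
  pre <- preset("spb_offset")
  sc <- make_cell(pre, rng_seed = 25)
  st <- render(sc, pre, channels = c("tubulin", "locus"), rng_seed = 26)
  spb <- detect_spb(st, centre_hint = sc$nucleus_centre)
  expect_lt(sqrt(sum((spb$position - sc$spb_true)^2)), 0.15)
  expect_error(detect_spb(stack_from(list(tubulin = array(10, c(31, 31, 9))))),
               "no SPB")
})

test_that("DIM detector recovers planted DIMs with accurate length", {
  pre <- preset("mms_hu")
  hits <- 0; total <- 0
  for (i in 1:30) {
    sc <- make_cell(pre, rng_seed = 400 + i)
    if (!length(sc$dim_segments)) next
    total <- total + 1
    st <- render(sc, pre, channels = "tubulin", rng_seed = 500 + i)
    spb <- detect_spb(st, centre_hint = sc$nucleus_centre)
    dd <- detect_dim(st, spb)
    if (!dd$present) next
    hits <- hits + 1
    L <- sqrt(sum((sc$dim_segments[[1]][2, ] - sc$dim_segments[[1]][1, ])^2))
    expect_lt(abs(dd$length - L) / L, 0.2)
    expect_true(dd$anchored_at_spb)
  }
  expect_gte(hits / total, 0.9)
})

test_that("DIM detector stays silent without a DIM and vetoes bipolar spindles", {
  pre <- scene_preset("spb_only", zone1_weight = 0, dim_prevalence = 0)
  fp <- 0
  for (i in 1:25) {
    sc <- make_cell(pre, rng_seed = 600 + i)
    st <- render(sc, pre, channels = "tubulin", rng_seed = 700 + i)
    spb <- detect_spb(st, centre_hint = sc$nucleus_centre)
    if (detect_dim(st, spb)$present) fp <- fp + 1
  }
  expect_lt(fp / 25, 0.05 + 1e-9)
  ## bipolar: two opposite 1-um segments from the SPB read as a spindle
  sc <- make_cell(pre, rng_seed = 800)
  inward <- (sc$nucleus_centre - sc$spb_true)
  inward <- inward / sqrt(sum(inward^2))
  sc$dim_segments <- list(rbind(sc$spb_true, sc$spb_true + 1.0 * inward),
                          rbind(sc$spb_true, sc$spb_true - 0.9 * inward))
  st <- render(sc, pre, channels = "tubulin", rng_seed = 801)
  spb <- detect_spb(st, centre_hint = sc$nucleus_centre)
  expect_false(detect_dim(st, spb)$present)
  ## the same scene with only the inward arm is a DIM
  sc$dim_segments <- sc$dim_segments[1]
  st1 <- render(sc, pre, channels = "tubulin", rng_seed = 802)
  spb1 <- detect_spb(st1, centre_hint = sc$nucleus_centre)
  expect_true(detect_dim(st1, spb1)$present)
})

test_that("colocalization requires a shared voxel, not adjacency", {
  a <- array(FALSE, c(5, 5, 3)); b <- array(FALSE, c(5, 5, 3))
  a[2, 2, 2] <- TRUE; b[2, 2, 2] <- TRUE
  expect_true(colocalize(a, b))
  ## edge-adjacent ("touching") masks do not overlap
  b2 <- array(FALSE, c(5, 5, 3)); b2[3, 2, 2] <- TRUE
  expect_false(colocalize(a, b2))
  ## corner adjacency is still touching
  b3 <- array(FALSE, c(5, 5, 3)); b3[3, 3, 3] <- TRUE
  expect_false(colocalize(a, b3))
  expect_true(colocalize(a, a))
  ## symmetry and dilation monotonicity
  expect_identical(colocalize(a, b2), colocalize(b2, a))
  dilate1 <- function(m) {
    out <- m
    idx <- which(m, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      p <- idx[k, ]
      out[max(1, p[1] - 1):min(dim(m)[1], p[1] + 1),
          max(1, p[2] - 1):min(dim(m)[2], p[2] + 1),
          max(1, p[3] - 1):min(dim(m)[3], p[3] + 1)] <- TRUE
    }
    out
  }
  expect_true(colocalize(dilate1(a), b2))   # touching becomes overlap
  expect_true(colocalize(dilate1(a), dilate1(b)))
  expect_error(colocalize(a, array(FALSE, c(4, 5, 3))), "dimensions")
})

test_that("SPB-locus distances are exact on coordinates and unbiased on scenes", {
  expect_equal(spb_locus_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(spb_locus_distance(c(0, 0, 0), c(0.6, 0, 0)), 0.6)
  pre <- preset("spb_offset")
  d <- vapply(1:40, function(i) {
    sc <- make_cell(pre, rng_seed = 900 + i)
    st <- render(sc, pre, channels = c("tubulin", "locus"), rng_seed = 950 + i)
    spb <- detect_spb(st, centre_hint = sc$nucleus_centre)
    locus <- detect_foci(st, "locus")[[1]]
    c(spb_locus_distance(spb, locus),
      spb_locus_distance(sc$spb_true, sc$locus_true))
  }, numeric(2))
  expect_lt(abs(mean(d[1, ]) - mean(d[2, ])) / mean(d[2, ]), 0.05)
})

test_that("detectors are deterministic given identical stacks", {
  pre <- preset("mms")
  sc <- make_cell(pre, rng_seed = 31)
  st <- render(sc, pre, channels = c("ring", "locus", "tubulin"),
               rng_seed = 32)
  expect_identical(detect_foci(st, "locus"), detect_foci(st, "locus"))
  spb <- detect_spb(st)
  expect_identical(detect_dim(st, spb), detect_dim(st, spb))
  expect_identical(score_cell(st), score_cell(st))
})
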