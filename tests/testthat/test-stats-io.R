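test_that("zone chi-squared matches the hand-computed contingency oracle", {
  ta <- data.frame(condition = "a", n1 = 50, n2 = 25, n3 = 25)
  tb <- data.frame(condition = "b", n1 = 25, n2 = 25, n3 = 50)
  ## hand computation: row totals 100/100, column totals 75/50/75,
  ## expected (37.5, 25, 37.5) per row, X^2 = 4 * 12.5^2 / 37.5 = 50/3
  r <- zone_chisq(ta, tb)
  expect_equal(r$statistic, 50 / 3, tolerance = 1e-8)
  expect_equal(r$dof, 2)
  expect_equal(r$p_raw, stats::pchisq(50 / 3, 2, lower.tail = FALSE),
               tolerance = 1e-8)
  ## doubling all counts doubles the statistic
  ta2 <- ta; tb2 <- tb
  ta2[, 2:4] <- ta[, 2:4] * 2; tb2[, 2:4] <- tb[, 2:4] * 2
  expect_equal(zone_chisq(ta2, tb2)$statistic, 2 * r$statistic,
               tolerance = 1e-8)
  ## identical tallies: statistic 0, p 1
  same <- zone_chisq(ta, ta)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_raw, 1)
  ## zero-margin zone reduces dof with a flag
  tz <- data.frame(condition = "z", n1 = 30, n2 = 20, n3 = 0)
  tz2 <- data.frame(condition = "z2", n1 = 20, n2 = 30, n3 = 0)
  rz <- zone_chisq(tz, tz2)
  expect_equal(rz$dof, 1)
  expect_true(any(grepl("zero-margin", rz$flags)))
})

test_that("Bonferroni adjustment caps at one and preserves order", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 5), 1)
  p <- c(0.001, 0.02, 0.2)
  expect_equal(order(bonferroni(p, 6)), order(p))
  ## explicit family size must cover the supplied values
  expect_error(bonferroni(c(0.1, 0.2), 1))
  ## agrees with p.adjust when the family is the supplied vector
  expect_equal(bonferroni(p), stats::p.adjust(p, "bonferroni"))
})

test_that("Welch's t matches the closed-form statistic", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6, 19.0, 21.7, 21.4)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.1, 22.9, 30.5, 31.2)
  ## closed-form Welch statistic and Welch-Satterthwaite dof
  se2a <- stats::var(a) / length(a); se2b <- stats::var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_hand <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  r <- welch_t(a, b)
  expect_equal(r$statistic, t_hand, tolerance = 1e-8)
  expect_equal(r$dof, df_hand, tolerance = 1e-8)
  expect_equal(r$p_raw, 2 * stats::pt(-abs(t_hand), df_hand),
               tolerance = 1e-8)
  ## swapping samples flips the sign only
  r2 <- welch_t(b, a)
  expect_equal(r2$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(r2$p_raw, r$p_raw, tolerance = 1e-12)
  expect_error(welch_t(c(1, 1), c(1, 1)), "variance")
})

test_that("per-cell CSV zoning applies the gates and tallies correctly", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:6),
    focus_x = c(0.9, 0.1, 0.7, 0.9, 0.9, 2.0),
    focus_y = 0,
    plane = c(12, 12, 12, 1, 12, 12),
    center_x = 0, center_y = 0, radius = 1, n_planes = 25,
    bud_area = c(4, 4, 4, 4, 0, 4),
    mother_area = 10,
    condition = "a")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cells, path, row.names = FALSE)
  res <- zone_cells_csv(path)
  ## cell 4 fails the mid-stack gate, cell 5 is G1, cell 6 is off-nucleus
  expect_identical(res$cells$kept,
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  tal <- res$tallies
  expect_identical(c(tal$n1, tal$n2, tal$n3), c(1L, 1L, 1L))
  ## schema violations are reported
  bad <- cells[, -2]
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(zone_cells_csv(path), "missing columns")
})

test_that("the configured pipeline runs end to end and is reproducible", {
  config <- list(seed = 77,
                 zoning = list(preset = "wt_cag130", n = 25),
                 mobility = list(rc_true = 0.5, n_traj = 10, n_frames = 150),
                 fluctuation = list(m_true = 1, n_cultures = 30, N_t = 1e7))
  out1 <- withr::local_tempdir()
  rep1 <- run_pipeline(config, out_dir = out1)
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_identical(rep1$zoning$n, 25L)
  ## reported zone-1 percent matches the tally arithmetic
  expect_equal(rep1$zoning$zone1_percent,
               100 * rep1$zoning$tally$n1 / rep1$zoning$tally$n_total)
  expect_equal(rep1$mobility$rc, sqrt(5 / 4 * rep1$mobility$plateau))
  expect_true(rep1$fluctuation$m_hat > 0)
  ## same config, same seed: byte-identical report
  out2 <- withr::local_tempdir()
  run_pipeline(config, out_dir = out2)
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
  expect_error(run_pipeline(list(zoning = list(preset = "mms", n = 5))),
               "seed")
})
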