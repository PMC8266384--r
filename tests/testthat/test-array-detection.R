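test_that("psi folding honours the Cn symmetry range", {
  expect_equal(fold_psi(-5, 2), 175)
  expect_equal(fold_psi(190, 2), 10)
  expect_equal(fold_psi(45, 1), 45)
  expect_error(fold_psi(NaN, 2), "finite")
  # idempotence over random angles and folds
  set.seed(1)
  for (n in c(1, 2, 3, 6)) {
    psi <- runif(200, -1000, 1000)
    f <- fold_psi(psi, n)
    expect_true(all(f >= 0 & f < 360 / n))
    expect_equal(fold_psi(f, n), f)
  }
})

test_that("delta-psi is symmetric, zero on identity, and folds correctly", {
  expect_equal(delta_psi(170, 175, 2), 5)
  expect_equal(delta_psi(10, 350, 2, circular = FALSE), 160)
  expect_equal(delta_psi(10, 350, 2, circular = TRUE), 20)
  set.seed(2)
  a <- runif(100, -720, 720); b <- runif(100, -720, 720)
  expect_equal(delta_psi(a, b, 2), delta_psi(b, a, 2))
  expect_equal(delta_psi(a, a, 2), rep(0, 100))
  expect_true(all(delta_psi(a, b, 2, circular = TRUE) <= 90))
})

test_that("pixel-to-Angstrom conversion multiplies by the pixel size", {
  expect_equal(px_to_angstrom(170, 1.26), 214.2)
  expect_equal(px_to_angstrom(0, 3.1), 0)
  expect_equal(px_to_angstrom(100, 1.08), 108)
  expect_error(px_to_angstrom(10, 0), "positive")
})

test_that("collinear particles pair only within the cutoff", {
  tab <- particle_table("m1", x_px = c(0, 100, 200), y_px = c(0, 0, 0),
                        psi_deg = c(0, 0, 0), pixel_size_A = 1.26)
  pr <- find_pairs(tab, array_config(cutoff_px = 170))
  expect_equal(nrow(pr), 2)
  expect_equal(pr$distance_A, c(126, 126))
  expect_equal(pr$id_a, c(0, 1))
  expect_equal(pr$id_b, c(1, 2))
})

test_that("pairs never span micrographs", {
  tab <- particle_table(rep(c("m1", "m2"), each = 2),
                        x_px = c(0, 50, 0, 50), y_px = rep(0, 4),
                        psi_deg = rep(0, 4), pixel_size_A = 1)
  pr <- find_pairs(tab, array_config(cutoff_px = 170, pixel_size_A = 1))
  expect_equal(nrow(pr), 2)
  expect_true(all(table(pr$micrograph) == 1))
})

test_that("the cell-list search equals the all-against-all oracle", {
  set.seed(3)
  cfg <- array_config()
  for (rep in 1:10) {
    tab <- random_table(n = sample(2:200, 1), n_mic = sample(1:3, 1),
                        field = 1500)
    got <- find_pairs(tab, cfg)
    want <- brute_force_pairs(tab, cfg)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$id_a, want$id_a)
    expect_equal(got$id_b, want$id_b)
    expect_equal(got$distance_A, want$distance_A)
    expect_equal(got$dpsi_deg, want$dpsi_deg)
  }
  # empty table is an empty result, not an error
  expect_equal(nrow(find_pairs(random_table(5)[0, ], cfg)), 0)
})

test_that("binning conserves counts and normalizes to the maximum", {
  cfg <- array_config()
  ident <- data.frame(micrograph = "m", id_a = 0:9, id_b = 10:19,
                      distance_A = rep(181, 10), dpsi_deg = rep(4.5, 10))
  g <- bin_pairs(ident, cfg)
  expect_equal(sum(g$counts), 10)
  expect_equal(max(g$counts), 10)
  expect_equal(max(g$normalized), 1)
  expect_equal(sum(g$counts > 0), 1)

  set.seed(4)
  tab <- random_table(150, n_mic = 2, field = 800)
  pr <- find_pairs(tab, cfg)
  g2 <- bin_pairs(pr, cfg)
  expect_equal(sum(g2$counts), nrow(pr))
  expect_true(all(g2$normalized >= 0 & g2$normalized <= 1))
  expect_error(bin_pairs(pr[0, ], cfg), "no particle pairs")
})

test_that("a value exactly on a bin edge goes to the upper bin", {
  cfg <- array_config(dist_bin_A = 2, dpsi_bin_deg = 2.6)
  pr <- data.frame(micrograph = "m", id_a = 0, id_b = 1,
                   distance_A = 4, dpsi_deg = 2.6)
  g <- bin_pairs(pr, cfg)
  hit <- which(g$counts == 1, arr.ind = TRUE)
  expect_equal(unname(hit[1, 1]), 3)  # [4, 6) is the third distance bin
  expect_equal(unname(hit[1, 2]), 2)  # [2.6, 5.2) is the second angle bin
})

test_that("peak extraction reports raw-pair statistics for the component", {
  cfg <- array_config()
  pr <- data.frame(micrograph = "m", id_a = 0:9, id_b = 10:19,
                   distance_A = rep(181, 10), dpsi_deg = rep(4.5, 10))
  pk <- extract_peak(bin_pairs(pr, cfg), pr, cfg)
  expect_equal(pk$mean_distance_A, 181)
  expect_equal(pk$sd_distance_A, 0)
  expect_equal(pk$mean_dpsi_deg, 4.5)
  expect_equal(pk$sd_dpsi_deg, 0)
  expect_equal(pk$n_pairs_in_peak, 10)
})

test_that("equal-height separated peaks break ties in scan order", {
  cfg <- array_config(peak_threshold = 0.5)
  # two delta peaks of equal height, well separated in distance
  pr <- data.frame(micrograph = "m", id_a = 1:10, id_b = 21:30,
                   distance_A = rep(c(51, 151), each = 5),
                   dpsi_deg = rep(10, 10))
  pk <- extract_peak(bin_pairs(pr, cfg), pr, cfg)
  # distance-major scan meets the 51 A peak first
  expect_equal(pk$mean_distance_A, 51)
  expect_equal(pk$n_pairs_in_peak, 5)
})

test_that("the peak component is 4-connected above the threshold", {
  cfg <- array_config(peak_threshold = 0.5)
  # centre bin 10 pairs; 4-neighbour bin 6 pairs (>= 0.5); a third
  # above-threshold bin touching the component only diagonally must be
  # excluded
  pr <- data.frame(
    micrograph = "m", id_a = seq_len(22), id_b = 100 + seq_len(22),
    distance_A = c(rep(101, 10), rep(103, 6), rep(105, 6)),
    dpsi_deg   = c(rep(1, 10),   rep(1, 6),   rep(4, 6)))
  pk <- extract_peak(bin_pairs(pr, cfg), pr, cfg)
  expect_equal(pk$n_pairs_in_peak, 16)
  expect_equal(sort(unique(pk$peak_bins[, "dist_bin"])), c(51, 52))
})

test_that("the end-to-end analysis recovers planted arrays and is deterministic", {
  sim <- simulate_micrographs(array_model(n_arrays_per_micrograph = 10),
                              sim_config(n_micrographs = 3, n_background = 60,
                                         seed = 11))
  star <- tempfile(fileext = ".star")
  write_star(sim$table, star)
  out1 <- tempfile(); out2 <- tempfile()
  res <- suppressMessages(run_array_analysis(star, array_config(),
                                             outdir = out1))
  suppressMessages(run_array_analysis(star, array_config(), outdir = out2))
  expect_true(abs(res$peak$mean_distance_A - 181) <= 2)
  expect_true(abs(res$peak$mean_dpsi_deg - 4.5) <= 2.6)
  for (f in c("pairs.tsv", "grid.tsv", "summary.json"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  rec <- evaluate_recovery(sim$truth, res$peak, array_model())
  expect_true(rec$recovered)
})
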