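test_that("photon filter keeps the inclusive window and is idempotent", {
  tab <- loc_tab(0:4, photons = c(300, 420, 5000, 10000, 12000))
  f <- filter_photons(tab)
  expect_equal(f$photons, c(420, 5000, 10000))
  expect_identical(as.data.frame(filter_photons(f)), as.data.frame(f))
  expect_equal(attr(f, "frame_time_s"), attr(tab, "frame_time_s"))
  empty <- filter_photons(loc_tab(integer(0), photons = numeric(0)))
  expect_equal(nrow(empty), 0)
  expect_error(filter_photons(tab, 500, 500), "lo must be")
})

test_that("circular picks are boundary-inclusive and match brute force", {
  pk <- pick_region(c(0, 0), diameter_nm = 200)
  on_edge <- loc_tab(0:2, x = c(100, 100.001, 0), y = c(0, 0, -100))
  kept <- pick_circle(on_edge, pk)
  expect_equal(kept$frame, c(0L, 2L))
  set.seed(6)
  tab <- loc_tab(0:999, x = runif(1000, -2000, 2000), y = runif(1000, -2000, 2000))
  pk2 <- pick_region(c(250, -100), diameter_nm = 3180)
  got <- pick_circle(tab, pk2)
  manual <- sqrt((tab$x - 250)^2 + (tab$y + 100)^2) <= 1590
  expect_equal(nrow(got), sum(manual))
  expect_equal(got$x, tab$x[manual])
  # estimate invariance under joint translation is geometric: same membership
  shifted <- loc_tab(tab$frame, x = tab$x + 5000, y = tab$y - 3000)
  pk3 <- pick_region(c(5250, -3100), diameter_nm = 3180)
  expect_equal(pick_circle(shifted, pk3)$frame, got$frame)
})

test_that("event linking merges consecutive frames and bridges single-frame gaps", {
  ev <- link_events(loc_tab(c(10, 11, 12, 50)), ignore_gap = 1)
  expect_equal(ev$start_frame, c(10L, 50L))
  expect_equal(ev$end_frame, c(12L, 50L))
  expect_equal(ev$n_locs, c(3L, 1L))
  expect_equal(nrow(link_events(loc_tab(c(5, 7)), ignore_gap = 1)), 1)
  expect_equal(link_events(loc_tab(c(5, 7)))$end_frame, 7L)
  expect_equal(nrow(link_events(loc_tab(c(5, 8)), ignore_gap = 1)), 2)
  expect_equal(nrow(link_events(loc_tab(integer(0)))), 0)
})

test_that("dark times count wholly-empty frames between events", {
  ev <- link_events(loc_tab(c(10, 11, 12, 50)))
  expect_equal(dark_times(ev, 0.1), 3.7)
  expect_equal(dark_times(link_events(loc_tab(c(12, 14))), 0.1), numeric(0))  # bridged
  expect_equal(dark_times(link_events(loc_tab(c(12, 15)), ignore_gap = 1), 0.1), 0.2)
  expect_length(dark_times(link_events(loc_tab(5)), 0.1), 0)
})

test_that("influx rate is k_on times concentration and scales linearly", {
  expect_equal(influx_rate(kinetic_params(1.5e6, 1e-9)), 1.5e-3)
  expect_equal(influx_rate(kinetic_params(1.5e6, 2e-9)), 3.0e-3)
  k1 <- influx_rate(kinetic_params(c_M = 7e-10))
  expect_equal(influx_rate(kinetic_params(c_M = 1.4e-9)), 2 * k1)
  expect_error(kinetic_params(c_M = 0), "concentration")
})

test_that("binding-site counts follow n = 1/(xi tau) with background clamped at zero", {
  xi <- 1.5e-3
  est <- binding_sites(rep(2000 / 3, 6), xi, "mean")
  expect_equal(est$n_sites_raw, 1.0, tolerance = 1e-12)
  est10 <- binding_sites(rep(200 / 3, 6), xi, "mean")
  expect_equal(est10$n_sites_raw, 10.0, tolerance = 1e-12)
  expect_equal(est10$influx_per_s, xi)
  expect_error(binding_sites(rep(1, 4), xi, "mean"), "insufficient.*4 observed")
  expect_error(binding_sites(rep(1, 19), xi, "cdf_fit"), "insufficient")
  # cdf fit recovers tau on ideal exponential quantiles
  set.seed(7)
  dk <- stats::qexp(ppoints(500), rate = 1 / 50)
  fit <- binding_sites(dk, xi, "cdf_fit")
  expect_equal(fit$tau_fit_s, 50, tolerance = 0.05)
  expect_equal(subtract_background(49.21, 5.12), 44.09)
  expect_equal(subtract_background(3.0), 0)
  expect_equal(subtract_background(7.5, 0), 7.5)
})

test_that("TP10M normalization scales by genome-matched library depth", {
  expect_equal(tp10m(24, 24e6), 10)
  expect_equal(tp10m(5, 5), 1e7)
  expect_equal(tp10m(0, 1e6), 0)
  expect_error(tp10m(10, 0), "must be > 0")
})

test_that("2-D rendering conserves counts and scales with bin size", {
  set.seed(8)
  tab <- loc_tab(0:499, x = runif(500, 0, 1000), y = runif(500, 0, 800))
  g <- render_histogram(tab, 16)
  expect_equal(sum(g), 500)
  g1 <- render_histogram(loc_tab(0, x = 123, y = 456), 16)
  expect_equal(dim(g1), c(1L, 1L))
  expect_equal(sum(g1 != 0), 1)
  g8 <- render_histogram(tab, 8)
  expect_true(all(abs(dim(g8) - 2 * dim(g)) <= 2))
})

test_that("drift correction recovers an injected linear drift", {
  # static fiducials, no noise: nothing changes
  fid0 <- simulate_fiducials(2, c(0, 0), noise_nm = 0, n_frames = 400, seed = 9)
  tab <- loc_tab(c(0, 100, 399), x = c(10, 20, 30), y = c(5, 5, 5), n_frames = 400)
  dc0 <- drift_correct(tab, fid0, window = 50)
  expect_equal(dc0$table$x, tab$x, tolerance = 1e-9)
  expect_equal(max(abs(dc0$drift$dx)), 0, tolerance = 1e-9)
  # linear drift with 5 nm fiducial noise, 3 fiducials
  fids <- simulate_fiducials(3, c(0.01, -0.005), noise_nm = 5, n_frames = 5000,
                             seed = 10)
  tab2 <- loc_tab(0:4999, x = 0.01 * (0:4999), y = -0.005 * (0:4999), n_frames = 5000)
  dc <- drift_correct(tab2, fids)
  true_x <- 0.01 * (0:4999)
  true_y <- -0.005 * (0:4999)
  rms <- sqrt(mean((dc$drift$dx - true_x)^2 + (dc$drift$dy - true_y)^2))
  expect_lt(rms, 2)
  # corrected target localizations sit near their true (undrifted) origin
  expect_lt(max(abs(dc$table$x - 0)), 3 * rms + 1)
  expect_error(drift_correct(tab2, list()), "at least one")
  short_fid <- list(loc_tab(0:100, x = 0, y = 0, n_frames = 5000))
  expect_error(drift_correct(tab2, short_fid), "insufficient fiducial coverage")
})

test_that("channel registration recovers translations at the least-squares rate", {
  a <- cbind(c(0, 100, 50, -20), c(0, 40, -60, 80))
  expect_equal(unname(register_channels(a, a)), c(0, 0))
  sh <- register_channels(a, a + matrix(rep(c(25, -10), each = 4), ncol = 2))
  expect_equal(unname(sh), c(25, -10))
  set.seed(11)
  n <- 16
  fa <- cbind(runif(n, 0, 2e4), runif(n, 0, 2e4))
  fb <- fa + matrix(rep(c(33, -12), each = n), ncol = 2) + rnorm(2 * n, 0, 3)
  got <- register_channels(fa, fb)
  expect_lt(sqrt(sum((got - c(33, -12))^2)), 3 * 2 / sqrt(n) * 3)
  expect_error(register_channels(fa[1, , drop = FALSE], fb[1, , drop = FALSE]),
               "at least 2")
  # applying the registration aligns channel B to A
  tabb <- loc_tab(seq_len(n) - 1, x = fb[, 1], y = fb[, 2])
  aligned <- apply_registration(tabb, got)
  expect_lt(abs(mean(aligned$x - fa[, 1])), 2)
})

test_that("localization CSV round-trips records and metadata columns", {
  tab <- localization_table(c(0, 3, 7), c(1.5, 2.5, 3.5), c(9, 8, 7),
                            c(500, 600, 700), precision = c(8, 8, 9))
  tmp <- tempfile(fileext = ".csv")
  write_locs_csv(tab, tmp)
  back <- read_locs_csv(tmp)
  expect_equal(back$frame, tab$frame)
  expect_equal(back$x, tab$x)
  expect_equal(back$photons, tab$photons)
  expect_equal(back$precision, tab$precision)
  unlink(tmp)
  expect_error(localization_table(-1, 0, 0, 100), "frames")
  expect_error(localization_table(0, 0, 0, 0), "photon")
})
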