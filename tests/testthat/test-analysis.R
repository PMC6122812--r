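full_grid_output <- function(time = 0.05, nodes = 16, traces = "Population.1.Q") {
  cfg <- single_e_config(kind = "map", time = time, dt = 1e-3,
                         interval = 1e-3, nodes = nodes, out_nodes = "All",
                         traces = traces)
  run_nf(cfg)
}

test_that("extraction preserves order, selects subsets and rejects unknowns", {
  out <- full_grid_output()
  all_ts <- nf_extract(out, "Population.1.Q")
  expect_equal(names(all_ts)[1], "time")
  expect_equal(ncol(all_ts), 17)
  expect_equal(as.matrix(all_ts[-1]), out$data, ignore_attr = TRUE)

  sub <- nf_extract(out, "Population.1.Q", nodes = c(5, 2))
  expect_equal(names(sub), c("time", "node_5", "node_2"))
  expect_error(nf_extract(out, "Population.1.Q", nodes = integer()), "empty")
  expect_error(nf_extract(out, "Propagator.9.phi"), "not in output")
  expect_error(nf_extract(out, "Population.1.Q", nodes = 99), "not recorded")
})

test_that("grid reshaping inverts flattening and places nodes at their cells", {
  out <- full_grid_output()
  arr <- nf_to_grid(out, "Population.1.Q")
  expect_equal(dim(arr), c(length(out$times), 4, 4))
  expect_equal(matrix(arr, nrow = dim(arr)[1]), out$data, ignore_attr = TRUE)
  # a synthetic single-node spike lands at the right cell: node 1 -> (1, 1),
  # node 6 on a 4 x 4 sheet -> (2, 2)
  out2 <- out
  out2$data <- matrix(0, length(out$times), 16)
  out2$data[, 6] <- 1
  arr2 <- nf_to_grid(out2, "Population.1.Q")
  expect_equal(arr2[1, 2, 2], 1)
  expect_equal(sum(arr2), length(out$times))
  # partial coverage is an error
  out3 <- out
  keep <- out3$nodes != 3
  out3$data <- out3$data[, keep, drop = FALSE]
  out3$labels <- out3$labels[keep]; out3$nodes <- out3$nodes[keep]
  expect_error(nf_to_grid(out3, "Population.1.Q"), "full grid")
})

test_that("the Welch spectrum finds tones, satisfies Parseval for noise, and puts DC at zero", {
  fs <- 512
  t <- seq(0, 16 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  sp <- nf_spectrum(x, fs = fs)
  expect_equal(sp$frequencies[which.max(sp$power)], 10, tolerance = 1 / 4)
  expect_true(all(sp$power >= 0))
  expect_true(all(diff(sp$frequencies) > 0))

  set.seed(2)
  sigma <- 1.7
  w <- rnorm(2^15, sd = sigma)
  spw <- nf_spectrum(w, fs = fs, seg_seconds = 2)
  expect_equal(sum(spw$power) * diff(spw$frequencies[1:2]), sigma^2,
               tolerance = 0.03)
  expect_equal(mean(spw$power), sigma^2 / (fs / 2), tolerance = 0.1)

  const <- rep(4.2, 2048)
  spc <- nf_spectrum(const, fs = fs)
  expect_equal(which.max(spc$power), 1L)   # all power at f = 0 ...
  # ... up to the Hann mainlobe, which spans the first two bins
  expect_gt(sum(spc$power[1:2]) / sum(spc$power), 0.999)
  expect_error(nf_spectrum(1.0, fs = fs), "too short")
})

test_that("spectra are invariant to a recording start offset for stationary signals", {
  set.seed(9)
  fs <- 256
  x <- as.vector(stats::filter(rnorm(2^14 + 512), rep(0.2, 5), sides = 1))
  x <- x[!is.na(x)]
  s1 <- nf_spectrum(x[1:2^13], fs = fs, seg_seconds = 2)
  s2 <- nf_spectrum(x[513:(512 + 2^13)], fs = fs, seg_seconds = 2)
  band <- s1$frequencies > 5 & s1$frequencies < 100
  expect_equal(mean(s1$power[band]), mean(s2$power[band]), tolerance = 0.2)
})

test_that("a spatially uniform signal gives a spatial spectrum equal to the temporal one", {
  out <- full_grid_output(time = 2)
  # overwrite with an exactly uniform synthetic signal
  sig <- 3 + sin(2 * pi * 5 * out$times)
  out$data <- matrix(rep(sig, 16), ncol = 16)
  ssp <- nf_spatial_spectrum(out, "Population.1.Q", seg_seconds = 1)
  tsp <- nf_spectrum(sig, fs = 1 / out$config$output$interval, seg_seconds = 1)
  expect_equal(ssp$power, tsp$power, tolerance = 1e-10)
  # an enormous cutoff leaves the filter at unity
  ssp2 <- nf_spatial_spectrum(out, "Population.1.Q", k0 = 1e12, seg_seconds = 1)
  expect_equal(ssp2$power, ssp$power, tolerance = 1e-8)
})

test_that("a standing wave concentrates power in its |m| = 1 spatial modes", {
  out <- full_grid_output(time = 4)
  grid <- out$config$grids[[1]]
  f0 <- 8
  x <- (seq_len(grid$nx) - 0.5) * grid$dx
  profile <- as.vector(matrix(rep(cos(2 * pi * x / grid$lx), grid$ny),
                              grid$nx, grid$ny))
  out$data <- outer(cos(2 * pi * f0 * out$times), profile)
  ssp <- nf_spatial_spectrum(out, "Population.1.Q", seg_seconds = 2)
  fbin <- which.min(abs(ssp$frequencies - f0))
  pk <- ssp$power_k[fbin, ]
  m_of_mode <- as.vector(outer(round(ssp$k$kx * grid$lx / (2 * pi)),
                               round(ssp$k$ky * grid$ly / (2 * pi)),
                               function(mx, my) paste(mx, my)))
  target <- m_of_mode %in% c("1 0", "-1 0")
  expect_gt(sum(pk[target]) / sum(pk), 0.999)
  # total power peaks at the oscillation frequency
  expect_equal(ssp$frequencies[which.max(ssp$power)], f0, tolerance = 0.5)
})

test_that("wavenumbers lie on the 2 pi m / L lattice", {
  g <- nf_grid(12, 0.6, longside = 4)
  kk <- nf_wavenumbers(g)
  expect_equal(sort(kk$kx), sort(2 * pi * c(0, 1, 2, -1) / 0.6))
  expect_equal(sort(kk$ky), sort(2 * pi * c(0, 1, -1) / g$ly))
  expect_equal(dim(kk$k2), c(4, 3))
  expect_equal(kk$k2[1, 1], 0)
})

test_that("tidiers and plots expose results as tibbles and ggplots", {
  out <- full_grid_output(time = 0.01)
  td <- tidy(out)
  expect_s3_class(td, "tbl_df")
  expect_equal(names(td), c("time", "trace", "node", "value"))
  expect_equal(nrow(td), length(out$times) * ncol(out$data))
  gl <- glance(out)
  expect_equal(gl$n_samples, length(out$times))
  expect_s3_class(autoplot(out), "ggplot")

  sp <- nf_spectrum(rnorm(1024), fs = 128)
  expect_equal(names(tidy(sp)), c("frequency", "power"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$power, sp$power)
  expect_s3_class(autoplot(sp), "ggplot")
  expect_equal(glance(sp)$estimator, "welch")
  expect_output(nf_report(out), "populations")
})
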