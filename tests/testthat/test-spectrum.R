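# Spectrum analysis: running averages, trace summaries, mixture fits,
# curve averaging, extension fractions, scenario classification.

ramp_trace <- function(ext_peak = 5, f_peak = 150, n = 201L) {
  ext <- seq(0.5, 8, length.out = n)
  f <- ifelse(ext <= ext_peak,
              f_peak * (ext - 0.5) / (ext_peak - 0.5),
              f_peak * pmax(0, (7.8 - ext) / (7.8 - ext_peak)))
  force_trace(time = seq_len(n) * 1.0, extension = ext, force = f,
              n_beads = 31L)
}

scenario_trace <- function(order_break, n_beads = 20L, two_peaks = FALSE) {
  # contacts split across the chain midpoint; `order_break` gives the frame
  # at which each contact ruptures (NA = never)
  nc <- length(order_break)
  nfr <- 100L
  intact <- matrix(TRUE, nfr, nc)
  for (c in seq_len(nc)) {
    if (!is.na(order_break[c])) intact[order_break[c]:nfr, c] <- FALSE
  }
  i <- c(seq_len(nc %/% 2), 10L + seq_len(nc - nc %/% 2))
  contacts <- data.frame(i = i, j = i + 4L)   # halves straddle the midpoint
  f <- 100 * exp(-((seq_len(nfr) - 30) / 8)^2)
  if (two_peaks) f <- f + 80 * exp(-((seq_len(nfr) - 75) / 8)^2)
  force_trace(time = seq_len(nfr) * 1.0,
              extension = seq(0.5, 6, length.out = nfr),
              force = f, contact_intact = intact, contacts = contacts,
              n_beads = n_beads)
}

test_that("running average is centered, shape-preserving, noise-reducing", {
  x <- sin(seq(0, 10, length.out = 400)) + 2
  expect_identical(running_average(x, 1L), x)
  expect_equal(running_average(rep(3.3, 100), 21L), rep(3.3, 100))
  expect_length(running_average(x, 51L), length(x))
  set.seed(1)
  z <- rnorm(20000)
  ratio <- var(running_average(z, 101L)[150:19850]) / var(z)
  expect_equal(ratio, 1 / 101, tolerance = 0.15)
  expect_error(running_average(x, 50L), "odd")
  expect_error(running_average(x[1:10], 21L), "length")
})

test_that("trace summary finds the global maximum with guards", {
  tr <- ramp_trace(ext_peak = 5, f_peak = 150)
  s <- summarize_trace(tr, smoothing_window = 1L)
  expect_equal(s$F_max, 150)
  expect_equal(s$r_NC_at_max, 5, tolerance = 1e-6)

  # two peaks: the global maximum wins
  tr2 <- ramp_trace()
  tr2$force <- 120 * exp(-((tr2$extension - 2) / 0.5)^2) +
               180 * exp(-((tr2$extension - 5) / 0.5)^2)
  s2 <- summarize_trace(tr2, smoothing_window = 1L)
  expect_equal(s2$F_max, 180, tolerance = 1e-3)
  expect_equal(s2$r_NC_at_max, 5, tolerance = 0.05)

  # smoothing can only lower the recorded maximum
  set.seed(4)
  for (k in 1:20) {
    f <- abs(rnorm(300, 100, 30))
    tr3 <- force_trace(1:300, seq(0.5, 6, length.out = 300), f)
    expect_lte(summarize_trace(tr3, 31L)$F_max,
               summarize_trace(tr3, 1L)$F_max + 1e-12)
  }

  # detachment guard: spike in the last 2% of extension is ignored
  tr4 <- ramp_trace()
  tr4$force[length(tr4$force)] <- 1e4
  expect_equal(summarize_trace(tr4, smoothing_window = 1L)$F_max, 150)

  tr5 <- force_trace(1:10, seq(1, 2, length.out = 10), rep(0, 10))
  expect_warning(s5 <- summarize_trace(tr5), "zero")
  expect_true(s5$degenerate)
  expect_equal(s5$F_max, 0)
})

test_that("mixture fit recovers generating parameters and degenerates safely", {
  set.seed(42)
  f1 <- fit_force_distribution(rnorm(2000, 121.7, 21.4))
  expect_equal(f1$n_components, 1L)
  expect_lt(abs(f1$components$mean - 121.7), 1.5)
  expect_lt(abs(f1$components$sd - 21.4), 1.5)
  expect_equal(sum(f1$components$weight), 1)

  f2 <- fit_force_distribution(c(rnorm(1000, 145.8, 15.9),
                                 rnorm(1000, 196.5, 24.8)))
  expect_equal(f2$n_components, 2L)
  expect_lt(abs(f2$components$mean[1] - 145.8), 3)
  expect_lt(abs(f2$components$mean[2] - 196.5), 3)
  expect_equal(sum(f2$components$weight), 1, tolerance = 1e-9)
  expect_named(f2$candidates, c("g1", "g2"))

  expect_warning(fd <- fit_force_distribution(rep(100, 10)), "degenerate")
  expect_equal(fd$n_components, 1L)
  expect_error(fit_force_distribution(rnorm(5)), "10")
})

test_that("curve averaging pools traces pointwise with masking", {
  tr <- ramp_trace()
  ten <- rep(list(tr), 10)
  av <- average_curves(ten)
  expect_true(all(av$sd_force_pN[av$coverage == 1] == 0))

  # common curve + independent noise: mean converges, sd estimates noise
  set.seed(9)
  noisy <- lapply(1:400, function(k) {
    t2 <- tr; t2$force <- t2$force + rnorm(length(t2$force), 0, 10); t2
  })
  grid <- tr$extension[seq(20L, 180L, by = 4L)]  # on-sample: no interpolation
  av2 <- average_curves(noisy, grid = grid)
  base <- approx(tr$extension, tr$force, xout = grid)$y
  expect_lt(max(abs(av2$mean_force_pN - base)), 2.5)       # ~ 5 SE
  expect_equal(mean(av2$sd_force_pN), 10, tolerance = 0.05)

  # no extrapolation beyond coverage
  av3 <- average_curves(ten, grid = c(2, 5, 60))
  expect_true(is.na(av3$mean_force_pN[3]))

  far <- tr; far$extension <- far$extension + 100
  expect_error(average_curves(list(tr, far)), "disjoint")
})

test_that("relative extension at the maximum spans native to contour", {
  m <- fh_model()
  r0 <- native_end_distance(m)
  expect_equal(relative_extension_at_fmax(list(r_NC_at_max = r0), m), 0)
  expect_equal(relative_extension_at_fmax(list(r_NC_at_max = contour_length(m)),
                                          m), 1)
  # fibroin-H-like peak position: a 31-bead hairpin whose maximum falls at
  # 5.51 nm sits near the middle of its unfolding path
  expect_equal(relative_extension_at_fmax(list(r_NC_at_max = 5.51), m),
               0.46, tolerance = 0.01)
})

test_that("scenario labels follow the rupture chronology", {
  # all C-half contacts break before the force peak, N-half never
  cb <- scenario_trace(order_break = c(NA, NA, NA, 20L, 22L, 24L))
  expect_equal(classify_scenario(cb)$primary, "C")
  expect_equal(classify_scenario(cb)$label, "C/0")

  # mirror image: N-half leads
  nb <- scenario_trace(order_break = c(20L, 22L, 24L, NA, NA, NA))
  expect_equal(classify_scenario(nb)$primary, "N")

  # simultaneous symmetric rupture
  ncb <- scenario_trace(order_break = c(20L, 21L, NA, 20L, 21L, NA))
  expect_equal(classify_scenario(ncb)$primary, "NC")

  # nothing ruptured by the first peak: uniform type 0
  t0 <- scenario_trace(order_break = c(90L, 91L, 92L, 93L, 94L, 95L))
  expect_equal(classify_scenario(t0)$primary, "0")

  # secondary peak: two-stage label without the /0 modifier
  two <- scenario_trace(order_break = c(70L, 72L, 74L, 20L, 22L, 24L),
                        two_peaks = TRUE)
  lab <- classify_scenario(two)
  expect_equal(lab$label, "C/NC")

  # no ruptures at all
  none <- scenario_trace(order_break = rep(NA, 6))
  expect_warning(out <- classify_scenario(none), "rupture")
  expect_equal(out$primary, "none")
})

test_that("classification is antisymmetric under chain reversal", {
  tr <- scenario_trace(order_break = c(NA, NA, NA, 18L, 20L, 26L))
  rev_tr <- tr
  n <- tr$n_beads
  rev_tr$contacts <- data.frame(i = n + 1L - tr$contacts$j,
                                j = n + 1L - tr$contacts$i)
  expect_equal(classify_scenario(tr)$primary, "C")
  expect_equal(classify_scenario(rev_tr)$primary, "N")
})
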