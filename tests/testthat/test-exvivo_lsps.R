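test_that("map normalisation sums to one and is idempotent", {
  m <- lsps_map(matrix(2, 11, 17), toy_layers())
  n1 <- normalize_map(m)
  expect_equal(sum(n1), 1)
  expect_true(all(abs(n1 - 1 / 187) < 1e-12))   # 11 x 17 = 187 pixels
  expect_equal(unclass(normalize_map(n1)), unclass(n1), tolerance = 1e-12)
  # single nonzero pixel takes all the mass
  g <- matrix(0, 11, 17); g[3, 5] <- 4.2
  n2 <- normalize_map(lsps_map(g, toy_layers()))
  expect_equal(n2[3, 5], 1)
  expect_equal(sum(n2), 1)
  expect_error(normalize_map(lsps_map(matrix(0, 11, 17))), "all-zero")
  expect_error(lsps_map(matrix(-1, 2, 2)), ">= 0")
})

test_that("columnar profiles and layer sums conserve the total exactly", {
  set.seed(4)
  g <- matrix(rexp(187), 11, 17)
  m <- lsps_map(g, toy_layers())
  prof <- columnar_profile(m)
  expect_length(prof, 11)
  expect_equal(sum(prof), sum(g))
  ls <- layer_input_sums(m)
  expect_equal(sum(ls), sum(g))
  nm <- normalize_map(m)
  expect_equal(sum(columnar_profile(nm)), 1)
  expect_equal(sum(layer_input_sums(nm)), 1)
  # planted L5b band dominates the profile at the planted rows
  g2 <- matrix(0.01, 11, 17); g2[8:9, ] <- 1
  expect_equal(which.max(columnar_profile(lsps_map(g2))), 8L)
  # uniform map split 4:7 across two layers keeps that ratio
  m47 <- lsps_map(matrix(1, 11, 17), list(upper = 0:3, lower = 4:10))
  expect_equal(unname(layer_input_sums(m47)["upper"] /
                        layer_input_sums(m47)["lower"]), 4 / 7)
  expect_error(layer_input_sums(lsps_map(matrix(1, 11, 17),
                                         list(L1 = 0:3))), "cover")
})

test_that("boundary-aligned averaging is exact on constructed maps", {
  g <- matrix(seq_len(187), 11, 17)
  m <- lsps_map(g, toy_layers())
  self <- align_and_average_maps(list(m, m))
  expect_equal(self$mean, unclass(g))
  expect_true(all(self$n == 2))
  # two identical-content maps offset by one row in their L4 boundary
  la <- toy_layers()
  lb <- list(L1 = 0:1, `L2/3` = 2:4, L4 = 5:6, L5a = 7L, L5b = 8:9,
             L6 = 10L)
  avg <- align_and_average_maps(list(lsps_map(g, la), lsps_map(g, lb)))
  expect_equal(avg$boundary_row, 7L)
  expect_equal(dim(avg$mean), c(12L, 17L))
  # overlap rows average the two contributions; edges keep single maps
  expect_equal(avg$n[1, 1], 1L)
  expect_equal(avg$mean[2, ], (g[1, ] + g[2, ]) / 2)
  expect_true(all(is.na(avg$mean[1, ]) == FALSE))
  # permutation invariance
  avg2 <- align_and_average_maps(list(lsps_map(g, lb), lsps_map(g, la)))
  expect_equal(avg$mean, avg2$mean)
  expect_error(align_and_average_maps(list(lsps_map(g))), "L4")
})

test_that("map CSV + sidecar round trips with geometry", {
  m <- lsps_map(matrix(runif(187), 11, 17), toy_layers(),
                soma_position = c(5, 8))
  p <- file.path(tempdir(), "map.csv")
  write_lsps_map(m, p)
  back <- read_lsps_map(p)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_equal(attr(back, "layer_rows")$L4, attr(m, "layer_rows")$L4)
  expect_equal(attr(back, "soma_position"), c(5, 8))
})

test_that("PSC features match forced arithmetic on a square pulse", {
  # 100 pA x 10 ms starting 5 ms post-stimulus: charge = 1 pC
  fs <- 20000
  x <- numeric(6000); stim <- 2000
  x[(stim + 100 + 1):(stim + 100 + 200)] <- 100
  f <- extract_psc_features(x, stim)
  expect_false(f$is_failure)
  expect_equal(f$onset_ms, 5, tolerance = 0.5)
  expect_equal(f$peak_amplitude_pa, 100)
  expect_equal(f$charge_pc, 1, tolerance = 0.01)
  # flat sweep is a failure
  set.seed(9)
  f0 <- extract_psc_features(rnorm(6000, 0, 2), stim)
  expect_true(f0$is_failure)
  # event outside the 0-50 ms monosynaptic window is a failure
  x2 <- numeric(6000)
  x2[(stim + 60 * 20 + 1):(stim + 60 * 20 + 200)] <- 100
  expect_true(extract_psc_features(x2, stim)$is_failure)
  expect_error(extract_psc_features(x[1:2100], stim), "outside sweep")
})

test_that("planted double-exponential PSCs are recovered", {
  for (s in 1:5) {
    sw <- psc_sweep(snr = 8, onset_ms = 3 + 4 * s, seed = s)
    f <- extract_psc_features(sw$sweep, sw$stim)
    expect_false(f$is_failure)
    expect_lt(abs(f$onset_ms - sw$true_onset_ms), 0.5)
    expect_lt(abs(f$charge_pc - sw$true_charge_pc) / sw$true_charge_pc,
              0.1)
  }
  # inward (EPSC) polarity handled by the sign convention
  sw <- psc_sweep(snr = 10, seed = 99)
  fi <- extract_psc_features(-sw$sweep, sw$stim, direction = "inward")
  expect_false(fi$is_failure)
  expect_gt(fi$peak_amplitude_pa, 0)
})

test_that("minimal-stimulation summaries count failures", {
  mk <- function(fail, amp = 40, q = 0.4)
    structure(list(is_failure = fail, onset_ms = 5,
                   peak_amplitude_pa = amp, charge_pc = q,
                   direction = "outward"), class = "psc_features")
  sweeps <- c(replicate(3, mk(TRUE), simplify = FALSE),
              replicate(3, mk(FALSE), simplify = FALSE))
  s <- minimal_input_summary(sweeps)
  expect_equal(s$failure_rate, 0.5)
  expect_equal(s$mean_amplitude_pa, 40)
  all_fail <- replicate(6, mk(TRUE), simplify = FALSE)
  s2 <- minimal_input_summary(all_fail)
  expect_equal(s2$failure_rate, 1)
  expect_true(is.na(s2$mean_amplitude_pa))
  s3 <- minimal_input_summary(c(sweeps, list(mk(FALSE))))
  expect_equal(s3$failure_rate, 3 / 7)
  expect_warning(minimal_input_summary(sweeps[1:4]), ">= 6")
})
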