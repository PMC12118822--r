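# minimal ps_curve constructor for closed-form tests
make_ps <- function(s_bp, P) {
  structure(data.frame(s_bp = s_bp, P = P),
            class = c("ps_curve", "data.frame"))
}

test_that("zero-jitter contacts are a hard distance cutoff", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 5, 0), c(1.2, 5, 0))
  conf <- smcsim:::new_conformation(pos, 200)
  ct <- simulate_contacts(conf, sigma_C_nm = 0, n_reps = 5, seed = 1)
  # beads 1-2 at distance 1.0 (< 1.1): frequency 1; 3-4 at 1.2: absent
  hit <- ct[ct$i == 1 & ct$j == 2, ]
  expect_equal(hit$freq, 1.0)
  expect_false(any(ct$i == 3 & ct$j == 4))
  expect_error(simulate_contacts(conf, 0, cutoff = 0), "cutoff")
})

test_that("jittered contact frequency matches a Monte-Carlo oracle", {
  # two beads 2.0 units apart, sigma_C = 48 nm at 10 nm beads
  conf <- smcsim:::new_conformation(rbind(c(0, 0, 0), c(2, 0, 0)), 200)
  n_reps <- 10000
  ct <- simulate_contacts(conf, sigma_C_nm = 48, n_reps = n_reps, seed = 2,
                          min_sep = 1)
  freq <- if (nrow(ct)) ct$freq[1] else 0
  # independent oracle: difference of two isotropic Gaussians
  set.seed(99)
  m <- 200000
  d <- matrix(rnorm(3 * m, 0, sqrt(2) * 4.8), ncol = 3)
  d[, 1] <- d[, 1] + 2
  p_oracle <- mean(sqrt(rowSums(d^2)) < 1.1)
  se <- sqrt(p_oracle * (1 - p_oracle) / n_reps)
  expect_lt(abs(freq - p_oracle), 3 * se + 3 * sqrt(p_oracle / m))
})

test_that("contact sampling is symmetric and deterministic", {
  conf <- generate_fixture("rw_conformation", list(n = 300), seed = 5)
  a <- simulate_contacts(conf, 20, n_reps = 10, seed = 7)
  b <- simulate_contacts(conf, 20, n_reps = 10, seed = 7)
  expect_identical(as.data.frame(a)[order(a$i, a$j), ],
                   as.data.frame(b)[order(b$i, b$j), ])
  expect_true(all(a$j > a$i))  # stored upper-triangle once
  expect_true(all(a$freq >= 0 & a$freq <= 1))
})

test_that("P(s) of uniform-frequency pairs is flat and linear in frequency", {
  n <- 80
  pairs <- do.call(rbind, lapply(1:(n - 1), function(i)
    data.frame(i = i, j = (i + 1):n, freq = 0.5)))
  ps <- ps_from_contacts(pairs, bp_per_bead = 1000, n_beads = n)
  expect_lt(diff(range(ps$P)), 1e-9)       # constant everywhere
  expect_equal(ps$P[1], 0.5, tolerance = 1e-9)
  pairs2 <- transform(pairs, freq = freq * 2)
  ps2 <- ps_from_contacts(pairs2, bp_per_bead = 1000, n_beads = n)
  expect_equal(ps2$P, 2 * ps$P, tolerance = 1e-12)  # pointwise linearity
})

test_that("a pure power law gives a constant log-derivative", {
  n <- 3000
  pairs <- do.call(rbind, lapply(seq(1, n - 1, by = 1), function(k)
    data.frame(i = 1, j = 1 + k, freq = k^(-1.5))))
  # spread over all pairs at each offset to keep the denominator honest
  ps <- ps_from_contacts(pairs, bp_per_bead = 1000, n_beads = n)
  d <- log_derivative(ps)
  sel <- d$s_bp > 1e4 & d$s_bp < 1e6 & !is.na(d$slope)
  # slope = -1.5 - 1 because the denominator (n - k) is ~constant there
  # while the numerator collects k^-1.5 over ~k-wide bins; instead use
  # mean_log_slope on an explicitly constructed flat-denominator curve
  ps_pl <- make_ps(10^seq(3.5, 7, by = 1 / 128),
                   (10^seq(3.5, 7, by = 1 / 128))^(-1.5))
  expect_lt(max(abs(log_derivative(ps_pl)$slope[-c(1, nrow(ps_pl))] + 1.5)),
            0.02)
  expect_equal(mean_log_slope(ps_pl, 1e4, 1e6), -1.5, tolerance = 1e-6)
})

test_that("an ideal helix shows a P(s) peak at one turn of beads", {
  # 60 beads per turn, 1 kb beads, tight pitch: adjacent gyres touch
  conf <- generate_fixture("helix_conformation",
                           list(n = 4000, beads_per_turn = 60, radius = 6,
                                pitch = 1.5, bp_per_bead = 1000), seed = 3)
  ps <- ps_from_conformation(conf, sigma_C_nm = 20, n_reps = 20, seed = 4)
  pk_Mb <- second_diagonal_position(ps, s_min = 3e4)
  expect_equal(pk_Mb * 1e6, 60 * 1000, tolerance = 0.15)
})

test_that("loop-size estimator finds the derivative peak", {
  # synthetic curve built from a slope profile with a local maximum at
  # 450 kb (the derivative shoulder of a dense loop array)
  ls <- seq(3, 8, by = 1 / 128)
  slope <- -1 + 0.8 * exp(-((ls - log10(4.5e5)) / 0.25)^2)
  lp <- cumsum(slope) / 128
  ps <- make_ps(10^ls, 10^lp)
  est <- loop_size_estimate(ps, calibration = 1)
  expect_gt(est, 350)
  expect_lt(est, 550)
  # the stored calibration shifts the estimate left of the peak
  expect_lt(loop_size_estimate(ps), est)
})

test_that("fit_rms satisfies its identities and closed form", {
  s <- 10^seq(3, 8, by = 1 / 128)
  x <- make_ps(s, s^(-1.2))
  expect_equal(fit_rms(x, x), 0)
  x2 <- make_ps(s, 2 * s^(-1.2))
  expect_equal(fit_rms(x, x2), 0, tolerance = 1e-12)  # scale invariance
  # shift half of the compared bins by 10^0.1 -> RMS = 0.1/sqrt(2)
  sel <- s >= 3e3 & s <= 4e7
  idx <- which(sel)
  half <- idx[idx > stats::median(idx)]
  # adjust so exactly half of the bins in range are shifted
  n_half <- floor(length(idx) / 2)
  half <- idx[(length(idx) - n_half + 1):length(idx)]
  P3 <- x$P
  P3[half] <- P3[half] * 10^0.1
  y <- make_ps(s, P3)
  expect_equal(fit_rms(x, y), 0.1 * sqrt(n_half / length(idx)),
               tolerance = 0.002)
  expect_error(fit_rms(make_ps(s[s > 1e4], s[s > 1e4]^-1), x), "3 kb")
})

test_that("increasing the contact radius smooths P(s)", {
  conf <- generate_fixture("helix_conformation",
                           list(n = 2500, beads_per_turn = 60, radius = 6,
                                pitch = 1.5, bp_per_bead = 1000), seed = 8)
  tv <- sapply(c(10, 30, 60), function(sg) {
    ps <- ps_from_conformation(conf, sigma_C_nm = sg, n_reps = 15, seed = 9)
    sum(abs(diff(log10(pmax(ps$P, 1e-12)))))
  })
  expect_true(all(diff(tv) < 0))
})
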