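test_that("phosphate counts from peak masses match the 80 Da ladder", {
  expect_equal(phosphate_count_from_peak(40.7, 39.9)$count, 10L)
  expect_equal(phosphate_count_from_peak(41.4, 39.9)$count, 19L)
  expect_equal(phosphate_count_from_peak(39.9, 39.9)$count, 0L)
  # the 40.5 kDa case is an exact half-integer: flagged as a tie
  tie <- phosphate_count_from_peak(40.5, 39.9)
  expect_true(tie$tie)
  expect_equal(tie$count, 7L)
  expect_equal(tie$exact, 7.5)
  expect_false(phosphate_count_from_peak(40.7, 39.9)$tie)
  expect_error(phosphate_count_from_peak(39.0, 39.9), "below base")
})

test_that("state weights integrate the 10 Da window around each state mass", {
  sp <- gen_spectrum(state_weights = c("10,0" = 1), peak_fwhm_da = 2)
  g <- state_grid(max_phos = 15, max_adduct = 3)
  w_target <- state_log_weight(sp, g, 10, 0)
  others <- c(state_log_weight(sp, g, 9, 0), state_log_weight(sp, g, 11, 0),
              state_log_weight(sp, g, 10, 1), state_log_weight(sp, g, 0, 0))
  expect_true(all(w_target > others))
  # zero spectrum: flat at the pseudo-area floor -> error at table level,
  # uniform weights when a floor exists
  zero <- mass_spectrum(seq(39800, 42000, 10), rep(0, 221))
  expect_error(run_assignment(zero, g), "no signal")
  # direct trapezoid oracle for overlapping windows
  m <- seq(39990, 40010, 0.1)
  y <- exp(-(m - 40000)^2 / 2)
  sp2 <- mass_spectrum(m, y, mass_range = c(39900, 40100))
  gfine <- state_grid(base_mass_da = 39998, phosphate_da = 1, adduct_da = 3,
                      max_phos = 5, max_adduct = 1, window_da = 10)
  # windows for p = 0 ([39993, 40003]) and p = 1 ([39994, 40004]) overlap
  a0 <- exp(state_log_weight(sp2, gfine, 0, 0, noise_threshold = 0))
  a1 <- exp(state_log_weight(sp2, gfine, 1, 0, noise_threshold = 0))
  trap <- function(lo, hi) {
    sel <- m >= lo & m <= hi
    xx <- m[sel]; yy <- y[sel]
    sum(diff(xx) * (yy[-1] + yy[-length(yy)]) / 2)
  }
  expect_equal(a0, trap(39993, 40003), tolerance = 1e-3)
  expect_equal(a1, trap(39994, 40004), tolerance = 1e-3)
})

test_that("MCMC marginal matches exhaustive enumeration on a 5x5 grid", {
  g5 <- state_grid(max_phos = 5, max_adduct = 5)
  sp <- gen_spectrum(state_weights = c("1,0" = 0.3, "2,1" = 0.4,
                                       "4,3" = 0.3))
  en <- enumerate_states(sp, g5)
  post <- run_assignment(sp, g5, chains = 24, steps = 3000, burn_in = 800,
                         thin = 10, seed = 5)
  expect_gte(nrow(post$samples), 5000)
  tv <- 0.5 * sum(abs(post$marginal_p$weight - rowSums(en)))
  expect_lt(tv, 0.05)
})

test_that("noise-free single-state spectra recover the exact mode", {
  g <- state_grid(max_phos = 26, max_adduct = 6)
  for (p in c(0, 7, 19, 25)) for (a in c(0, 5)) {
    sp <- gen_spectrum(state_weights = stats::setNames(1, paste0(p, ",", a)))
    post <- run_assignment(sp, g, seed = 17)
    expect_equal(post$mode_p, p)
    amode <- as.integer(names(which.max(table(post$samples$a))))
    expect_equal(amode, a)
  }
})

test_that("with adducts disabled, recovery of p is exact", {
  g1 <- state_grid(max_phos = 30, max_adduct = 1)
  for (p in c(3, 12, 24)) {
    sp <- gen_spectrum(state_weights = stats::setNames(1, paste0(p, ",0")))
    post <- run_assignment(sp, g1, seed = 21)
    expect_equal(post$mode_p, p)
    expect_equal(post$mean_p, p)
    expect_equal(post$sd_p, 0)
  }
})

test_that("an equal mixture gives a bimodal marginal over p", {
  g <- state_grid(max_phos = 26, max_adduct = 6)
  sp <- gen_spectrum(state_weights = c("5,0" = 0.5, "15,0" = 0.5))
  post <- run_assignment(sp, g, chains = 24, seed = 9)
  m <- post$marginal_p
  top2 <- sort(m$p[order(-m$weight)][1:2])
  expect_equal(top2, c(5, 15))
  expect_gt(min(m$weight[m$p %in% c(5, 15)]), 0.2)
})

test_that("the posterior is deterministic under a fixed seed", {
  sp <- gen_spectrum(state_weights = c("8,1" = 0.7, "9,1" = 0.3))
  a <- run_assignment(sp, state_grid(max_phos = 20, max_adduct = 4),
                      seed = 33)
  b <- run_assignment(sp, state_grid(max_phos = 20, max_adduct = 4),
                      seed = 33)
  expect_identical(a$samples, b$samples)
  expect_identical(a$marginal_p, b$marginal_p)
})

test_that("translating the spectrum by +80 Da shifts the mode by one", {
  g <- state_grid(max_phos = 26, max_adduct = 6)
  sp <- gen_spectrum(state_weights = c("9,2" = 1))
  shifted <- mass_spectrum(sp$mass_da + 80, sp$intensity,
                           mass_range = sp$mass_range + 80)
  m0 <- run_assignment(sp, g, seed = 13)$mode_p
  m1 <- run_assignment(shifted, g, seed = 13)$mode_p
  expect_equal(m1, m0 + 1L)
})

test_that("posterior mean tracks the simulated phosphorylation extent", {
  g <- state_grid(max_phos = 26, max_adduct = 6)
  w <- stats::dpois(0:25, 11); w <- w / sum(w)
  sw <- stats::setNames(w, paste0(0:25, ",0"))
  true_mean <- sum((0:25) * w)
  peak_height <- max(gen_spectrum(state_weights = sw)$intensity)
  sp <- gen_spectrum(state_weights = sw, noise_sd = 0.01 * peak_height,
                     seed = 3)
  post <- run_assignment(sp, g, thin = 10, seed = 4)
  expect_lt(abs(post$mean_p - true_mean), 0.5)
  s <- summarize_extent(post)
  expect_equal(s$mean_p, post$mean_p)
  expect_equal(sum(s$marginal$weight), 1)
})

test_that("extent summaries handle point and split posteriors", {
  g <- state_grid(max_phos = 26, max_adduct = 2)
  sp0 <- gen_spectrum(state_weights = c("0,0" = 1))
  s0 <- summarize_extent(run_assignment(sp0, g, seed = 2))
  expect_equal(s0$mean_p, 0)
  expect_equal(s0$sd_p, 0)
  # equal mass at p = 10 and p = 11 (adjacent states mix freely)
  sp2 <- gen_spectrum(state_weights = c("10,0" = 0.5, "11,0" = 0.5))
  s2 <- summarize_extent(run_assignment(sp2, g, chains = 24, steps = 3000,
                                        burn_in = 800, thin = 10, seed = 6))
  expect_equal(s2$mean_p, 10.5, tolerance = 0.05)
})
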