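test_that("histogramming conserves samples with deterministic edge assignment", {
  w <- new_window_series(1, 1.5, 2000, c(1.0, 1.0, 2.0))
  h <- build_histograms(list(w), 0.5)
  expect_equal(sum(h$counts), 3)
  expect_equal(sum(h$counts > 0), 2)
  # a sample exactly on an edge goes to the bin starting there (left-closed)
  w2 <- new_window_series(1, 0, 2000, c(0, 0.5))
  h2 <- build_histograms(list(w2), 0.5)
  expect_equal(as.numeric(h2$counts[1, 1:2]), c(1, 1))
  # conservation property over random inputs
  set.seed(8)
  for (rep in 1:20) {
    ws <- lapply(1:3, function(i)
      new_window_series(i, i, 500, stats::rnorm(sample(5:200, 1), mean = i)))
    bw <- stats::runif(1, 0.01, 0.3)
    expect_equal(sum(build_histograms(ws, bw)$counts),
                 sum(vapply(ws, function(w) length(w$samples), integer(1))))
  }
  expect_error(build_histograms(list(), 0.1), "no windows")
  expect_error(build_histograms(list(w), -1), "bin width")
})

test_that("WHAM reduces to the normalized histogram for a single unbiased window", {
  set.seed(2)
  w <- new_window_series(1, 0, 1e-9, stats::rnorm(2000))
  h <- build_histograms(list(w), 0.25)
  sol <- solve_wham(h, list(bias_potential(0, 1e-9)))
  occ <- colSums(h$counts) > 0
  expect_true(sol$converged)
  expect_equal(sol$unbiased_prob, h$counts[1, occ] / sum(h$counts),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sol$window_offsets, 0)
})

test_that("WHAM is invariant to window splitting, permutation and offset gauge", {
  pot <- potential_spec("double_well", barrier = 2, xi0 = 1, width = 0.3)
  wins <- make_umbrella_windows(0.3, 1.7, 8, 500)
  ws <- sample_umbrella(pot, wins, 3000, seed = 5)
  h <- build_histograms(ws, 0.05)
  sol <- solve_wham(h, wins)
  expect_true(sol$converged)
  # splitting one window's samples into two windows with the same bias is an
  # exact invariance of the estimator
  s3 <- ws[[3]]$samples
  half <- list(new_window_series(31, ws[[3]]$center, ws[[3]]$spring_k,
                                 s3[1:1500]),
               new_window_series(32, ws[[3]]$center, ws[[3]]$spring_k,
                                 s3[1501:3000]))
  hs <- build_histograms(c(ws[-3], half), 0.05)
  sol_s <- solve_wham(hs, c(wins[-3], wins[3], wins[3]))
  expect_equal(sol_s$unbiased_prob, sol$unbiased_prob, tolerance = 1e-6)
  # permutation of windows
  perm <- c(5, 1, 8, 3, 2, 7, 4, 6)
  sol_p <- solve_wham(build_histograms(ws[perm], 0.05), wins[perm])
  expect_equal(sol_p$unbiased_prob, sol$unbiased_prob, tolerance = 1e-6)
  # constant added to all initial offset guesses
  sol_g <- solve_wham(h, wins, f_init = rep(12.5, 8))
  expect_equal(sol_g$unbiased_prob, sol$unbiased_prob, tolerance = 1e-6)
  expect_equal(sol_g$window_offsets, sol$window_offsets, tolerance = 1e-6)
  # re-listing a window (its own samples included) only reweights that
  # window's noise: the solution stays the same to statistical accuracy
  hd <- build_histograms(c(ws, ws[3]), 0.05)
  sol_d <- solve_wham(hd, c(wins, wins[3]))
  expect_equal(sol_d$unbiased_prob, sol$unbiased_prob, tolerance = 0.05)
})

test_that("WHAM recovers a known double-well potential from exact samples", {
  pot <- potential_spec("double_well", barrier = 2.5, xi0 = 1, width = 0.3)
  wins <- make_umbrella_windows(0.25, 1.75, 24, 1000)
  ws <- sample_umbrella(pot, wins, 15000, seed = 13)
  # steep quartic walls + stiff springs call for fine bins: WHAM evaluates
  # the bias at bin centers, an approximation that degrades with bin width
  h <- build_histograms(ws, 0.01)
  sol <- solve_wham(h, wins)
  expect_true(sol$converged)
  kbt <- capsidhot:::KB_KCAL * 300
  g <- -kbt * log(sol$unbiased_prob)
  # histogram estimators see the Boltzmann average of U over each bin, so
  # the analytic reference is bin-averaged (closed form via quadrature)
  U <- vapply(sol$xi, function(xc) {
    -kbt * log(stats::integrate(function(x) exp(-pot$U(x) / kbt),
                                xc - 0.005, xc + 0.005)$value / 0.01)
  }, numeric(1))
  ok <- colSums(h$counts)[colSums(h$counts) > 0] >= 500
  resid <- (g - U)[ok]
  resid <- resid - mean(resid)   # match up to the arbitrary constant
  expect_lt(sqrt(mean(resid^2)), 0.1)
})

test_that("disconnected windows are reported as such", {
  w1 <- new_window_series(1, 0, 5000, stats::rnorm(200, 0, 0.02))
  w2 <- new_window_series(2, 5, 5000, stats::rnorm(200, 5, 0.02))
  h <- build_histograms(list(w1, w2), 0.05)
  expect_error(
    suppressWarnings(solve_wham(h, list(bias_potential(0, 5000),
                                        bias_potential(5, 5000)))),
    "disconnected")
})

test_that("PMF conversion applies -kT log P with a large-separation zero", {
  # uniform probability: g identically zero at any temperature
  sol <- structure(list(xi = seq(1, 3, by = 0.1),
                        unbiased_prob = rep(1 / 21, 21),
                        window_offsets = 0, converged = TRUE, iterations = 1,
                        temperature = 300), class = "wham_solution")
  pmf <- pmf_from_solution(sol)
  expect_equal(pmf$g, rep(0, 21), tolerance = 1e-12)
  pmf2 <- pmf_from_solution(sol, temperature = 600)
  expect_equal(pmf2$g, rep(0, 21), tolerance = 1e-12)
  # P proportional to exp(-U/kT) gives back U minus its plateau value
  kbt <- capsidhot:::KB_KCAL * 300
  expect_equal(kbt, 0.59616)
  xi <- seq(0.5, 5, by = 0.05)
  U <- 3 * exp(-(xi - 1)^2 / 0.1) - 4 * exp(-(xi - 1.5)^2 / 0.05)
  p <- exp(-U / kbt); p <- p / sum(p)
  solU <- structure(list(xi = xi, unbiased_prob = p, window_offsets = 0,
                         converged = TRUE, iterations = 1, temperature = 300),
                    class = "wham_solution")
  pmfU <- pmf_from_solution(solU)
  ref <- mean(U[xi >= pmfU$reference_region[1]])
  expect_equal(pmfU$g, U - ref, tolerance = 1e-9)
  # unconverged solutions are refused unless forced
  solU$converged <- FALSE
  expect_error(pmf_from_solution(solU), "converge")
  expect_s3_class(pmf_from_solution(solU, force = TRUE), "pmf_profile")
})

test_that("binding free energy is the PMF global minimum with a no-binding guard", {
  xi <- seq(0.5, 10, by = 0.05)
  g <- -144.9 * exp(-(xi - 0.9)^2 / 0.18)
  bd <- binding_dg(pmf_profile(xi, g))
  expect_equal(bd$dg, -144.9, tolerance = 1e-6)
  expect_false(bd$no_binding)
  # monotonically increasing profile: no stable complex
  flat <- binding_dg(pmf_profile(xi, seq(0, 5, length.out = length(xi))))
  expect_equal(flat$dg, 0)
  expect_true(flat$no_binding)
  # synthetic double-well: global minimum recovered within bin resolution
  g2 <- -3 * exp(-(xi - 1)^2 / 0.02) - 5 * exp(-(xi - 2)^2 / 0.02)
  bd2 <- binding_dg(pmf_profile(xi, g2))
  expect_equal(bd2$dg, -5, tolerance = 0.05)
  expect_equal(bd2$xi_min, 2, tolerance = 0.05)
})

test_that("ddG bookkeeping matches printed-table differencing semantics", {
  be <- function(dg, err = NA_real_) structure(
    list(dg = dg, dg_err = err, xi_min = 1, no_binding = FALSE,
         variant_id = "", temperature = 300), class = "binding_energy")
  # differencing printed minima: -37.4 - (-144.9) = 107.5 (tables that
  # difference before rounding may print 107.6)
  expect_equal(delta_delta_g(be(-37.4), be(-144.9))$ddg, 107.5)
  expect_equal(delta_delta_g(be(-144.1), be(-144.9))$ddg, 0.8)
  expect_equal(delta_delta_g(be(-5), be(-5))$ddg, 0)
  # errors add in quadrature
  dd <- delta_delta_g(be(-37.4, 5.3), be(-144.9, 4.9))
  expect_equal(dd$ddg_err, sqrt(5.3^2 + 4.9^2))
  # temperature mismatch is an analysis error
  wt <- be(-144.9); wt$temperature <- 310
  expect_error(delta_delta_g(be(-37.4), wt), "temperature")
})

test_that("bootstrap errors are seeded, reproducible and calibrated", {
  pot <- potential_spec("morse", depth = 3, xi0 = 1, width = 0.3)
  wins <- make_umbrella_windows(0.8, 3.0, 16, 800)
  ws <- sample_umbrella(pot, wins, 1500, seed = 3)
  b1 <- bootstrap_dg(ws, wins, n_boot = 3, seed = 99, tol = 1e-6)
  b2 <- bootstrap_dg(ws, wins, n_boot = 3, seed = 99, tol = 1e-6)
  expect_identical(b1, b2)
  expect_error(bootstrap_dg(ws, wins, n_boot = 1), "n_boot")
  # calibration: bootstrap sd within a factor of two of the true spread of
  # the binding free energy over independent regenerations of the data
  regen <- vapply(1:20, function(k) {
    wsk <- sample_umbrella(pot, wins, 1500, seed = 100 + k)
    sol <- solve_wham(build_histograms(wsk, 0.05), wins, tol = 1e-6)
    binding_dg(pmf_from_solution(sol, force = TRUE))$dg
  }, numeric(1))
  boot <- bootstrap_dg(ws, wins, n_boot = 20, seed = 7, tol = 1e-6)
  ratio <- boot$dg_err / stats::sd(regen)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  # block resampling preserves sample count and stays reproducible
  bb <- bootstrap_dg(ws, wins, n_boot = 2, seed = 5, block_len = 50, tol = 1e-5)
  expect_identical(bb, bootstrap_dg(ws, wins, n_boot = 2, seed = 5,
                                    block_len = 50, tol = 1e-5))
})

test_that("energy units convert exactly between kJ and kcal", {
  # a 2000 kJ/mol/nm^2 spring displaced 0.1 nm stores 10 kJ = 10/4.184 kcal
  b <- bias_potential(1, 2000)
  expect_equal(b$energy(1.1), 10 / 4.184, tolerance = 1e-12)
})
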