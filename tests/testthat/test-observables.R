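synthetic_pair <- function(ell = 10, A = 1, L_QC = 15) {
  g <- grid1d(-100, 100, 0.5, L_QC)
  pB_wt <- exp(-(g$x) / ell) * (g$x >= -L_QC / 2)
  list(grid = g, wt = pB_wt, mut = A * pB_wt)
}

test_that("delta_x: identical profiles, pure shift, exponential scaling", {
  s <- synthetic_pair()
  expect_equal(compute_delta_x(s$wt, s$wt, s$grid)$delta_x, 0)
  # a pure shootward shift by L_QC gives xi = 1
  shifted <- exp(-(s$grid$x - s$grid$L_QC) / 10) * (s$grid$x >= -7.5)
  d <- compute_delta_x(s$wt, shifted, s$grid)
  expect_equal(d$delta_x / s$grid$L_QC, 1, tolerance = 1e-6)
  # amplitude scaling of an exponential tail: delta_x = ell * log(A)
  for (A in c(1.5, 3)) {
    sa <- synthetic_pair(ell = 8, A = A)
    d <- compute_delta_x(sa$wt, sa$mut, sa$grid)
    # linear interpolation of an exponential on a dx = 0.5 grid
    expect_equal(d$delta_x, 8 * log(A), tolerance = 5e-3)
  }
})

test_that("delta_x flags a mutant profile that never reaches the reference", {
  s <- synthetic_pair()
  s$mut <- rep(1e-6, length(s$wt))
  expect_warning(d <- compute_delta_x(s$wt, s$mut, s$grid), "no crossing")
  expect_true(d$no_crossing)
  expect_equal(d$delta_x, -(s$grid$x_VI - s$grid$x_min))
})

test_that("observables on a degenerate identical pair", {
  spec <- default_spec("sequestration")
  p <- default_params("sequestration")
  wt <- solve_genotype(spec, p, "euler", t_final = 400)
  obs <- compute_observables(wt, wt, p, spec)
  expect_equal(obs$xi, 0)
  expect_equal(obs$R_B, 1)
  # R_W inapplicable without self-repression
  expect_false(obs$R_W_applicable)
  expect_true(is.na(obs$R_W))
})

test_that("without binding (lambda = 0) the WT and mutant coincide", {
  p <- default_params("sequestration")
  p$lambda <- 0
  pr <- run_pair(default_spec("sequestration"), p, t_final = 600)
  expect_equal(pr$obs$xi, 0, tolerance = 1e-8)
  expect_equal(pr$obs$R_B, 1, tolerance = 1e-8)
})

test_that("compatibility verdict equals the brute-force AND of range tests", {
  rg <- compatibility_ranges()
  set.seed(11)
  for (k in 1:50) {
    obs <- structure(list(
      xi = runif(1, -1, 7), R_B = runif(1, 0, 3), R_BW = runif(1, 0, 1),
      R_W = runif(1, 0, 1.2), R_W_applicable = runif(1) > 0.5,
      delta_x = NA, pB_star = NA, no_crossing = FALSE),
      class = "scn_observables")
    brute <- obs$xi >= 0.5 && obs$xi <= 5 &&
      obs$R_B >= 1 && obs$R_B <= 2 &&
      obs$R_BW >= 0.05 && obs$R_BW <= 0.5 &&
      (!obs$R_W_applicable || (obs$R_W >= 0.5 && obs$R_W <= 0.9))
    expect_identical(is_compatible(obs, rg), brute)
  }
})

test_that("scan cells match direct single-pair runs and record failures", {
  spec <- default_spec("sequestration")
  p <- default_params("sequestration")
  sc <- scan_plane(spec, p, axis1 = list(name = "lambda", lo = 0.05, hi = 1),
                   axis2 = list(name = "D_W", lo = 2, hi = 20), n = 3,
                   t_final = 300)
  expect_equal(nrow(sc), 9)
  ax <- attr(sc, "axes")
  # middle cell vs a direct run with the same parameters
  pm <- p
  pm$lambda <- ax$values1[2]
  pm$D_W <- ax$values2[2]
  direct <- run_pair(spec, pm, t_final = 300)
  row <- sc[sc$lambda == ax$values1[2] & sc$D_W == ax$values2[2], ]
  expect_equal(row$xi, direct$obs$xi)
  expect_equal(row$R_B, direct$obs$R_B)
  # a cell violating the stability bound is recorded, not fatal
  sc2 <- scan_plane(spec, p, axis1 = list(name = "lambda", lo = 0.1, hi = 1),
                    axis2 = list(name = "D_W", lo = 30, hi = 80), n = 2,
                    t_final = 10)
  expect_true(any(!sc2$compatible & nzchar(sc2$reason)))
})

test_that("expansion shrinks monotonically as binding weakens", {
  spec <- default_spec("sequestration")
  p <- default_params("sequestration")
  lam <- p$lambda * c(1, 1 / 4, 1 / 16)
  xi <- vapply(lam, function(l) {
    pl <- p; pl$lambda <- l
    run_pair(spec, pl, t_final = 600)$obs$xi
  }, numeric(1))
  expect_true(all(diff(xi) < 0))
  expect_gt(xi[1], 0)
})

test_that("e-folding distance recovers the length scale of an exponential", {
  g <- grid1d(-100, 100, 0.5, 15)
  y <- exp(-abs(g$x) / 12)
  expect_equal(efolding_distance(y, g, 10, +1), 12, tolerance = 1e-2)
  expect_equal(efolding_distance(y, g, -10, -1), 12, tolerance = 1e-2)
})

test_that("WOX5 dosage response: identity at factor 1, linear when decoupled", {
  spec <- default_spec("sequestration")
  p <- default_params("sequestration")
  p$lambda <- 0 # decoupled: the whole system is linear in gamma
  tb <- robustness_to_wox5(spec, p, gamma_factors = c(0.5, 1, 2),
                           t_final = 600)
  expect_equal(tb$pB0_fold[tb$factor == 1], 1)
  expect_equal(tb$decay_len_fold[tb$factor == 1], 1)
  expect_equal(tb$pB0_fold, tb$factor, tolerance = 1e-6)
  # decay length is unchanged by a pure amplitude rescaling
  expect_equal(tb$decay_len_fold, rep(1, 3), tolerance = 1e-3)
})
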