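test_that("decoupled WOX5 profile matches the piecewise closed form", {
  p <- model_params(lambda = 0, D_W = 10, d_W = 0.05, gamma = 1)
  spec <- model_spec("sequestration", "linear", genotype = "bravo")
  # fine grid: the first-order error of the node-sampled source indicator
  # at the QC edges scales with dx
  g <- grid1d(-600, 600, 0.01, p$L_QC)
  st <- solve_stationary_bvp(spec, p, g)
  exact <- closed_form_W(g$x, p$D_W, p$d_W, p$gamma, p$L_QC / 2, g$x_max)
  expect_lt(max_rel_dev(exact, st$W_s), 1e-3)
})

test_that("gamma = 0 gives the identically zero state on both routes", {
  p <- model_params(gamma = 0)
  spec <- model_spec("sequestration", "linear")
  bv <- solve_stationary_bvp(spec, p)
  expect_equal(max(abs(bv$W_s)), 0)
  expect_equal(max(abs(bv$B_s)), 0)
  eu <- integrate_to_steady(spec, p, t_final = 50)
  expect_equal(max(abs(eu$W_s)), 0)
})

test_that("mutant stationary WOX5 is symmetric about the QC centre", {
  p <- model_params()
  spec <- model_spec("sequestration", "linear", genotype = "bravo")
  st <- solve_stationary_bvp(spec, p)
  W <- st$W_s
  expect_lt(max(abs(W - rev(W))) / max(W), 1e-8)
})

test_that("forward-Euler route agrees with the BVP route", {
  spec <- default_spec("sequestration")
  p <- default_params("sequestration")
  eu <- integrate_to_steady(spec, p)
  bv <- solve_stationary_bvp(spec, p)
  Wb <- on_grid(bv$W_s, bv$grid$x, eu$grid$x)
  Bb <- on_grid(bv$B_s, bv$grid$x, eu$grid$x)
  expect_lt(max_rel_dev(Wb, eu$W_s), 0.01)
  expect_lt(max_rel_dev(Bb, eu$B_s), 0.01)
})

test_that("explicit-scheme stability is checked before stepping", {
  p <- model_params(D_W = 60) # dt*D/dx^2 = 0.6 > 1/2 on the dx = 1 grid
  spec <- model_spec("sequestration", "linear")
  expect_error(integrate_to_steady(spec, p, dt = 0.01, t_final = 1),
               "stability")
})

test_that("BVP route rejects an all-reaction (zero-diffusion) system", {
  p <- model_params(D_W = 0, D_Z = 0, lambda = 0)
  spec <- model_spec("repression", "hill")
  expect_error(solve_stationary_bvp(spec, p), "fixed point")
})

test_that("promoter profiles follow their defining identities", {
  spec <- default_spec("sequestration")
  p <- default_params("sequestration")
  for (gt in c("wt", "bravo")) {
    sp <- spec; sp$genotype <- gt
    st <- integrate_to_steady(sp, p, t_final = 400)
    pr <- promoter_profiles(st, sp, p)
    x <- st$grid$x
    # pW is state-independent without self-repression: gamma inside the QC
    expect_equal(pr$pW, p$gamma * qc_indicator(x, p$L_QC))
    # pB is the production function evaluated on the stationary activator
    expect_equal(pr$pB, prod_bravo(st$W_s, x, p, sp))
    expect_true(all(pr$pB >= 0))
  }
})

test_that("WT gradient is steeper shootward of the QC than rootward", {
  spec <- default_spec("sequestration")
  p <- default_params("sequestration")
  st <- integrate_to_steady(spec, p)
  g <- st$grid
  shoot <- efolding_distance(st$W_s, g, p$L_QC / 2, +1)
  root <- efolding_distance(st$W_s, g, -p$L_QC / 2, -1)
  expect_lt(shoot, root)
  # the mutant, lacking BRAVO, decays equally on both sides
  spm <- spec; spm$genotype <- "bravo"
  stm <- integrate_to_steady(spm, p)
  shoot_m <- efolding_distance(stm$W_s, g, p$L_QC / 2, +1)
  root_m <- efolding_distance(stm$W_s, g, -p$L_QC / 2, -1)
  expect_lt(abs(shoot_m - root_m), g$dx)
})

test_that("stationary tails are monotone toward the boundaries", {
  for (variant in c("sequestration", "sequestration_z", "repression",
                    "mixed")) {
    spec <- default_spec(variant)
    p <- default_params(variant)
    st <- integrate_to_steady(spec, p, t_final = 600)
    x <- st$grid$x
    for (nm in intersect(c("B_s", "W_s", "Z_s"), names(st))) {
      y <- st[[nm]]
      # B can form a shoulder just past the VI where the sequestration
      # sink (lambda*W) fades faster than its activator; its tail is
      # monotone farther out
      from <- if (nm == "B_s") 3 * p$L_QC else 3 * p$L_QC / 2
      right <- y[x > from]
      left <- y[x < -p$L_QC / 2]
      expect_true(all(diff(right) <= 1e-12), label = paste(variant, nm))
      expect_true(all(diff(left) >= -1e-12), label = paste(variant, nm))
    }
  }
})

test_that("sequestrator-S variant: confinement survives scarce S only", {
  spec <- default_spec("sequestration_S")
  p <- default_params("sequestration_S")
  # scarce competitor: expansion close to the plain sequestration model
  scarce <- run_pair(spec, p, t_final = 600)
  expect_gt(scarce$obs$delta_x, 0)
  # abundant competitor: S immobilizes WOX5 in the mutant too, and the
  # mutant expansion collapses
  p2 <- p
  p2$alpha_S <- 0.5
  abundant <- run_pair(spec, p2, t_final = 600)
  expect_lt(abundant$obs$delta_x, scarce$obs$delta_x / 2)
})

test_that("profiles CSV round-trips with metadata", {
  spec <- default_spec("sequestration")
  p <- default_params("sequestration")
  sol <- solve_genotype(spec, p, "euler", t_final = 200)
  path <- tempfile(fileext = ".csv")
  write_profiles(sol$state, sol$prof, spec, p, path)
  df <- read_profiles(path)
  expect_equal(df$W, sol$state$W_s)
  expect_equal(df$pB, sol$prof$pB)
  meta <- attr(df, "meta")
  expect_true(any(grepl("#variant sequestration", meta)))
  expect_true(any(grepl("#params-hash", meta)))
})
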