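# shared small fixtures: build once per file
mini_layout <- local({
  lay <- NULL
  function() {
    if (is.null(lay)) lay <<- generate_layout(layout_template("mini"), 1)
    lay
  }
})

zero_rate_params <- function() {
  p <- default_params_2d()
  p$alpha <- p$alpha_0 <- p$beta <- p$gamma <- 0
  p$d_B <- p$d_W <- p$d_Z <- p$lambda <- p$c <- 0
  p
}

test_that("heterogeneous Laplacian: uniform field, stencil, conservation", {
  D <- matrix(1, 11, 11)
  expect_equal(heterogeneous_laplacian(matrix(3.2, 11, 11), D),
               matrix(0, 11, 11))
  # single hot pixel on uniform D reproduces the 5-point stencil
  u <- matrix(0, 11, 11); u[6, 6] <- 1
  lap <- heterogeneous_laplacian(u, D)
  expect_equal(lap[6, 6], -4)
  expect_equal(lap[5, 6], 1)
  expect_equal(lap[6, 7], 1)
  expect_equal(sum(lap), 0)
  # any D map with a zero border conserves mass to machine precision
  set.seed(2)
  D2 <- matrix(runif(30 * 25, 0, 2), 30, 25)
  D2[c(1, 30), ] <- 0; D2[, c(1, 25)] <- 0
  D2[sample(750, 100)] <- 0 # interior obstacles too
  u2 <- matrix(runif(30 * 25), 30, 25)
  expect_lt(abs(sum(heterogeneous_laplacian(u2, D2))), 1e-11)
  expect_error(heterogeneous_laplacian(u2, -D2), "negative")
})

test_that("diffusion-only FTCS run conserves mass over 1000 steps", {
  lay <- mini_layout()
  maps <- build_field_maps(lay, zero_rate_params(), params2d(d_GFP = 0))
  f0 <- scniche:::zero_fields(nrow(lay$labels), ncol(lay$labels))
  # seed a blob inside the root for every species
  blob <- matrix(0, nrow(lay$labels), ncol(lay$labels))
  inside <- which(lay$labels > 1L, arr.ind = TRUE)
  blob[inside[100, 1], inside[100, 2]] <- 7
  for (nm in names(f0)) f0[[nm]] <- blob
  st <- ftcs_run(maps, "wt", dt = 0.1, t_end = 100, state0 = f0)
  for (nm in c("W", "Z", "W_GFP"))
    expect_equal(sum(st[[nm]]), 7, tolerance = 1e-12)
  # fields remain exactly zero outside the root
  outside <- lay$labels == lay$outside_label
  expect_equal(max(abs(st$W[outside])), 0)
  expect_equal(max(abs(st$Z[outside])), 0)
})

test_that("field maps respect the wall/outside/cell-type rules", {
  lay <- mini_layout()
  p <- default_params_2d()
  p2d <- params2d()
  maps <- build_field_maps(lay, p, p2d)
  wall <- lay$labels == 1L
  outside <- lay$labels == 0L
  # walls: no production, wall diffusivity; BRAVO immobile across walls
  expect_equal(max(maps$alpha_map[wall]), 0)
  expect_equal(max(maps$gamma_map[wall]), 0)
  expect_equal(max(maps$cell[wall]), 0)
  expect_equal(unique(maps$D$W[wall]), p2d$D_wall[["W"]])
  expect_equal(unique(maps$D$B[wall]), 0)
  # outside: everything zero
  for (m in c(maps$D, list(maps$alpha_map, maps$gamma_map, maps$cell)))
    expect_equal(max(abs(m[outside])), 0)
  # CSC cells are not BRAVO-activating; QC cells are; WOX5 only in the QC
  csc <- as.integer(names(lay$cell_types)[lay$cell_types == "CSC"])
  qc <- as.integer(names(lay$cell_types)[lay$cell_types == "QC"])
  cscpx <- matrix(lay$labels %in% csc, nrow(lay$labels))
  qcpx <- matrix(lay$labels %in% qc, nrow(lay$labels))
  expect_equal(max(maps$alpha_map[cscpx]), 0)
  expect_equal(min(maps$alpha_map[qcpx]), p$alpha)
  expect_equal(min(maps$gamma_map[qcpx]), p$gamma)
  expect_equal(max(maps$gamma_map[!qcpx]), 0)
  expect_error(params2d(D_wall = c(B = 0, W = 2, Z = 0.1)),
               "must not exceed")
  expect_error(params2d(D_wall = c(B = 0.1, W = 0.05, Z = 0.1)), "B")
})

test_that("reactions act on cell pixels only", {
  lay <- mini_layout()
  p <- default_params_2d()
  p2d <- params2d(D_cyt = c(B = 0, W = 0, Z = 0),
                  D_wall = c(B = 0, W = 0, Z = 0),
                  D_GFP_cyt = 0, D_GFP_wall = 0)
  maps <- build_field_maps(lay, p, p2d)
  st <- ftcs_run(maps, "wt", dt = 0.1, t_end = 50)
  grown <- st$W > 0
  expect_true(all(lay$labels[grown] > 1L)) # only cell pixels changed
  expect_equal(max(abs(st$W[lay$labels == 1L])), 0)
})

test_that("bravo mutant: protein absent, reporter alive, variant-invariant", {
  lay <- mini_layout()
  maps <- build_field_maps(lay, default_params_2d(), params2d())
  mut <- ftcs_run(maps, "bravo", t_end = 500)
  expect_equal(max(abs(mut$B)), 0)
  expect_gt(sum(mut$B_GFP > 0), 0)
  # the mutant reporter is blind to both lambda and c
  red <- reduced_variant_run(maps, list(c = 0), t_end = 500)
  expect_equal(red$mut$B_GFP, mut$B_GFP, tolerance = 1e-12)
  red2 <- reduced_variant_run(maps, list(lambda = 0), t_end = 500)
  expect_equal(red2$mut$B_GFP, mut$B_GFP, tolerance = 1e-12)
  expect_error(reduced_variant_run(maps, list(bogus = 1)), "override")
})

test_that("with lambda = 0 and c = 0 the WT equals the mutant reporter", {
  lay <- mini_layout()
  p <- default_params_2d()
  p$lambda <- 0; p$c <- 0
  maps <- build_field_maps(lay, p, params2d())
  wt <- ftcs_run(maps, "wt", t_end = 500)
  mut <- ftcs_run(maps, "bravo", t_end = 500)
  expect_equal(wt$B_GFP, mut$B_GFP, tolerance = 1e-10)
  expect_equal(wt$W, mut$W, tolerance = 1e-10)
})

test_that("transverse profile: sums, partition identity, uniform field", {
  lay <- mini_layout()
  f <- matrix(0, nrow(lay$labels), ncol(lay$labels))
  rootpx <- lay$labels != lay$outside_label
  f[rootpx] <- runif(sum(rootpx))
  prof <- transverse_profile(f, lay)
  expect_equal(sum(prof), sum(f[rootpx]))
  one <- matrix(0, nrow(lay$labels), ncol(lay$labels))
  idx <- which(rootpx, arr.ind = TRUE)[50, ]
  one[idx[1], idx[2]] <- 3.3
  pr1 <- transverse_profile(one, lay)
  expect_equal(sum(pr1 > 0), 1)
  expect_equal(max(pr1), 3.3)
})

test_that("a single-file layout reproduces the 1D picture qualitatively", {
  tpl <- layout_template("mini", file_roles = c("V"), file_widths = c(10),
                         L_x = 20)
  lay <- generate_layout(tpl, 1)
  maps <- build_field_maps(lay, default_params_2d(), params2d())
  wt <- ftcs_run(maps, "wt", t_end = 1500)
  w <- transverse_profile(wt$W, lay)
  pk <- which.max(w)
  # monotone tails away from the production peak
  expect_true(all(diff(w[pk:length(w)]) <= 1e-9))
  expect_true(all(diff(w[1:pk]) >= -1e-9))
  # steeper shootward (BRAVO side) far field than rootward, as in 1D
  # sequestration (the near field reflects the QC cell outline)
  up <- w[pk:min(pk + 20, length(w))] / w[pk]
  down <- rev(w[max(pk - 20, 1):pk]) / w[pk]
  expect_lt(sum(up[8:20]), sum(down[8:20]))
})
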