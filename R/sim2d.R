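#' Transport and reporter parameters of the 2D pixel-grid model
#'
#' Per-species diffusion coefficients inside cells (`cyt`) and in cell
#' walls (`wall`), plus the shared GFP reporter parameters. Wall
#' diffusivities must not exceed the cytoplasmic ones (walls gate
#' cell-to-cell transport); BRAVO and the implicit BRAVO-WOX5 complex have
#' zero wall diffusivity (they cannot move between cells). Outside the
#' root every diffusivity is zero, which makes the root border reflecting.
#'
#' @param D_cyt named vector `c(B =, W =, Z =)` of cytoplasmic diffusion
#'   coefficients (px^2/time).
#' @param D_wall named vector `c(B =, W =, Z =)` of wall diffusion
#'   coefficients; `B` must be 0.
#' @param D_GFP_cyt,D_GFP_wall GFP diffusion coefficients.
#' @param d_GFP shared GFP degradation rate (1/time).
#' @param basal_types cell types carrying basal (WOX5-independent) BRAVO
#'   production.
#' @param activating_types cell types in which WOX5(-driven Z) activates
#'   BRAVO.
#' @return An `scn_params2d` list.
#' @export
params2d <- function(D_cyt = c(B = 0.5, W = 0.5, Z = 2),
                     D_wall = c(B = 0, W = 0.1, Z = 0.8),
                     D_GFP_cyt = 0.5, D_GFP_wall = 0.05, d_GFP = 0.1,
                     basal_types = "VI",
                     activating_types = c("QC", "VI", "V", "CX", "END")) {
  need <- c("B", "W", "Z")
  stopifnot(all(need %in% names(D_cyt)), all(need %in% names(D_wall)))
  if (any(D_wall[need] > D_cyt[need]))
    stop("wall diffusivity must not exceed cytoplasmic diffusivity")
  if (D_wall[["B"]] != 0)
    stop("BRAVO cannot diffuse through cell walls: D_wall['B'] must be 0")
  if (D_GFP_wall > D_GFP_cyt)
    stop("wall diffusivity must not exceed cytoplasmic diffusivity (GFP)")
  structure(list(D_cyt = D_cyt[need], D_wall = D_wall[need],
                 D_GFP_cyt = D_GFP_cyt, D_GFP_wall = D_GFP_wall,
                 d_GFP = d_GFP, basal_types = basal_types,
                 activating_types = activating_types),
            class = "scn_params2d")
}

#' Default kinetic parameters of the 2D mixed model
#'
#' The 2D runs use the saturating (Hill) production functions with WOX5
#' self-repression. Compared to the 1D defaults, WOX5 turnover is faster
#' and its wall mobility low (WOX5 barely leaves the niche), the
#' intermediary Z is long-lived and wall-mobile (it carries the activation
#' signal outward), and both the sequestration (`lambda`) and repression
#' (`c`) arms are active so that the wild type confines the BRAVO reporter
#' while the mutant expands it by more than one cell row.
#'
#' @return An `scn_params` object.
#' @export
default_params_2d <- function() {
  model_params(alpha = 0.5, k_B = 0.2, n = 2, beta = 1, k_Z = 0.5,
               gamma = 1, k_W = 2, h = 1, d_B = 0.1, d_W = 0.1,
               d_Z = 0.02, alpha_0 = 0.01, lambda = 1, c = 10)
}

#' Per-pixel field maps for the 2D simulator
#'
#' Expands a typed root layout into the per-pixel maps the FTCS engine
#' consumes: one diffusion map per species (cytoplasmic value on cell
#' pixels, wall value on wall pixels, zero outside), the production-rate
#' maps (WOX5 production `gamma` on QC pixels only; BRAVO activation
#' `alpha` on pixels of the activating cell types; basal BRAVO `alpha_0`
#' on the template-designated basal cells) and the reaction-enable mask
#' (cell pixels only: inside walls only diffusion can happen).
#'
#' @param layout a typed `scn_layout`.
#' @param p an [model_params()] (2D production uses the Hill-saturated
#'   rates `alpha`, `beta`, `gamma` and, for basal cells, `alpha_0`).
#' @param p2d an [params2d()].
#' @return An `scn_maps2d` list of matrices.
#' @export
build_field_maps <- function(layout, p, p2d = params2d()) {
  stopifnot(inherits(layout, "scn_layout"))
  if (is.null(layout$cell_types))
    stop("layout has no cell types; run assign_cell_types() first")
  lab <- layout$labels
  cellpx <- lab > layout$wall_label
  wallpx <- lab == layout$wall_label
  type_of <- layout$cell_types
  if (!any(type_of == "QC")) stop("layout has no QC cells")
  px_of_types <- function(types) {
    labs <- as.integer(names(type_of)[type_of %in% types])
    cellpx & matrix(lab %in% labs, nrow(lab))
  }
  dmap <- function(cyt, wall) {
    m <- matrix(0, nrow(lab), ncol(lab))
    m[cellpx] <- cyt
    m[wallpx] <- wall
    m
  }
  rate_map <- function(rate, mask) {
    m <- matrix(0, nrow(lab), ncol(lab))
    m[mask] <- rate
    m
  }
  structure(list(
    D = list(B = dmap(p2d$D_cyt[["B"]], p2d$D_wall[["B"]]),
             W = dmap(p2d$D_cyt[["W"]], p2d$D_wall[["W"]]),
             Z = dmap(p2d$D_cyt[["Z"]], p2d$D_wall[["Z"]]),
             GFP = dmap(p2d$D_GFP_cyt, p2d$D_GFP_wall)),
    alpha_map = rate_map(p$alpha, px_of_types(p2d$activating_types)),
    alpha0_map = rate_map(p$alpha_0, px_of_types(p2d$basal_types)),
    gamma_map = rate_map(p$gamma, px_of_types("QC")),
    cell = matrix(as.numeric(cellpx), nrow(lab)),
    layout = layout, p = p, p2d = p2d), class = "scn_maps2d")
}

#' Heterogeneous-diffusion operator
#'
#' Conservative (flux-form) discretization of `div(D grad u)` on the pixel
#' grid. The face diffusivity between neighbouring pixels is the
#' arithmetic mean of the two pixel values, and a face with zero
#' diffusivity on either side carries no flux, so zero-D regions act as
#' reflecting boundaries: total mass is conserved exactly under pure
#' diffusion.
#'
#' @param field,Dmap numeric matrices of the same shape; `Dmap >= 0`.
#' @param dx,dy pixel spacings.
#' @return Matrix of the same shape.
#' @export
heterogeneous_laplacian <- function(field, Dmap, dx = 1, dy = 1) {
  if (any(Dmap < 0)) stop("negative diffusivity in Dmap")
  .het_laplacian_cpp(field, Dmap, dx, dy)
}

zero_fields <- function(nr, nc) {
  z <- matrix(0, nr, nc)
  list(B = z, W = z, Z = z, B_GFP = z, W_GFP = z, Z_GFP = z)
}

#' FTCS run of the 2D mixed model with GFP reporters
#'
#' Explicit forward-time central-space integration of the mixed model
#' (BRAVO activation by the WOX5-driven intermediary Z, BRAVO-WOX5
#' sequestration with strength `lambda`, repression of Z by BRAVO with
#' strength `c`, WOX5 self-repression) together with the three GFP
#' reporters, which share one diffusion coefficient and one degradation
#' rate and inherit the production term of their cognate species.
#' Reactions act on cell pixels only; every species diffuses according to
#' its own per-pixel map. Defaults: `dt = 0.1`, `t_end = 3000`, all-zero
#' initial conditions. For `genotype = "bravo"` the BRAVO protein field is
#' held at zero while its GFP reporter still evolves.
#'
#' @param maps an [build_field_maps()] result.
#' @param genotype `"wt"` or `"bravo"`.
#' @param dt time step; checked against the 2D stability bound
#'   `max(D) * dt * (1/dx^2 + 1/dy^2) <= 1/2` for every species.
#' @param t_end final time.
#' @param state0 optional initial `State2D` fields (named list of
#'   matrices); defaults to all-zero.
#' @param wox5_self_repression logical.
#' @return An `scn_state2d`: list of final fields `B`, `W`, `Z`, `B_GFP`,
#'   `W_GFP`, `Z_GFP`, plus `t`, `genotype`, and the maps used.
#' @export
ftcs_run <- function(maps, genotype = c("wt", "bravo"), dt = 0.1,
                     t_end = 3000, state0 = NULL,
                     wox5_self_repression = TRUE) {
  stopifnot(inherits(maps, "scn_maps2d"), dt > 0, t_end > 0)
  genotype <- match.arg(genotype)
  p <- maps$p
  Dmax <- max(vapply(maps$D, max, numeric(1)))
  if (Dmax * dt * 2 > 0.5)
    stop(sprintf("FTCS stability violated: max(D)*dt*(1/dx^2+1/dy^2) = %.3g > 1/2",
                 Dmax * dt * 2))
  nr <- nrow(maps$cell); nc <- ncol(maps$cell)
  if (is.null(state0)) state0 <- zero_fields(nr, nc)
  pars <- list(k_B = p$k_B, n = p$n, beta = p$beta, k_Z = p$k_Z, c = p$c,
               k_W = p$k_W, h = p$h, lambda = p$lambda, d_B = p$d_B,
               d_W = p$d_W, d_Z = p$d_Z, d_GFP = maps$p2d$d_GFP,
               self_rep = isTRUE(wox5_self_repression),
               mutant = genotype == "bravo", has_z = TRUE)
  nsteps <- as.integer(ceiling(t_end / dt))
  fields <- .ftcs2d_cpp(state0, maps$D, maps$alpha_map, maps$alpha0_map,
                        maps$gamma_map, maps$cell, pars, 1, 1, dt, nsteps)
  structure(c(fields, list(t = nsteps * dt, genotype = genotype,
                           maps = maps)),
            class = "scn_state2d")
}

#' Transverse (axial) profile of a 2D field
#'
#' Sum of the field over the transverse direction for each row along the
#' root axis (root pixels only; the field is zero outside the root, so
#' this is the plain row sum). This is the quantity plotted for
#' transversally integrated GFP reporters.
#'
#' @param field matrix on the layout lattice.
#' @param layout the `scn_layout` (for the lattice check).
#' @return Numeric vector of length `nrow(field)`.
#' @export
transverse_profile <- function(field, layout) {
  stopifnot(all(dim(field) == dim(layout$labels)))
  rowSums(field * (layout$labels != layout$outside_label))
}

#' Mass fraction of a field within a cell-type region
#'
#' Fraction of the field's total mass lying in the pixels of the given
#' cell types plus the wall pixels adjacent to them (the 2-pixel wall ring
#' shared by those cells; walls carry no degradation, so they equilibrate
#' with the adjacent cell interiors and belong to the region spatially).
#' Used to check that, absent regulation, WOX5 stays localized to the
#' stem-cell niche (quiescent centre, vascular initials, columella stem
#' cells).
#'
#' @param field matrix on the layout lattice.
#' @param layout a typed `scn_layout`.
#' @param types cell types defining the region.
#' @return Fraction in `[0, 1]`.
#' @export
region_mass_fraction <- function(field, layout,
                                 types = c("QC", "VI", "CSC")) {
  stopifnot(!is.null(layout$cell_types))
  ids <- as.integer(names(layout$cell_types)[layout$cell_types %in% types])
  m <- matrix(layout$labels %in% ids, nrow(layout$labels))
  md <- m
  for (dr in -2:2) for (dc in -2:2) md <- md | shift_mat(m, dr, dc)
  md <- md & (layout$labels != layout$outside_label)
  sum(field[md]) / sum(field)
}

#' Single-parameter reductions of the mixed 2D model
#'
#' Reruns [ftcs_run()] for a wild-type/mutant pair under the stated
#' overrides: `c = 0` removes the repression of Z by BRAVO, `lambda = 0`
#' removes BRAVO-WOX5 sequestration, `D_Z_wall = 0` makes the intermediary
#' Z cell-autonomous. Mutant runs are unaffected by `c` and `lambda`
#' (BRAVO is absent), so their reporter fields are identical across the
#' mixed, `c = 0` and `lambda = 0` variants.
#'
#' @param maps an [build_field_maps()] result.
#' @param overrides named list among `c`, `lambda`, `D_Z_wall`.
#' @param ... forwarded to [ftcs_run()] (`dt`, `t_end`, ...).
#' @return List with `wt` and `mut` (`scn_state2d`).
#' @export
reduced_variant_run <- function(maps, overrides = list(), ...) {
  stopifnot(inherits(maps, "scn_maps2d"))
  bad <- setdiff(names(overrides), c("c", "lambda", "D_Z_wall"))
  if (length(bad)) stop("unsupported override: ", paste(bad, collapse = ", "))
  p <- maps$p
  p2d <- maps$p2d
  if (!is.null(overrides$c)) p$c <- overrides$c
  if (!is.null(overrides$lambda)) p$lambda <- overrides$lambda
  if (!is.null(overrides$D_Z_wall)) p2d$D_wall[["Z"]] <- overrides$D_Z_wall
  maps2 <- build_field_maps(maps$layout, p, p2d)
  list(wt = ftcs_run(maps2, "wt", ...), mut = ftcs_run(maps2, "bravo", ...))
}
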