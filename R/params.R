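#' Kinetic, regulatory and transport parameters of the 1D models
#'
#' Collects every rate constant used by the one-dimensional model variants.
#' All quantities are in arbitrary units (a.u.) of concentration, length and
#' time, matching the dimensionless framework in which the models are posed.
#' Parameters not used by a given variant/production mode are simply ignored
#' by the right-hand sides (they are never silently combined).
#'
#' @param alpha_L linear BRAVO production rate per unit activator (1/time).
#' @param alpha saturated BRAVO production rate (conc/time), Hill mode.
#' @param k_B half-saturation concentration for BRAVO activation.
#' @param n Hill cooperativity exponent (>= 1).
#' @param gamma WOX5 production rate in the quiescent centre (conc/time).
#' @param k_W WOX5 concentration at which self-repressed production is
#'   `gamma/2`.
#' @param h WOX5 self-repression exponent (>= 1).
#' @param beta_L linear Z production rate per unit WOX5 (1/time).
#' @param beta saturated Z production rate (conc/time), Hill mode.
#' @param k_Z half-saturation concentration for Z activation by WOX5.
#' @param c repression strength of BRAVO on Z (1/conc); `c = 0` disables
#'   the repression exactly.
#' @param alpha_0 basal (WOX5-independent) BRAVO production rate in the
#'   vascular-initials region (conc/time).
#' @param d_B,d_W,d_Z linear degradation rates (1/time).
#' @param lambda effective BRAVO-WOX5 sequestration rate per unit of each
#'   concentration (1/(conc*time)). Lumps the binding, unbinding and complex
#'   degradation rates of the explicit-complex description.
#' @param D_W,D_Z diffusion coefficients (length^2/time).
#' @param L_QC length of the quiescent-centre region (default 15 a.u.).
#' @param alpha_S,d_S,lambda_S,D_S production, degradation, WOX5-binding and
#'   diffusion rates of the additional competing sequestrator S.
#' @return An object of class `scn_params` (a validated named list).
#' @seealso [model_spec()], [default_params()]
#' @export
model_params <- function(alpha_L = 0.1, alpha = 0.5, k_B = 0.2, n = 2,
                         gamma = 1, k_W = 2, h = 1,
                         beta_L = 0.3, beta = 1, k_Z = 0.5,
                         c = 1, alpha_0 = 0.01,
                         d_B = 0.1, d_W = 0.05, d_Z = 0.05,
                         lambda = 0.2, D_W = 10, D_Z = 4, L_QC = 15,
                         alpha_S = 0.01, d_S = 0.1, lambda_S = 0.2,
                         D_S = 10) {
  p <- list(alpha_L = alpha_L, alpha = alpha, k_B = k_B, n = n,
            gamma = gamma, k_W = k_W, h = h,
            beta_L = beta_L, beta = beta, k_Z = k_Z,
            c = c, alpha_0 = alpha_0,
            d_B = d_B, d_W = d_W, d_Z = d_Z,
            lambda = lambda, D_W = D_W, D_Z = D_Z, L_QC = L_QC,
            alpha_S = alpha_S, d_S = d_S, lambda_S = lambda_S, D_S = D_S)
  validate_params(p)
  structure(p, class = "scn_params")
}

validate_params <- function(p) {
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1 && !is.na(v),
                logical(1))
  if (!all(num))
    stop("non-numeric or missing parameter: ",
         paste(names(p)[!num], collapse = ", "))
  neg <- vapply(p, function(v) v < 0, logical(1))
  if (any(neg))
    stop("negative parameter value: ", paste(names(p)[neg], collapse = ", "))
  if (p$n < 1) stop("Hill exponent n must be >= 1")
  if (p$h < 1) stop("self-repression exponent h must be >= 1")
  if (p$L_QC <= 0) stop("L_QC must be positive")
  invisible(p)
}

#' Explicit BRAVO-WOX5 complex parameters
#'
#' Rates of the full model in which the complex is an explicit dynamical
#' variable. Its stationary solutions coincide with those of the minimal
#' (lumped) description with effective sequestration rate
#' `lambda_eff = k_on * d_C / (k_off + d_C)`.
#'
#' @param k_on complex association rate (1/(conc*time)).
#' @param k_off complex dissociation rate (1/time).
#' @param d_C complex degradation rate (1/time).
#' @return An object of class `scn_full_params`.
#' @export
full_model_params <- function(k_on = 1, k_off = 0.1, d_C = 0.1) {
  stopifnot(k_on >= 0, k_off >= 0, d_C >= 0)
  structure(list(k_on = k_on, k_off = k_off, d_C = d_C),
            class = "scn_full_params")
}

#' Effective sequestration rate of the explicit-complex model
#'
#' `lambda_eff = k_on * d_C / (k_off + d_C)`: the rate at which a bound
#' BRAVO-WOX5 pair is permanently removed. An irreversible complex
#' (`k_off = 0`) gives `lambda_eff = k_on`; a reversible, non-degrading
#' complex (`d_C = 0`) gives `lambda_eff = 0` and confers no confinement.
#'
#' @param fp an [full_model_params()] object.
#' @return The effective rate (1/(conc*time)).
#' @export
lambda_eff <- function(fp) {
  stopifnot(inherits(fp, "scn_full_params"))
  if (fp$k_off + fp$d_C == 0) return(0)
  fp$k_on * fp$d_C / (fp$k_off + fp$d_C)
}

.variants <- c("sequestration", "sequestration_z", "repression", "mixed",
               "sequestration_S", "full_complex")

variant_code <- function(variant) match(variant, .variants)

#' Model variant and run-mode selection
#'
#' @param variant one of `"sequestration"` (WOX5 activates BRAVO directly
#'   and is sequestered by it), `"sequestration_z"` (activation through a
#'   diffusible intermediary Z), `"repression"` (BRAVO represses the
#'   production of its mobile activator Z; no sequestration),
#'   `"mixed"` (both sequestration and repression), `"sequestration_S"`
#'   (sequestration with a competing sequestrator S) or `"full_complex"`
#'   (sequestration with the complex as an explicit variable).
#' @param production_mode `"linear"` or `"hill"` regulatory functions.
#'   Exactly one mode applies per run.
#' @param wox5_self_repression logical; include WOX5 negative feedback on
#'   its own production.
#' @param basal_vi_production logical; add a WOX5-independent basal BRAVO
#'   production term in the vascular-initials region.
#' @param genotype `"wt"` or `"bravo"`. The `bravo` loss-of-function mutant
#'   is modelled by the same equations with the BRAVO protein forced to
#'   `B(x, t) = 0` for all positions and times; the BRAVO promoter activity
#'   is still reported from the mutant's stationary activator profile.
#' @return An object of class `scn_spec`.
#' @export
model_spec <- function(variant = "sequestration",
                       production_mode = c("linear", "hill"),
                       wox5_self_repression = FALSE,
                       basal_vi_production = FALSE,
                       genotype = c("wt", "bravo")) {
  variant <- match.arg(variant, .variants)
  production_mode <- match.arg(production_mode)
  genotype <- match.arg(genotype)
  stopifnot(is.logical(wox5_self_repression), is.logical(basal_vi_production))
  structure(list(variant = variant, production_mode = production_mode,
                 wox5_self_repression = wox5_self_repression,
                 basal_vi_production = basal_vi_production,
                 genotype = genotype),
            class = "scn_spec")
}

spec_has_z <- function(spec)
  spec$variant %in% c("sequestration_z", "repression", "mixed")

spec_lambda <- function(spec, p) {
  # the repression variant has no BRAVO-WOX5 binding term
  if (spec$variant == "repression") 0 else p$lambda
}

#' Uniform 1D grid
#'
#' Node positions cover `[x_min, x_max]` with constant step `dx`. The QC
#' occupies `[-L_QC/2, L_QC/2]` and the vascular-initials (VI) region, of
#' the same length, ends at `x_VI = 3 L_QC / 2`.
#'
#' @param x_min,x_max domain bounds (a.u. length).
#' @param dx spatial step; `(x_max - x_min) / dx` must be integral.
#' @param L_QC QC length used to locate the QC, VI and `x_VI` markers.
#' @return An object of class `scn_grid1d` with fields `x`, `dx`, `x_VI`.
#' @export
grid1d <- function(x_min = -600, x_max = 600, dx = 0.05, L_QC = 15) {
  stopifnot(x_min < x_max, dx > 0, L_QC > 0)
  nsteps <- (x_max - x_min) / dx
  if (abs(nsteps - round(nsteps)) > 1e-8)
    stop("(x_max - x_min) / dx must be an integer")
  x_VI <- 3 * L_QC / 2
  if (!(x_min < -L_QC / 2 && x_VI < x_max))
    stop("domain must contain the QC and VI regions")
  x <- x_min + dx * seq(0, round(nsteps))
  structure(list(x = x, dx = dx, x_min = x_min, x_max = x_max,
                 L_QC = L_QC, x_VI = x_VI),
            class = "scn_grid1d")
}

#' Default grids of the two solver routes
#'
#' The boundary-value route uses a fine grid (`dx = 0.05` on
#' `[-600, 600]`); the forward-Euler route a coarser one (`dx = 1` on
#' `[-400, 400]`). Cross-comparisons are done on the coarse grid.
#'
#' @param L_QC QC length.
#' @return A `scn_grid1d`.
#' @export
bvp_grid <- function(L_QC = 15) grid1d(-600, 600, 0.05, L_QC)

#' @rdname bvp_grid
#' @export
euler_grid <- function(L_QC = 15) grid1d(-400, 400, 1, L_QC)

#' Shipped default parameters and specification per model variant
#'
#' `default_params()` returns a parameter set for which the given variant,
#' in the stated production mode, produces wild-type/mutant behaviour
#' inside the experimental compatibility ranges (see
#' [compatibility_ranges()]). `default_spec()` returns the canonical
#' specification each variant is studied under: direct sequestration with
#' linear activation; the intermediary-Z and mixed variants with saturating
#' (Hill) regulation and WOX5 self-repression; the repression variant with
#' saturating regulation and immobile WOX5 (`D_W = 0`).
#'
#' @param variant model variant name.
#' @param production_mode `"linear"` or `"hill"`.
#' @return An `scn_params` / `scn_spec` object.
#' @export
default_params <- function(variant = "sequestration",
                           production_mode = c("linear", "hill")) {
  variant <- match.arg(variant, .variants)
  production_mode <- match.arg(production_mode)
  p <- model_params()
  if (variant == "sequestration_z") {
    p$alpha <- 0.15
    p$D_W <- 4
  } else if (variant == "repression") {
    # self-confinement without WOX5 mobility: Z carries the signal
    p$D_W <- 0
    p$d_W <- 0.1
    p$k_Z <- 1
  } else if (variant == "mixed") {
    p$alpha <- 0.18
    p$D_W <- 4
  }
  p
}

#' @rdname default_params
#' @export
default_spec <- function(variant = "sequestration") {
  variant <- match.arg(variant, .variants)
  switch(variant,
    sequestration = model_spec(variant, "linear"),
    sequestration_z = model_spec(variant, "hill",
                                 wox5_self_repression = TRUE),
    repression = model_spec(variant, "hill"),
    mixed = model_spec(variant, "hill", wox5_self_repression = TRUE),
    sequestration_S = model_spec(variant, "linear"),
    full_complex = model_spec(variant, "linear"))
}
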