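#' Spatial production masks
#'
#' `qc_indicator()` is 1 on the quiescent-centre region
#' `-L_QC/2 <= x <= L_QC/2` (both boundaries inclusive) and 0 elsewhere;
#' WOX5 production is restricted to it. `activation_mask()` is the
#' Heaviside factor `Theta(x + L_QC/2)`: BRAVO activation is only possible
#' from the QC towards the vasculature (shootward), i.e. at
#' `x >= -L_QC/2`, never on the columella side. `vi_indicator()` marks the
#' vascular-initials region `L_QC/2 < x <= x_VI` where basal BRAVO
#' production (when enabled) acts.
#'
#' @param x position(s), a.u. May be a vector.
#' @param L_QC QC length (> 0).
#' @return 0/1 numeric vector of the same length as `x`.
#' @export
qc_indicator <- function(x, L_QC) {
  stopifnot(L_QC > 0)
  as.numeric(x >= -L_QC / 2 & x <= L_QC / 2)
}

#' @rdname qc_indicator
#' @export
activation_mask <- function(x, L_QC) {
  stopifnot(L_QC > 0)
  as.numeric(x >= -L_QC / 2)
}

#' @rdname qc_indicator
#' @export
vi_indicator <- function(x, L_QC) {
  stopifnot(L_QC > 0)
  as.numeric(x > L_QC / 2 & x <= 3 * L_QC / 2)
}

#' BRAVO production rate
#'
#' Linear mode: `alpha_L * activator * Theta(x + L_QC/2)`. Hill mode:
#' `alpha * activator^n / (k_B^n + activator^n) * Theta(x + L_QC/2)`.
#' The activator is WOX5 in the direct-sequestration variants and the
#' intermediary Z otherwise. With basal VI production enabled, `alpha_0`
#' is added on the VI region only.
#'
#' @param activator activator concentration(s) (>= 0).
#' @param x position(s).
#' @param p an [model_params()] object.
#' @param spec an [model_spec()] object.
#' @return Production rate(s), conc/time.
#' @export
prod_bravo <- function(activator, x, p, spec) {
  if (any(activator < 0)) stop("negative activator concentration")
  theta <- activation_mask(x, p$L_QC)
  r <- if (spec$production_mode == "hill") {
    p$alpha * hill_up(activator, p$k_B, p$n) * theta
  } else {
    p$alpha_L * activator * theta
  }
  if (isTRUE(spec$basal_vi_production)) r <- r + p$alpha_0 * vi_indicator(x, p$L_QC)
  r
}

#' WOX5 production rate
#'
#' Constant rate `gamma` inside the QC; zero outside. With self-repression,
#' `gamma / (1 + (W/k_W)^h)` inside the QC, so production is `gamma/2` at
#' `W = k_W` for any exponent `h`.
#'
#' @param W WOX5 concentration(s) (>= 0).
#' @inheritParams prod_bravo
#' @return Production rate(s), conc/time.
#' @export
prod_wox5 <- function(W, x, p, spec) {
  if (any(W < 0)) stop("negative WOX5 concentration")
  r <- p$gamma * qc_indicator(x, p$L_QC)
  if (isTRUE(spec$wox5_self_repression)) {
    if (p$k_W <= 0) stop("k_W must be positive when WOX5 self-represses")
    r <- r / (1 + (W / p$k_W)^p$h)
  }
  r
}

#' Z production rate
#'
#' WOX5-driven activation (`beta_L * W` linear, or a Hill function with
#' half-point `k_Z` in hill mode), multiplied in the repression and mixed
#' variants by the BRAVO repression factor `1 / (1 + c * B)`. Setting
#' `c = 0` disables the repression exactly.
#'
#' @param W,B WOX5 and BRAVO concentration(s) (>= 0).
#' @inheritParams prod_bravo
#' @return Production rate(s), conc/time.
#' @export
prod_z <- function(W, B, p, spec) {
  if (any(W < 0) || any(B < 0)) stop("negative concentration")
  r <- if (spec$production_mode == "hill") {
    p$beta * hill_up(W, p$k_Z, p$n)
  } else {
    p$beta_L * W
  }
  if (spec$variant %in% c("repression", "mixed")) r <- r / (1 + p$c * B)
  r
}

hill_up <- function(u, k, n) {
  un <- ifelse(u > 0, u^n, 0)
  un / (k^n + un)
}

#' Reaction terms of the 1D model variants
#'
#' Evaluates the reaction part (production, degradation, sequestration) of
#' the chosen variant at the given state; diffusion is excluded and handled
#' by the solvers. The state is a named list of concentration vectors over
#' positions `x`; species not present in the variant are ignored. For the
#' `bravo` mutant genotype the equations are evaluated with `B == 0` and no
#' `dB` component is returned.
#'
#' @param state named list with components among `B`, `W`, `Z`, `S`
#'   (nonnegative numeric vectors, same length as `x`).
#' @param x positions.
#' @inheritParams prod_bravo
#' @return Named list of time derivatives (`dB`, `dW`, and `dZ`/`dS` when
#'   the variant includes them).
#' @export
model_rhs <- function(state, x, p, spec) {
  if (!spec$variant %in% .variants) stop("unknown model variant")
  if (spec$variant == "full_complex")
    stop("use full_complex_rhs() for the explicit-complex model")
  mutant <- spec$genotype == "bravo"
  lam <- spec_lambda(spec, p)
  W <- state$W
  B <- if (mutant) rep(0, length(W)) else state$B
  if (any(W < 0) || any(B < 0)) stop("negative concentration in state")
  has_z <- spec_has_z(spec)

  activator <- if (has_z) state$Z else W
  PB <- prod_bravo(activator, x, p, spec)
  PW <- prod_wox5(W, x, p, spec)
  seq_loss <- lam * B * W

  out <- list()
  if (!mutant) out$dB <- PB - p$d_B * B - seq_loss
  dW <- PW - p$d_W * W - seq_loss
  if (has_z) {
    Z <- state$Z
    if (any(Z < 0)) stop("negative concentration in state")
    out$dZ <- prod_z(W, B, p, spec) - p$d_Z * Z
  }
  if (spec$variant == "sequestration_S") {
    S <- state$S
    if (any(S < 0)) stop("negative concentration in state")
    dW <- dW - p$lambda_S * S * W
    out$dS <- p$alpha_S - p$d_S * S - p$lambda_S * S * W
  }
  out$dW <- dW
  out[intersect(c("dB", "dW", "dZ", "dS"), names(out))]
}

#' Reaction terms of the explicit-complex (full) model
#'
#' Mass-action complex dynamics: `dC = k_on*B*W - (k_off + d_C)*C`, with the
#' matching `-k_on*B*W + k_off*C` exchange terms on B and W. Its stationary
#' solutions equal those of the minimal sequestration model with
#' `lambda = lambda_eff(fp)`.
#'
#' @param state named list with components `B`, `W`, `C`.
#' @param x positions.
#' @param p an [model_params()] object.
#' @param fp an [full_model_params()] object.
#' @param spec an [model_spec()] object (`variant = "full_complex"`).
#' @return Named list with `dB`, `dW`, `dC` (no `dB`/`dC` for the mutant).
#' @export
full_complex_rhs <- function(state, x, p, fp, spec) {
  mutant <- spec$genotype == "bravo"
  W <- state$W
  B <- if (mutant) rep(0, length(W)) else state$B
  C <- if (mutant) rep(0, length(W)) else state$C
  if (any(W < 0) || any(B < 0) || any(C < 0))
    stop("negative concentration in state")
  PB <- prod_bravo(W, x, p, spec)
  PW <- prod_wox5(W, x, p, spec)
  bind <- fp$k_on * B * W
  out <- list()
  if (!mutant) {
    out$dB <- PB - p$d_B * B - bind + fp$k_off * C
    out$dC <- bind - (fp$k_off + fp$d_C) * C
  }
  out$dW <- PW - p$d_W * W - bind + fp$k_off * C
  out[intersect(c("dB", "dW", "dC"), names(out))]
}
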