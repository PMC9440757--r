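# Closed-form stationary solution of the linear source-diffusion-decay
# problem D W'' - d W + g * 1[|x| <= a] = 0 with W(-X) = W(X) = 0,
# assembled piecewise (interior: plateau + cosh; exterior: sinh decay to
# the boundary). Independent oracle for the decoupled (lambda = 0) WOX5
# equation.
closed_form_W <- function(x, D, d, g, a, X) {
  l <- sqrt(D / d)
  u <- (X - a) / l
  v <- a / l
  A <- (g / d) / (sinh(u) + cosh(u) / tanh(v))
  B <- -A * cosh(u) / sinh(v)
  ifelse(abs(x) <= a,
         g / d + B * cosh(x / l),
         A * sinh(pmax(X - abs(x), 0) / l))
}

# normalized maximum deviation between two profiles on a common grid
max_rel_dev <- function(a, b) max(abs(a - b)) / max(abs(a))

# interpolate a fine-grid state onto a coarse grid
on_grid <- function(y, from_x, to_x) approx(from_x, y, xout = to_x)$y

# random nonnegative state for property tests
random_state <- function(n, species) {
  setNames(lapply(species, function(s) runif(n, 0, 5)), species)
}
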