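#' Experimental compatibility ranges for the observables
#'
#' Inclusive ranges within which a simulated wild-type/mutant pair is
#' considered compatible with the reported root phenotypes: a mutant
#' expansion between half and five QC lengths, up to a twofold increase of
#' BRAVO promoter activity at the QC, a BRAVO/WOX5 expression ratio between
#' 0.05 and 0.5 in the wild type, and a 10--50\% drop of WOX5 promoter
#' activity in the mutant (the latter only when the model couples BRAVO to
#' the WOX5 promoter).
#'
#' @param xi_range,R_B_range,R_BW_range,R_W_range numeric length-2 ranges.
#' @return An `scn_ranges` list.
#' @export
compatibility_ranges <- function(xi_range = c(0.5, 5),
                                 R_B_range = c(1, 2),
                                 R_BW_range = c(0.05, 0.5),
                                 R_W_range = c(0.5, 0.9)) {
  ok <- function(r) is.numeric(r) && length(r) == 2 && r[1] <= r[2]
  stopifnot(ok(xi_range), ok(R_B_range), ok(R_BW_range), ok(R_W_range))
  structure(list(xi_range = xi_range, R_B_range = R_B_range,
                 R_BW_range = R_BW_range, R_W_range = R_W_range),
            class = "scn_ranges")
}

interp_at <- function(y, x, x0) approx(x, y, xout = x0, rule = 2)$y

#' Mutant expansion of the BRAVO promoter domain
#'
#' The reference level `pB_star` is the wild-type stationary BRAVO promoter
#' activity at the end of the VI region, `pB_wt(x_VI)`. `x_bravo` is the
#' largest position at which the mutant profile crosses `pB_star`, located
#' by linear interpolation between adjacent nodes on the decaying shootward
#' tail, and `delta_x = x_bravo - x_VI` (negative if the mutant profile
#' sits below the reference already at `x_VI`).
#'
#' If the mutant profile lies everywhere below `pB_star` there is no
#' crossing: `delta_x` is reported as the sentinel `-(x_VI - x_min)` with a
#' warning. If the tail is non-monotone and crosses several times, the
#' rightmost crossing is used and a warning is emitted.
#'
#' @param pB_wt,pB_mut promoter profiles over the nodes of `grid`.
#' @param grid the shared [grid1d()].
#' @return List with `delta_x`, `pB_star`, `x_bravo` and `no_crossing`.
#' @export
compute_delta_x <- function(pB_wt, pB_mut, grid) {
  stopifnot(length(pB_wt) == length(grid$x),
            length(pB_mut) == length(grid$x))
  x <- grid$x
  pB_star <- interp_at(pB_wt, x, grid$x_VI)
  if (pB_star <= 0)
    stop("pB_wt(x_VI) must be positive to define the expansion reference")
  above <- pB_mut >= pB_star
  if (!any(above)) {
    warning("mutant pB profile never reaches the WT reference level: ",
            "no crossing; sentinel delta_x reported")
    return(list(delta_x = -(grid$x_VI - grid$x_min), pB_star = pB_star,
                x_bravo = NA_real_, no_crossing = TRUE))
  }
  i <- max(which(above))
  if (i == length(x)) {
    x_bravo <- x[i]
  } else {
    # linear interpolation on the decaying tail between nodes i, i+1
    x_bravo <- x[i] + (pB_star - pB_mut[i]) /
      (pB_mut[i + 1] - pB_mut[i]) * (x[i + 1] - x[i])
  }
  # multiple down-crossings on the shootward tail indicate non-monotonicity
  # (the up-crossing at the activation boundary is structural, not a tail)
  tail_idx <- which(x >= 0)
  ncross <- sum(diff(above[tail_idx]) == -1)
  if (ncross > 1)
    warning("non-monotone tail: ", ncross,
            " crossings of the reference level; rightmost used")
  list(delta_x = x_bravo - grid$x_VI, pB_star = pB_star, x_bravo = x_bravo,
       no_crossing = FALSE)
}

#' Compatibility observables for one wild-type/mutant pair
#'
#' Computes, on a common grid, `xi = delta_x / L_QC` (spatial expansion of
#' the mutant BRAVO promoter domain in QC lengths),
#' `R_B = pB_mut(0) / pB_wt(0)` (fold-increase at the QC centre),
#' `R_BW = pB_wt(x_VI) / pW_wt(0)` (BRAVO vs WOX5 expression in the wild
#' type) and `R_W = pW_mut(0) / pW_wt(0)`. `R_W` is only applicable when
#' the model couples BRAVO to the WOX5 promoter, i.e. with both
#' sequestration (`lambda > 0`) and WOX5 self-repression.
#'
#' @param wt,mut lists with components `state` (`scn_state1d`) and `prof`
#'   (`scn_promoters`), as returned by [solve_genotype()].
#' @param p,spec parameters and model specification of the pair.
#' @return An `scn_observables` list with fields `delta_x`, `xi`, `R_B`,
#'   `R_BW`, `R_W` (NA when inapplicable), `pB_star`, `R_W_applicable` and
#'   `no_crossing`.
#' @export
compute_observables <- function(wt, mut, p, spec) {
  g <- wt$state$grid
  stopifnot(identical(g$x, mut$state$grid$x))
  pW0_wt <- interp_at(wt$prof$pW, g$x, 0)
  pB0_wt <- interp_at(wt$prof$pB, g$x, 0)
  if (pW0_wt <= 0)
    stop("pW_wt(0) is zero (is gamma = 0?): R_BW/R_W undefined")
  if (pB0_wt <= 0)
    stop("pB_wt(0) is zero (degenerate activation): R_B undefined")
  dx <- compute_delta_x(wt$prof$pB, mut$prof$pB, g)
  applicable <- spec_lambda(spec, p) > 0 && isTRUE(spec$wox5_self_repression)
  structure(list(
    delta_x = dx$delta_x,
    xi = dx$delta_x / g$L_QC,
    R_B = interp_at(mut$prof$pB, g$x, 0) / pB0_wt,
    R_BW = dx$pB_star / pW0_wt,
    R_W = if (applicable) interp_at(mut$prof$pW, g$x, 0) / pW0_wt
          else NA_real_,
    pB_star = dx$pB_star,
    R_W_applicable = applicable,
    no_crossing = dx$no_crossing), class = "scn_observables")
}

in_range <- function(v, r) !is.na(v) && v >= r[1] && v <= r[2]

#' Compatibility verdict for an observable set
#'
#' The verdict is the AND of the inclusive range tests on `xi`, `R_B` and
#' `R_BW`, plus `R_W` when applicable.
#'
#' @param obs an `scn_observables`.
#' @param ranges an [compatibility_ranges()].
#' @return Logical.
#' @export
is_compatible <- function(obs, ranges = compatibility_ranges()) {
  ok <- in_range(obs$xi, ranges$xi_range) &&
    in_range(obs$R_B, ranges$R_B_range) &&
    in_range(obs$R_BW, ranges$R_BW_range)
  if (obs$R_W_applicable) ok <- ok && in_range(obs$R_W, ranges$R_W_range)
  ok
}

#' Wild-type/mutant pair at one parameter set
#'
#' Solves the wild type and the `bravo` mutant to stationarity with the
#' same parameters and returns the observables.
#'
#' @inheritParams solve_genotype
#' @return List with `wt`, `mut` (solver outputs) and `obs`.
#' @export
run_pair <- function(spec, p, method = c("euler", "bvp"), ...) {
  method <- match.arg(method)
  spec_wt <- spec; spec_wt$genotype <- "wt"
  spec_mut <- spec; spec_mut$genotype <- "bravo"
  wt <- solve_genotype(spec_wt, p, method, ...)
  mut <- solve_genotype(spec_mut, p, method, ...)
  list(wt = wt, mut = mut, obs = compute_observables(wt, mut, p, spec))
}

#' Log-grid parameter-plane scan with compatibility mask
#'
#' Discretizes two parameter axes into a regular `n x n` lattice of
#' log-spaced values (default 15 x 15, i.e. 225 pairs). For each pair the
#' wild type and the mutant are solved to stationarity by the forward-Euler
#' route (the same route used for the published heatmaps) and the
#' observables and compatibility verdict are recorded. Zero-valued controls
#' (`lambda = 0`, `D = 0`) cannot sit on a log grid and should be run as
#' single-point evaluations with [run_pair()].
#'
#' @param spec an [model_spec()].
#' @param p_base base parameters; the two axis parameters are overridden
#'   per cell.
#' @param axis1,axis2 lists `list(name =, lo =, hi =)` with `lo > 0`.
#' @param n lattice side (default 15).
#' @param ranges an [compatibility_ranges()].
#' @param grid,dt,t_final forwarded to [integrate_to_steady()].
#' @return An `scn_scan`: a long-format data frame (one row per cell) with
#'   the axis values, observables, `compatible` flag and failure `reason`,
#'   plus the axes in attributes.
#' @export
scan_plane <- function(spec, p_base, axis1, axis2, n = 15,
                       ranges = compatibility_ranges(),
                       grid = euler_grid(p_base$L_QC), dt = 0.01,
                       t_final = 1000) {
  for (ax in list(axis1, axis2)) {
    if (!all(c("name", "lo", "hi") %in% names(ax)))
      stop("axis must be a list(name =, lo =, hi =)")
    if (!ax$name %in% names(p_base))
      stop("unknown parameter axis: ", ax$name)
    if (ax$lo <= 0) stop("log spacing requires lo > 0 on axis ", ax$name)
  }
  v1 <- exp(seq(log(axis1$lo), log(axis1$hi), length.out = n))
  v2 <- exp(seq(log(axis2$lo), log(axis2$hi), length.out = n))
  cells <- expand.grid(i = seq_len(n), j = seq_len(n))
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    p <- p_base
    p[[axis1$name]] <- v1[cells$i[k]]
    p[[axis2$name]] <- v2[cells$j[k]]
    res <- tryCatch({
      pr <- run_pair(spec, p, method = "euler", grid = grid, dt = dt,
                     t_final = t_final)
      o <- pr$obs
      data.frame(axis1 = v1[cells$i[k]], axis2 = v2[cells$j[k]],
                 xi = o$xi, R_B = o$R_B, R_BW = o$R_BW, R_W = o$R_W,
                 compatible = is_compatible(o, ranges), reason = "")
    }, error = function(e) {
      data.frame(axis1 = v1[cells$i[k]], axis2 = v2[cells$j[k]],
                 xi = NA_real_, R_B = NA_real_, R_BW = NA_real_,
                 R_W = NA_real_, compatible = FALSE,
                 reason = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  names(out)[1:2] <- c(axis1$name, axis2$name)
  attr(out, "axes") <- list(axis1 = axis1, axis2 = axis2, n = n,
                            values1 = v1, values2 = v2)
  attr(out, "ranges") <- ranges
  class(out) <- c("scn_scan", class(out))
  out
}

#' E-folding distance of a decaying profile tail
#'
#' Distance over which the profile falls by a factor `e`, measured from
#' `from_x` in the given direction by linear interpolation of `log(y)`.
#'
#' @param y profile over `grid` nodes.
#' @param grid an [grid1d()].
#' @param from_x starting position.
#' @param direction `+1` (shootward) or `-1` (rootward).
#' @return Distance (a.u.), or `NA` if the profile does not decay below
#'   `y(from_x)/e` within the domain.
#' @export
efolding_distance <- function(y, grid, from_x, direction = 1) {
  x <- grid$x
  y0 <- interp_at(y, x, from_x)
  if (y0 <= 0) return(NA_real_)
  target <- y0 / exp(1)
  s <- if (direction > 0) which(x > from_x) else rev(which(x < from_x))
  for (k in seq_along(s)) {
    if (y[s[k]] <= target) {
      i <- s[k]
      prev_x <- if (k == 1) from_x else x[s[k - 1]]
      prev_y <- if (k == 1) y0 else y[s[k - 1]]
      if (y[i] <= 0) return(abs(x[i] - from_x))
      # interpolate in log space on the decaying segment
      f <- (log(prev_y) - log(target)) / (log(prev_y) - log(y[i]))
      return(abs(prev_x + f * (x[i] - prev_x) - from_x))
    }
  }
  NA_real_
}

#' Response of the wild-type profile to WOX5 production changes
#'
#' Reruns the wild-type stationary solve with `gamma` scaled by each
#' factor and reports the fold-change of `pB_wt(0)` and of the shootward
#' e-folding length of `pB` (measured from `x_VI`), relative to factor 1.
#'
#' @param spec,p model specification and parameters.
#' @param gamma_factors multipliers applied to `gamma`.
#' @param method solver route.
#' @param ... forwarded to the solver.
#' @return Data frame with one row per factor: `factor`, `pB0`,
#'   `decay_len`, `pB0_fold`, `decay_len_fold`.
#' @export
robustness_to_wox5 <- function(spec, p, gamma_factors = c(0.5, 1, 2),
                               method = "euler", ...) {
  spec$genotype <- "wt"
  rows <- lapply(gamma_factors, function(f) {
    pf <- p
    pf$gamma <- p$gamma * f
    sol <- solve_genotype(spec, pf, method, ...)
    g <- sol$state$grid
    data.frame(factor = f,
               pB0 = interp_at(sol$prof$pB, g$x, 0),
               decay_len = efolding_distance(sol$prof$pB, g, g$x_VI, +1))
  })
  out <- do.call(rbind, rows)
  ref <- out[out$factor == 1, ]
  if (nrow(ref) == 1) {
    out$pB0_fold <- out$pB0 / ref$pB0
    out$decay_len_fold <- out$decay_len / ref$decay_len
  } else {
    out$pB0_fold <- out$decay_len_fold <- NA_real_
  }
  out
}
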