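new_state1d <- function(grid, fields, genotype, method, residual,
                        rel_change = NA_real_) {
  structure(c(list(grid = grid, genotype = genotype, method = method,
                   residual = residual, rel_change = rel_change), fields),
            class = "scn_state1d")
}

#' @export
print.scn_state1d <- function(x, ...) {
  sp <- intersect(c("B_s", "W_s", "Z_s", "S_s", "C_s"), names(x))
  cat("<scn_state1d> ", x$genotype, " genotype, method = ", x$method,
      "\n  species: ", paste(sp, collapse = ", "),
      "\n  grid: ", length(x$grid$x), " nodes on [", x$grid$x_min, ", ",
      x$grid$x_max, "], dx = ", x$grid$dx,
      "\n  residual: ", format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

# clamped reaction evaluation for Newton iterates that stray below zero;
# at the (nonnegative) solution it coincides with model_rhs()
clamped_rhs <- function(state, x, p, spec) {
  model_rhs(lapply(state, function(u) pmax(u, 0)), x, p, spec)
}

# stationary elimination of non-diffusible species: given the diffusible
# fields, return all fields. B follows from its stationary relation
# B = P_B / (d_B + lambda W); Z (when non-diffusible) from a damped fixed
# point of Z = P_Z(W, B(Z)) / d_Z; W (repression variant with D_W = 0)
# from its pointwise production-degradation balance.
eliminate_fields <- function(diff_fields, x, p, spec) {
  mutant <- spec$genotype == "bravo"
  lam <- spec_lambda(spec, p)
  has_z <- spec_has_z(spec)
  f <- diff_fields
  if (is.null(f$W)) { # W non-diffusible: repression variant only
    W <- p$gamma * qc_indicator(x, p$L_QC) / p$d_W
    if (isTRUE(spec$wox5_self_repression)) {
      wqc <- uniroot(function(w) p$gamma / (1 + (w / p$k_W)^p$h) - p$d_W * w,
                     c(0, p$gamma / p$d_W + 1))$root
      W <- wqc * qc_indicator(x, p$L_QC)
    }
    f$W <- W
  }
  Wc <- pmax(f$W, 0)
  if (has_z && is.null(f$Z)) {
    if (p$d_Z <= 0) stop("d_Z must be positive to eliminate a static Z")
    Z <- prod_z(Wc, 0 * Wc, p, spec) / p$d_Z
    if (!mutant && spec$variant %in% c("repression", "mixed")) {
      for (k in 1:200) { # contraction: P_Z decreases with B, B grows with Z
        B <- prod_bravo(pmax(Z, 0), x, p, spec) / (p$d_B + lam * Wc)
        Znew <- prod_z(Wc, B, p, spec) / p$d_Z
        if (max(abs(Znew - Z)) < 1e-13 * max(1, max(Z))) { Z <- Znew; break }
        Z <- 0.5 * (Z + Znew)
      }
    }
    f$Z <- Z
  }
  activator <- if (has_z) pmax(f$Z, 0) else Wc
  f$B <- if (mutant) 0 * Wc
         else prod_bravo(activator, x, p, spec) / (p$d_B + lam * Wc)
  if (spec$variant == "sequestration_S" && is.null(f$S))
    f$S <- p$alpha_S / (p$d_S + p$lambda_S * Wc)
  f
}

bvp_diffusible <- function(spec, p) {
  out <- character(0)
  if (p$D_W > 0) out <- c(out, "W")
  if (spec_has_z(spec) && p$D_Z > 0) out <- c(out, "Z")
  if (spec$variant == "sequestration_S" && p$D_S > 0) out <- c(out, "S")
  out
}

#' Stationary 1D profiles via boundary-value reduction
#'
#' Sets the reaction terms of the non-diffusible species to zero,
#' substitutes their stationary relations, and solves the remaining
#' second-order system with zero Dirichlet boundaries (periodic for the
#' sequestrator S) by a damped Newton iteration on the finite-difference
#' discretization of the user grid.
#'
#' @param spec an [model_spec()] object (not `full_complex`; the explicit-
#'   complex model is integrated in time, see [integrate_to_steady()]).
#' @param p an [model_params()] object.
#' @param grid an [grid1d()]; defaults to the fine grid `dx = 0.05` on
#'   `[-600, 600]`.
#' @param tol max-norm tolerance on the stationary residual.
#' @param max_iter Newton iteration cap.
#' @return An `scn_state1d` with stationary fields `B_s`, `W_s` (plus
#'   `Z_s`/`S_s` when present), the genotype tag and convergence metadata.
#' @export
solve_stationary_bvp <- function(spec, p, grid = bvp_grid(p$L_QC),
                                 tol = 1e-8, max_iter = 60) {
  stopifnot(inherits(spec, "scn_spec"), inherits(grid, "scn_grid1d"))
  validate_params(p)
  if (spec$variant == "full_complex")
    stop("full_complex has no BVP reduction here; integrate it in time ",
         "or solve the minimal model with lambda = lambda_eff()")
  if (p$D_W == 0 && spec$variant != "repression" &&
      spec_lambda(spec, p) > 0)
    stop("D_W = 0 with active sequestration is not supported by the BVP ",
         "route; use integrate_to_steady()")
  dn <- bvp_diffusible(spec, p)
  if (length(dn) == 0)
    stop("no diffusible species: the stationary state is a pure-reaction ",
         "fixed point; evaluate eliminate_fields() on the node positions")

  x <- grid$x
  n <- length(x)
  dx2 <- grid$dx^2
  periodic <- dn == "S"
  idx <- lapply(seq_along(dn), function(k) if (periodic[k]) 1:n else 2:(n - 1))
  m <- vapply(idx, length, integer(1))
  off <- cumsum(c(0, m[-length(m)]))
  Dco <- c(W = p$D_W, Z = p$D_Z, S = p$D_S)[dn]

  lap_mat <- function(mm, per) {
    L <- Matrix::bandSparse(mm, k = c(-1, 0, 1),
                            diagonals = list(rep(1, mm - 1), rep(-2, mm),
                                             rep(1, mm - 1)))
    if (per) { L[1, mm] <- 1; L[mm, 1] <- 1 }
    L / dx2
  }
  Ls <- lapply(seq_along(dn), function(k) Dco[k] * lap_mat(m[k], periodic[k]))
  A <- do.call(Matrix::bdiag, Ls)

  unpack <- function(u) {
    f <- list()
    for (k in seq_along(dn)) {
      v <- numeric(n)
      v[idx[[k]]] <- u[off[k] + seq_len(m[k])]
      f[[dn[k]]] <- v
    }
    f
  }
  reaction <- function(fields) {
    full <- eliminate_fields(fields, x, p, spec)
    r <- clamped_rhs(full[intersect(c("B", "W", "Z", "S"), names(full))],
                     x, p, spec)
    lapply(seq_along(dn), function(k) r[[paste0("d", dn[k])]][idx[[k]]])
  }
  resid <- function(u) {
    f <- unpack(u)
    r <- reaction(f)
    unlist(lapply(seq_along(dn), function(k)
      as.numeric(Ls[[k]] %*% u[off[k] + seq_len(m[k])]) + r[[k]]))
  }
  react_jac <- function(u) {
    f <- unpack(u)
    r0 <- reaction(f)
    trip_i <- trip_j <- integer(0); trip_x <- numeric(0)
    for (k2 in seq_along(dn)) {
      eps <- 1e-6 * (1 + abs(f[[dn[k2]]]))
      fp <- f
      fp[[dn[k2]]] <- f[[dn[k2]]] + eps
      rp <- reaction(fp)
      for (k1 in seq_along(dn)) {
        d <- (rp[[k1]] - r0[[k1]]) / eps[idx[[k1]]]
        # node-local coupling: align shared nodes of the two species
        common <- intersect(idx[[k1]], idx[[k2]])
        i1 <- match(common, idx[[k1]]); i2 <- match(common, idx[[k2]])
        trip_i <- c(trip_i, off[k1] + i1)
        trip_j <- c(trip_j, off[k2] + i2)
        trip_x <- c(trip_x, d[i1])
      }
    }
    Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                         dims = c(sum(m), sum(m)))
  }

  u <- numeric(sum(m))
  Fu <- resid(u)
  nf <- max(abs(Fu))
  mu <- 0
  iter <- 0
  while (nf > tol && iter < max_iter) {
    iter <- iter + 1
    J <- A + react_jac(u)
    if (mu > 0) J <- J + mu * Matrix::Diagonal(sum(m))
    step <- tryCatch(as.numeric(Matrix::solve(J, -Fu)),
                     error = function(e) NULL)
    if (is.null(step)) { mu <- max(mu * 10, 1e-6); next }
    accepted <- FALSE
    t <- 1
    for (ls in 1:8) {
      Ft <- resid(u + t * step)
      if (max(abs(Ft)) < nf) {
        u <- u + t * step; Fu <- Ft; nf <- max(abs(Ft))
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (accepted) mu <- mu / 4 else mu <- max(mu * 10, 1e-6)
    if (mu > 1e8)
      stop(sprintf("BVP Newton iteration failed to converge (residual %.3g)",
                   nf))
  }
  if (nf > tol)
    stop(sprintf("BVP solver did not reach tolerance %.1g (residual %.3g ",
                 tol, nf), "after ", iter, " iterations")

  f <- lapply(unpack(u), pmax, 0)
  full <- eliminate_fields(f, x, p, spec)
  fields <- list(W_s = full$W)
  if (spec$genotype != "bravo") fields$B_s <- full$B
  if (spec_has_z(spec)) fields$Z_s <- full$Z
  if (spec$variant == "sequestration_S") fields$S_s <- full$S
  fields <- fields[intersect(c("B_s", "W_s", "Z_s", "S_s"), names(fields))]
  new_state1d(grid, fields, spec$genotype, "bvp", nf)
}

#' Stationary 1D profiles via forward-Euler time integration
#'
#' Integrates the full time-dependent equations from all-zero initial
#' conditions with zero Dirichlet boundaries (periodic for the sequestrator
#' S) and a central-difference Laplacian, returning the state at `t_final`.
#' The explicit-scheme stability condition `dt * D / dx^2 <= 1/2` is
#' checked for every diffusive species before stepping.
#'
#' @inheritParams solve_stationary_bvp
#' @param grid an [grid1d()]; defaults to the coarse grid `dx = 1` on
#'   `[-400, 400]`.
#' @param dt time step (default 0.01).
#' @param t_final final time (default 1000).
#' @param fp [full_model_params()], required for `variant = "full_complex"`.
#' @return An `scn_state1d` with the final fields and a stationarity record
#'   (`residual`: max-norm of the rhs at `t_final`; `rel_change`: relative
#'   field change over the last 1\% of steps).
#' @export
integrate_to_steady <- function(spec, p, grid = euler_grid(p$L_QC),
                                dt = 0.01, t_final = 1000, fp = NULL) {
  stopifnot(inherits(spec, "scn_spec"), inherits(grid, "scn_grid1d"),
            dt > 0, t_final > 0)
  validate_params(p)
  if (spec$variant == "full_complex" && is.null(fp))
    stop("full_complex requires fp = full_model_params(...)")
  if (is.null(fp)) fp <- full_model_params(0, 0, 0)
  Dmax <- max(p$D_W,
              if (spec_has_z(spec)) p$D_Z else 0,
              if (spec$variant == "sequestration_S") p$D_S else 0)
  if (dt * Dmax / grid$dx^2 > 0.5)
    stop(sprintf("explicit-scheme stability violated: dt*D/dx^2 = %.3g > 1/2",
                 dt * Dmax / grid$dx^2))
  x <- grid$x
  pars <- c(unclass(p), unclass(fp),
            list(variant = variant_code(spec$variant),
                 hillmode = as.integer(spec$production_mode == "hill"),
                 self_rep = isTRUE(spec$wox5_self_repression),
                 basal = isTRUE(spec$basal_vi_production),
                 mutant = spec$genotype == "bravo"))
  pars$lambda <- spec_lambda(spec, p)
  nsteps <- ceiling(t_final / dt)
  res <- .euler1d_cpp(pars, qc_indicator(x, p$L_QC),
                      activation_mask(x, p$L_QC), vi_indicator(x, p$L_QC),
                      grid$dx, dt, as.integer(nsteps))
  fields <- list(W_s = res$W)
  if (spec$genotype != "bravo") fields$B_s <- res$B
  if (spec_has_z(spec)) fields$Z_s <- res$Z
  if (spec$variant == "sequestration_S") fields$S_s <- res$S
  if (spec$variant == "full_complex" && spec$genotype != "bravo")
    fields$C_s <- res$C
  fields <- fields[intersect(c("B_s", "W_s", "Z_s", "S_s", "C_s"),
                             names(fields))]
  new_state1d(grid, fields, spec$genotype, "euler", res$residual,
              res$rel_change)
}

#' Promoter-activity profiles at the stationary state
#'
#' Evaluates the production functions on the stationary concentration
#' profiles: `pB(x) = P_B(activator_s(x), x)`, `pW(x) = P_W(W_s(x), x)` and,
#' when the variant includes Z, `pZ(x) = P_Z(W_s(x), B_s(x))`. For the
#' `bravo` mutant, `pB` is computed from the mutant's stationary activator
#' profile (the promoter is intact even though the protein is absent) and
#' `pZ` uses `B = 0`.
#'
#' @param state an `scn_state1d` from either solver route.
#' @param spec,p the model specification and parameters used to produce it.
#' @return An `scn_promoters` list with components `pB`, `pW` and (when
#'   applicable) `pZ`, each a nonnegative vector over the grid nodes.
#' @export
promoter_profiles <- function(state, spec, p) {
  stopifnot(inherits(state, "scn_state1d"))
  x <- state$grid$x
  W <- state$W_s
  B <- if (spec$genotype == "bravo") 0 * W else state$B_s
  activator <- if (spec_has_z(spec)) state$Z_s else W
  out <- list(pB = prod_bravo(activator, x, p, spec),
              pW = prod_wox5(W, x, p, spec))
  if (spec_has_z(spec)) out$pZ <- prod_z(W, B, p, spec)
  structure(out, class = "scn_promoters")
}

#' Solve one genotype to stationarity and attach promoter profiles
#'
#' Convenience wrapper used throughout the scans: runs the requested solver
#' route and returns both the stationary state and the promoter profiles.
#'
#' @inheritParams solve_stationary_bvp
#' @param method `"euler"` or `"bvp"`.
#' @param ... passed to the solver.
#' @return List with components `state` and `prof`.
#' @export
solve_genotype <- function(spec, p, method = c("euler", "bvp"), ...) {
  method <- match.arg(method)
  state <- if (method == "bvp") solve_stationary_bvp(spec, p, ...)
           else integrate_to_steady(spec, p, ...)
  list(state = state, prof = promoter_profiles(state, spec, p))
}

#' Write stationary profiles to an annotated CSV
#'
#' Columns `x`, `B`, `W`, `Z`, `S`, `pB`, `pW`, `pZ` (absent species as NA)
#' preceded by `#variant`, `#genotype` and `#params-hash` metadata lines.
#'
#' @param state an `scn_state1d`.
#' @param prof matching `scn_promoters`.
#' @param spec,p model specification and parameters (for the metadata).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(state, prof, spec, p, path) {
  df <- data.frame(x = state$grid$x,
                   B = state$B_s %||% NA, W = state$W_s %||% NA,
                   Z = state$Z_s %||% NA, S = state$S_s %||% NA,
                   pB = prof$pB %||% NA, pW = prof$pW %||% NA,
                   pZ = prof$pZ %||% NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#variant ", spec$variant),
               paste0("#genotype ", spec$genotype),
               paste0("#params-hash ", config_hash(c(unclass(spec),
                                                     unclass(p))))), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a profiles CSV written by [write_profiles()]
#'
#' @param path file path.
#' @return A data frame with the profile columns; metadata in
#'   `attr(, "meta")`.
#' @export
read_profiles <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- read.csv(text = lines[!grepl("^#", lines)])
  attr(df, "meta") <- meta
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
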