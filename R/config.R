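#' FNV-1a hash of a configuration
#'
#' Short stable hash embedded in every artifact so that a run can be traced
#' back to the exact configuration that produced it.
#'
#' @param x any R object (serialized via its deparsed form).
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  bytes <- utf8ToInt(s)
  # polynomial rolling hash modulo a Mersenne prime (exact in doubles)
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.config_keys <- list(
  variant = "character", production_mode = "character",
  wox5_self_repression = "logical", basal_vi_production = "logical",
  genotype = "character", params = "list", grid = "list",
  solver = "list", seed = "numeric", scan = "list", layout = "list",
  params2d = "list", ranges = "list")

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML configuration (chosen by file extension), applies
#' the package defaults for anything not given, and validates the result.
#' Every parameter key matches the model symbol it stands for (`alpha_L`,
#' `lambda`, `c`, ...). Unknown keys are rejected with the offending name.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return An `scn_config` list with components `spec` ([model_spec()]),
#'   `params` ([model_params()]), `grid`, `solver`, `seed` and the
#'   optional `scan` / `layout` / `params2d` / `ranges` blocks.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = , yml = yaml::read_yaml(path),
                stop("unsupported config format: .", ext,
                     " (use JSON or YAML)"))
  as_config(raw)
}

#' @rdname load_config
#' @param raw a named list with the same structure as the file contents.
#' @export
as_config <- function(raw) {
  stopifnot(is.list(raw))
  unknown <- setdiff(names(raw), names(.config_keys))
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  spec <- model_spec(
    variant = raw$variant %||% "sequestration",
    production_mode = raw$production_mode %||% "linear",
    wox5_self_repression = raw$wox5_self_repression %||% FALSE,
    basal_vi_production = raw$basal_vi_production %||% FALSE,
    genotype = raw$genotype %||% "wt")
  pdef <- default_params(spec$variant, spec$production_mode)
  pknown <- names(unclass(pdef))
  pbad <- setdiff(names(raw$params), pknown)
  if (length(pbad))
    stop("unknown parameter key: ", paste(pbad, collapse = ", "))
  p <- do.call(model_params, modifyList(unclass(pdef),
                                        as.list(raw$params %||% list())))
  sdef <- list(method = "bvp", dt = 0.01, t_final = 1000, tol = 1e-8,
               dt2d = 0.1, t_end2d = 3000)
  solver <- modifyList(sdef, as.list(raw$solver %||% list()))
  if (!solver$method %in% c("bvp", "euler"))
    stop("solver$method must be 'bvp' or 'euler'")
  # each solver route has its own canonical grid
  gdef <- if (solver$method == "euler")
    list(x_min = -400, x_max = 400, dx = 1)
  else list(x_min = -600, x_max = 600, dx = 0.05)
  gcfg <- modifyList(gdef, as.list(raw$grid %||% list()))
  cfg <- list(spec = spec, params = p,
              grid = grid1d(gcfg$x_min, gcfg$x_max, gcfg$dx, p$L_QC),
              solver = solver, seed = as.integer(raw$seed %||% 1L),
              scan = raw$scan, layout = raw$layout,
              params2d = if (!is.null(raw$params2d))
                do.call(params2d, raw$params2d) else params2d(),
              ranges = if (!is.null(raw$ranges))
                do.call(compatibility_ranges, lapply(raw$ranges, unlist))
              else compatibility_ranges())
  class(cfg) <- "scn_config"
  cfg
}

#' Save a configuration
#'
#' @param cfg an `scn_config` (or the raw list form).
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  raw <- if (inherits(cfg, "scn_config")) {
    c(unclass(cfg$spec),
      list(params = unclass(cfg$params),
           grid = list(x_min = cfg$grid$x_min, x_max = cfg$grid$x_max,
                       dx = cfg$grid$dx),
           solver = cfg$solver, seed = cfg$seed))
  } else cfg
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::write_json(raw, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         yaml = , yml = yaml::write_yaml(raw, path),
         stop("unsupported config format: .", ext))
  invisible(path)
}

artifact_header <- function(cfg) {
  c(paste0("#scniche-version ",
           as.character(utils::packageVersion("scniche"))),
    paste0("#config-hash ", config_hash(list(unclass(cfg$spec),
                                             unclass(cfg$params)))))
}

#' Run one orchestrated command
#'
#' Dispatches the verbs tying the modules together, writing deterministic
#' artifacts (annotated with the config hash and package version) to
#' `out_dir`:
#' \describe{
#'   \item{simulate1d}{solve the configured variant for wild type and
#'     `bravo` mutant, write `profiles_wt.csv`, `profiles_bravo.csv` and
#'     `observables.json`.}
#'   \item{scan}{parameter-plane scan per `cfg$scan` (fields `axis1`,
#'     `axis2` as `list(name, lo, hi)`, optional `n`); writes the 225-row
#'     `scan.csv`.}
#'   \item{layout}{generate the synthetic layout per `cfg$layout` (field
#'     `preset`); writes `layout_labels.tsv`, `layout_meta.json`,
#'     `layout_stain.png`.}
#'   \item{simulate2d}{generate the layout, build field maps, run the
#'     FTCS engine for both genotypes; writes `transverse_profiles.csv`
#'     and `fields_<genotype>.rds`.}
#'   \item{observables}{like `simulate1d` but emits only
#'     `observables.json`.}
#' }
#'
#' @param verb one of `"simulate1d"`, `"scan"`, `"layout"`,
#'   `"simulate2d"`, `"observables"`.
#' @param cfg an `scn_config`.
#' @param out_dir output directory (created if missing).
#' @return Character vector of artifact paths, invisibly.
#' @export
run_command <- function(verb = c("simulate1d", "scan", "layout",
                                 "simulate2d", "observables"),
                        cfg, out_dir = ".") {
  verb <- match.arg(verb)
  stopifnot(inherits(cfg, "scn_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- artifact_header(cfg)
  paths <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    write.csv(df, con, row.names = FALSE)
    path
  }
  if (verb %in% c("simulate1d", "observables")) {
    for (gt in c("wt", "bravo")) {
      spec <- cfg$spec; spec$genotype <- gt
      sol <- solve_genotype(spec, cfg$params, cfg$solver$method,
                            grid = cfg$grid)
      if (verb == "simulate1d") {
        path <- file.path(out_dir, paste0("profiles_", gt, ".csv"))
        write_profiles(sol$state, sol$prof, spec, cfg$params, path)
        paths <- c(paths, path)
      }
      assign(paste0("sol_", gt), sol)
    }
    obs <- compute_observables(get("sol_wt"), get("sol_bravo"),
                               cfg$params, cfg$spec)
    obs$compatible <- is_compatible(obs, cfg$ranges)
    path <- file.path(out_dir, "observables.json")
    jsonlite::write_json(c(unclass(obs),
                           list(config_hash = config_hash(unclass(cfg$params)))),
                         path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, path)
  } else if (verb == "scan") {
    if (is.null(cfg$scan)) stop("config has no scan block")
    sc <- scan_plane(cfg$spec, cfg$params,
                     axis1 = as.list(cfg$scan$axis1),
                     axis2 = as.list(cfg$scan$axis2),
                     n = cfg$scan$n %||% 15, ranges = cfg$ranges,
                     dt = cfg$solver$dt,
                     t_final = cfg$scan$t_final %||% cfg$solver$t_final)
    paths <- c(paths, emit_csv(as.data.frame(sc), "scan.csv"))
  } else if (verb == "layout") {
    tpl <- layout_template(cfg$layout$preset %||% "wt")
    lay <- generate_layout(tpl, seed = cfg$seed)
    prefix <- file.path(out_dir, "layout")
    write_layout(lay, prefix)
    paths <- c(paths, paste0(prefix, c("_labels.tsv", "_meta.json",
                                       "_stain.png")))
  } else if (verb == "simulate2d") {
    tpl <- layout_template(cfg$layout$preset %||% "mini")
    lay <- generate_layout(tpl, seed = cfg$seed)
    maps <- build_field_maps(lay, cfg$params, cfg$params2d)
    prof <- list()
    for (gt in c("wt", "bravo")) {
      st <- ftcs_run(maps, gt, dt = cfg$solver$dt2d,
                     t_end = cfg$solver$t_end2d,
                     wox5_self_repression = cfg$spec$wox5_self_repression)
      path <- file.path(out_dir, paste0("fields_", gt, ".rds"))
      saveRDS(st[c("B", "W", "Z", "B_GFP", "W_GFP", "Z_GFP", "t")], path)
      paths <- c(paths, path)
      prof[[gt]] <- transverse_profile(st$B_GFP, lay)
    }
    df <- data.frame(row = seq_along(prof$wt), pB_GFP_wt = prof$wt,
                     pB_GFP_bravo = prof$bravo)
    paths <- c(paths, emit_csv(df, "transverse_profiles.csv"))
  }
  invisible(paths)
}
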