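.cell_types <- c("QC", "VI", "V", "CEI", "PER", "CX", "END", "EPI",
                 "CSC", "CC", "LRC")

#' Geometric recipe for a synthetic root layout
#'
#' Describes a segmented confocal midplane of the root apical meristem as a
#' pixel lattice: tissue files (columns of cells) arranged symmetrically
#' around the vasculature, cell rows stacked along the root axis with the
#' columella tiers, columella stem cells, quiescent centre and vascular
#' initials at the tip, all separated by 2-pixel cell walls. The recipe
#' also carries the intensity model for the synthetic wall-stain image on
#' which the segmentation routine is exercised.
#'
#' Presets: `"wt"` gives the 228 x 448 wild-type lattice, `"bravo"` the
#' slightly wider 231 x 448 mutant lattice, `"mini"` a 100 x 200 lattice
#' for fast simulation runs. One pixel corresponds to 0.5 um.
#'
#' @param preset `"wt"`, `"bravo"` or `"mini"`.
#' @param ... named overrides of recipe fields (e.g. `noise_sd`).
#' @return An `scn_template` list.
#' @export
layout_template <- function(preset = c("wt", "bravo", "mini"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    wt = list(
      L_x = 228, L_y = 448,
      file_roles = c("LRC", "EPI", "CX", "END", "PER", "V", "V", "V",
                     "PER", "END", "CX", "EPI", "LRC"),
      file_widths = c(12, 14, 16, 12, 10, 14, 14, 14, 10, 12, 16, 14, 12),
      n_cc_rows = 3, cc_len = 20, csc_len = 14, qc_len = 14, vi_len = 16,
      body_len = 22, margin_y = 12),
    bravo = list(
      L_x = 231, L_y = 448,
      file_roles = c("LRC", "EPI", "CX", "END", "PER", "V", "V", "V",
                     "PER", "END", "CX", "EPI", "LRC"),
      file_widths = c(12, 14, 16, 12, 10, 14, 17, 14, 10, 12, 16, 14, 12),
      n_cc_rows = 3, cc_len = 20, csc_len = 14, qc_len = 14, vi_len = 16,
      body_len = 22, margin_y = 12),
    mini = list(
      L_x = 100, L_y = 200,
      file_roles = c("LRC", "EPI", "CX", "END", "PER", "V", "V", "V",
                     "PER", "END", "CX", "EPI", "LRC"),
      file_widths = c(4, 6, 6, 5, 4, 6, 6, 6, 4, 5, 6, 6, 4),
      n_cc_rows = 3, cc_len = 10, csc_len = 8, qc_len = 8, vi_len = 8,
      body_len = 12, margin_y = 6))
  tpl <- modifyList(c(base, list(
    wall = 2, pixel_size = 0.5,
    wall_mean = 0.80, cell_mean = 0.22, outside_mean = 0.08,
    noise_sd = 0.02, basal_types = "VI", preset = preset)), list(...))
  if (length(tpl$file_roles) != length(tpl$file_widths))
    stop("file_roles and file_widths must have the same length")
  needed_x <- sum(tpl$file_widths) + tpl$wall * (length(tpl$file_widths) + 1)
  if (needed_x + 2 > tpl$L_x)
    stop("template dimensions too small to place all tissue files (needs ",
         needed_x + 2, " columns)")
  structure(tpl, class = "scn_template")
}

# column/row intervals of the cell lattice described by a template
template_geometry <- function(tpl) {
  w <- tpl$wall
  needed_x <- sum(tpl$file_widths) + w * (length(tpl$file_widths) + 1)
  margin_x <- floor((tpl$L_x - needed_x) / 2)
  # files: [start, end] column range of each file interior
  c0 <- margin_x + 1 # first wall column
  col_lo <- integer(0); col_hi <- integer(0)
  pos <- c0 + w
  for (k in seq_along(tpl$file_widths)) {
    col_lo[k] <- pos
    col_hi[k] <- pos + tpl$file_widths[k] - 1
    pos <- col_hi[k] + 1 + w
  }
  root_c <- c(c0, pos - 1) # inclusive wall-to-wall column range
  # rows from the rootward tip upwards
  heights <- c(rep(tpl$cc_len, tpl$n_cc_rows), tpl$csc_len, tpl$qc_len,
               tpl$vi_len)
  kinds <- c(rep("CCROW", tpl$n_cc_rows), "CSCROW", "QCROW", "VIROW")
  r0 <- tpl$margin_y + 1 # first wall row
  pos <- r0 + w
  row_lo <- integer(0); row_hi <- integer(0); row_kind <- character(0)
  for (k in seq_along(heights)) {
    row_lo <- c(row_lo, pos); row_hi <- c(row_hi, pos + heights[k] - 1)
    row_kind <- c(row_kind, kinds[k])
    pos <- pos + heights[k] + w
  }
  # body rows until the top margin
  top_limit <- tpl$L_y - tpl$margin_y - w
  while (pos + tpl$body_len - 1 <= top_limit) {
    row_lo <- c(row_lo, pos); row_hi <- c(row_hi, pos + tpl$body_len - 1)
    row_kind <- c(row_kind, "BODYROW")
    pos <- pos + tpl$body_len + w
  }
  root_r <- c(r0, pos - 1)
  list(col_lo = col_lo, col_hi = col_hi, row_lo = row_lo, row_hi = row_hi,
       row_kind = row_kind, root_r = root_r, root_c = root_c)
}

type_for <- function(role, kind) {
  if (role == "LRC") return("LRC")
  switch(kind,
         CCROW = "CC",
         CSCROW = "CSC",
         QCROW = switch(role, V = "QC", CX = "CEI", END = "CEI", role),
         VIROW = if (role == "V") "VI" else role,
         BODYROW = role)
}

#' Generate a synthetic labeled root layout and its wall-stain image
#'
#' Builds the pixel-label grid described by the template (one label per
#' cell, a single shared label for all wall pixels, a single label for the
#' outside), assigns cell types from the file/row recipe, and renders a
#' synthetic propidium-iodide-like stain image: bright on wall pixels,
#' dark in cell interiors and background, plus clipped Gaussian noise.
#' The layout is deterministic given the template; the stain noise is
#' deterministic given `seed`.
#'
#' @param template an [layout_template()].
#' @param seed integer seed for the stain noise.
#' @return An `scn_layout` with fields `labels` (integer matrix; outside
#'   `0`, wall `1`, cells `2..`), `cell_types` (named character vector over
#'   cell labels), `wall_label`, `outside_label`, `pixel_size`, `stain` and
#'   the generating `template`.
#' @export
generate_layout <- function(template, seed = 1) {
  stopifnot(inherits(template, "scn_template"))
  g <- template_geometry(template)
  lab <- matrix(0L, template$L_y, template$L_x)
  lab[g$root_r[1]:g$root_r[2], g$root_c[1]:g$root_c[2]] <- 1L
  types <- character(0)
  nextlab <- 2L
  for (ri in seq_along(g$row_lo)) {
    for (ci in seq_along(g$col_lo)) {
      lab[g$row_lo[ri]:g$row_hi[ri], g$col_lo[ci]:g$col_hi[ci]] <- nextlab
      types[as.character(nextlab)] <-
        type_for(template$file_roles[ci], g$row_kind[ri])
      nextlab <- nextlab + 1L
    }
  }
  stain <- matrix(template$outside_mean, template$L_y, template$L_x)
  stain[lab == 1L] <- template$wall_mean
  stain[lab >= 2L] <- template$cell_mean
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  stain <- stain + matrix(rnorm(length(stain), 0, template$noise_sd),
                          nrow(stain))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  stain <- pmin(pmax(stain, 0), 1)
  structure(list(labels = lab, cell_types = types, wall_label = 1L,
                 outside_label = 0L, pixel_size = template$pixel_size,
                 stain = stain, template = template),
            class = "scn_layout")
}

#' @export
print.scn_layout <- function(x, ...) {
  cat("<scn_layout> ", nrow(x$labels), " x ", ncol(x$labels),
      " pixels (", x$pixel_size, " um/px), ",
      sum(x$labels == x$wall_label), " wall px, ",
      length(unique(x$labels[x$labels > x$wall_label])), " cells",
      if (is.null(x$cell_types)) " (untyped)" else " (typed)", "\n",
      sep = "")
  invisible(x)
}

shift_mat <- function(m, dr, dc) {
  out <- matrix(0L, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Segment a wall-stain image into cell/wall/outside labels
#'
#' Pipeline: (1) global Otsu threshold separating bright wall pixels from
#' dark interiors; (2) morphological skeletonization of the wall mask,
#' re-dilated to the fixed 2-pixel wall width; (3) 4-connected labeling of
#' the non-wall regions, with every component touching the image border
#' merged into the single outside label and the remaining components
#' becoming cells. Cells smaller than 4 pixels are merged into the wall
#' with a warning.
#'
#' @param image numeric matrix in `[0, 1]` with bright walls on a dark
#'   background.
#' @return An `scn_layout` with labels only (`cell_types` is `NULL`).
#' @export
segment_image <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (diff(range(image)) < 0.05)
    stop("segmentation error: image intensities are not bimodal")
  thr <- EBImage::otsu(EBImage::Image(image), range = range(image))
  mask <- image > thr
  frac <- mean(mask)
  if (frac < 0.005 || frac > 0.95)
    stop("segmentation error: Otsu threshold does not isolate cell walls")
  skel <- .thin_cpp(matrix(as.integer(mask), nrow(mask)))
  wall <- (skel | shift_mat(skel, 1, 0) | shift_mat(skel, 0, 1) |
             shift_mat(skel, 1, 1))
  comp <- EBImage::bwlabel(EBImage::Image(1 - wall))
  comp <- matrix(as.integer(comp), nrow(wall))
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1],
                     comp[, ncol(comp)]))
  border <- setdiff(border, 0L)
  lab <- matrix(1L, nrow(wall), ncol(wall)) # wall by default
  lab[comp %in% border] <- 0L
  cells <- setdiff(unique(as.integer(comp)), c(0L, border))
  sizes <- table(factor(comp[comp %in% cells], levels = cells))
  tiny <- cells[sizes < 4]
  if (length(tiny) > 0) {
    warning(length(tiny), " cell region(s) of area < 4 px merged into wall")
    cells <- setdiff(cells, tiny)
  }
  # renumber cells in raster order of first occurrence
  first <- vapply(cells, function(k) which(comp == k)[1], numeric(1))
  cells <- cells[order(first)]
  for (k in seq_along(cells)) lab[comp == cells[k]] <- k + 1L
  structure(list(labels = lab, cell_types = NULL, wall_label = 1L,
                 outside_label = 0L, pixel_size = NA_real_, stain = image,
                 template = NULL),
            class = "scn_layout")
}

#' Assign cell types to a segmented layout from a template
#'
#' Maps each cell label to a cell type by the position of its centroid in
#' the template's file/row geometry. Errors if any cell centroid falls
#' outside the template lattice.
#'
#' @param layout an `scn_layout` (labels present).
#' @param template the [layout_template()] describing the geometry.
#' @return The layout with `cell_types` and `pixel_size` filled in.
#' @export
assign_cell_types <- function(layout, template) {
  stopifnot(inherits(layout, "scn_layout"), inherits(template,
                                                     "scn_template"))
  g <- template_geometry(template)
  labs <- sort(unique(layout$labels[layout$labels > layout$wall_label]))
  types <- character(0)
  for (l in labs) {
    idx <- which(layout$labels == l, arr.ind = TRUE)
    cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
    fi <- which(cc >= g$col_lo - 1 & cc <= g$col_hi + 1)
    ri <- which(cr >= g$row_lo - 1 & cr <= g$row_hi + 1)
    if (length(fi) != 1 || length(ri) != 1)
      stop(sprintf("unassignable cell label %d (centroid %.1f, %.1f)",
                   l, cr, cc))
    types[as.character(l)] <- type_for(template$file_roles[fi],
                                       g$row_kind[ri])
  }
  layout$cell_types <- types
  layout$pixel_size <- template$pixel_size
  layout$template <- template
  layout
}

#' Persist / load a root layout
#'
#' The label grid goes to a plain TSV, the metadata (label semantics, cell
#' types, pixel size) to a JSON sidecar, and the stain image (if present)
#' to an 8-bit grayscale PNG.
#'
#' @param layout an `scn_layout`.
#' @param prefix path prefix; writes `<prefix>_labels.tsv`,
#'   `<prefix>_meta.json` and (if present) `<prefix>_stain.png`.
#' @return The prefix, invisibly.
#' @export
write_layout <- function(layout, prefix) {
  utils::write.table(layout$labels, paste0(prefix, "_labels.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(wall_label = layout$wall_label,
               outside_label = layout$outside_label,
               pixel_size = layout$pixel_size,
               cell_types = as.list(layout$cell_types))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, null = "null")
  if (!is.null(layout$stain))
    png::writePNG(layout$stain, paste0(prefix, "_stain.png"))
  invisible(prefix)
}

#' @rdname write_layout
#' @export
read_layout <- function(prefix) {
  lab <- as.matrix(utils::read.table(paste0(prefix, "_labels.tsv"),
                                     sep = "\t"))
  dimnames(lab) <- NULL
  storage.mode(lab) <- "integer"
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  stain_path <- paste0(prefix, "_stain.png")
  stain <- if (file.exists(stain_path)) png::readPNG(stain_path) else NULL
  ct <- unlist(meta$cell_types)
  structure(list(labels = lab,
                 cell_types = if (length(ct)) ct else NULL,
                 wall_label = as.integer(meta$wall_label),
                 outside_label = as.integer(meta$outside_label),
                 pixel_size = meta$pixel_size, stain = stain,
                 template = NULL),
            class = "scn_layout")
}
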