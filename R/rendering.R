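#' Rendered RGB image
#'
#' The output artefact of every rendering path: a rows x cols x 3 array in
#' \[0,1\] plus structured annotations (legend entries, scale bars, warnings)
#' and, when known, the source pixel size.
#'
#' @param rgb rows x cols x 3 numeric array, all values in \[0,1\].
#' @param annotations list of annotation records (`kind`, `payload`).
#' @param pixel_size_um optional micrometres per pixel, carried from the
#'   source image.
#' @return an object of class `rendered_image`.
#' @export
rendered_image <- function(rgb, annotations = list(), pixel_size_um = NULL) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L) {
    stop("rgb must be a rows x cols x 3 array", call. = FALSE)
  }
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 1)) {
    stop("rgb values must lie in [0,1]", call. = FALSE)
  }
  check_pixel_size(pixel_size_um)
  structure(list(rgb = rgb, annotations = annotations,
                 pixel_size_um = pixel_size_um),
            class = "rendered_image")
}

#' @export
dim.rendered_image <- function(x) dim(x$rgb)

#' @export
print.rendered_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<rendered_image> %d x %d px, %d annotation(s)\n",
              d[1], d[2], length(x$annotations)))
  invisible(x)
}

annotation <- function(kind, payload) list(kind = kind, payload = payload)

#' Categorical colour palette
#'
#' Maps metadata levels to RGB colours, with a colour for cells missing from
#' the table or outside the plotted subset (default white, the convention for
#' "all other cells") and a background colour (default black).
#'
#' @param colors named vector/list: level -> colour (hex string, colour name
#'   or RGB triple in \[0,1\]).
#' @param missing_color colour for unselected/unknown cells.
#' @param background_color colour for background pixels.
#' @return an object of class `categorical_palette`.
#' @examples
#' categorical_palette(c(beta = "#E41A1C", Tc = "#377EB8", Th = "#4DAF4A"))
#' @export
categorical_palette <- function(colors, missing_color = "white",
                                background_color = "black") {
  mat <- if (length(colors)) as_rgb_matrix(colors) else
    matrix(numeric(0), 0L, 3L)
  if (nrow(mat) && (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))) {
    stop("palette levels must be uniquely named", call. = FALSE)
  }
  structure(list(colors = mat,
                 missing_color = as_rgb(missing_color),
                 background_color = as_rgb(background_color)),
            class = "categorical_palette")
}

# Fill an RGB canvas: n x 3 matrix initialized to one colour.
flat_canvas <- function(n, color) {
  matrix(rep(color, each = n), n, 3L)
}

# Map per-object colours onto mask pixels. ids/colmat give each object's
# colour; objects not listed get `missing`, background gets `background`.
paint_objects <- function(labels, ids, colmat, missing, background) {
  n <- length(labels)
  out <- flat_canvas(n, background)
  pos <- match(labels, ids)
  hit <- which(!is.na(pos))
  out[hit, ] <- colmat[pos[hit], , drop = FALSE]
  orphan <- which(labels > 0L & is.na(pos))
  if (length(orphan)) out[orphan, ] <- flat_canvas(length(orphan), missing)
  out
}

#' Colour mask objects by a numeric feature
#'
#' Colours every object of a segmentation mask by its cell's value of a
#' marker (or numeric metadata column), interpolated along a colour ramp —
#' expression painted onto the tissue. Each value is mapped to
#' `t = clip((v - lo)/(hi - lo), 0, 1)` and `t` is interpolated
#' piecewise-linearly (in RGB space) along the ramp. The default range is the
#' min/max of the feature over the plotted cells; pass `range` for
#' cross-image comparability. A single plotted cell (or constant feature)
#' degenerates to `t = 0`, the first ramp colour.
#'
#' @param m a [segmentation_mask].
#' @param cells a [cell_table]; only rows of `image_name` are used.
#' @param image_name the image to render.
#' @param feature marker name or numeric metadata column.
#' @param ramp ordered vector/list of >= 2 colours.
#' @param range optional `c(lo, hi)`, `lo < hi`.
#' @param missing_color colour for mask objects absent from the table (or
#'   with an NA feature value).
#' @param background_color background colour.
#' @return a [rendered_image] with a `legend_entry` annotation recording the
#'   feature and its range; object ids in the table but absent from the mask
#'   produce a `warning` annotation, not an error.
#' @export
colorize_mask_by_feature <- function(m, cells, image_name, feature,
                                     ramp = c("black", "red"), range = NULL,
                                     missing_color = "white",
                                     background_color = "black") {
  ramp <- as_rgb_matrix(ramp)
  if (nrow(ramp) < 2L) stop("ramp needs at least 2 colours", call. = FALSE)
  sub <- cells[cells_for_image(cells, image_name)]
  v <- feature_values(sub, feature)
  if (n_cells(sub) && all(is.na(v))) {
    stop(sprintf("feature '%s' is NA for every plotted cell", feature),
         call. = FALSE)
  }
  if (is.null(range)) {
    range <- if (length(v)) base::range(v, na.rm = TRUE) else c(0, 1)
  } else if (length(range) != 2L || range[1L] >= range[2L]) {
    stop("range must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  t <- if (range[2L] > range[1L]) {
    clip01((v - range[1L]) / (range[2L] - range[1L]))
  } else rep(0, length(v))
  colmat <- ramp_interpolate(ifelse(is.na(t), 0, t), ramp)
  # NA feature -> treated like a missing cell
  ids <- sub$object_id[!is.na(v)]
  colmat <- colmat[!is.na(v), , drop = FALSE]
  ann <- list(annotation("legend_entry",
                         list(feature = feature, lo = range[1L], hi = range[2L])))
  absent <- setdiff(sub$object_id, object_ids(m))
  if (length(absent)) {
    ann <- c(ann, list(annotation("warning", list(
      message = "cell rows without a mask object",
      image_name = image_name, object_ids = absent))))
  }
  out <- paint_objects(as.vector(m$labels), ids, colmat,
                       as_rgb(missing_color), as_rgb(background_color))
  rendered_image(array(out, c(dim(m), 3L)), ann, m$pixel_size_um)
}

#' Colour mask objects by a categorical metadata column
#'
#' The cell-type view: objects whose level is in `subset` (all levels when
#' `subset` is `NULL`) take their palette colour; every other cell — outside
#' the subset or missing from the table — takes the palette's missing colour
#' (white by default), and background the background colour.
#'
#' @param m a [segmentation_mask].
#' @param cells a [cell_table].
#' @param image_name the image to render.
#' @param column categorical metadata column name.
#' @param palette a [categorical_palette] covering every plotted level.
#' @param subset optional set of levels to highlight.
#' @return a [rendered_image] with one `legend_entry` per plotted level, plus
#'   a `warning` annotation when mask objects are absent from the table.
#' @export
colorize_mask_by_metadata <- function(m, cells, image_name, column, palette,
                                      subset = NULL) {
  if (!column %in% names(cells$metadata)) {
    stop(sprintf("unknown metadata column '%s'", column), call. = FALSE)
  }
  sub <- cells[cells_for_image(cells, image_name)]
  lev <- as.character(sub$metadata[[column]])
  plotted <- if (is.null(subset)) unique(lev[!is.na(lev)]) else as.character(subset)
  nopal <- setdiff(plotted, rownames(palette$colors))
  if (length(nopal)) {
    stop(sprintf("palette has no colour for level(s): %s",
                 paste(nopal, collapse = ", ")), call. = FALSE)
  }
  in_subset <- !is.na(lev) & lev %in% plotted
  ids <- sub$object_id
  colmat <- flat_canvas(length(ids), palette$missing_color)
  if (any(in_subset)) {
    colmat[in_subset, ] <- palette$colors[lev[in_subset], , drop = FALSE]
  }
  ann <- lapply(plotted, function(lv) {
    annotation("legend_entry", list(level = lv,
                                    color = as.numeric(palette$colors[lv, ])))
  })
  lab <- as.vector(m$labels)
  table_ids <- ids
  orphan_objects <- setdiff(object_ids(m), table_ids)
  if (length(orphan_objects)) {
    ann <- c(ann, list(annotation("warning", list(
      message = "mask objects without a cell row",
      image_name = image_name, object_ids = orphan_objects))))
  }
  out <- paint_objects(lab, ids, colmat, palette$missing_color,
                       palette$background_color)
  rendered_image(array(out, c(dim(m), 3L)), ann, m$pixel_size_um)
}

#' Per-channel colour assignment for composites
#'
#' Describes how up to six channels blend into one RGB composite: each
#' channel gets a colour, an intensity window `range = c(lo, hi)` and a
#' background/contrast/gamma (bcg) adjustment. Per channel the pixel value is
#' multiplied by `contrast`, offset by `background`, clamped at 0, raised to
#' `gamma`, then windowed by `(u - lo)/(hi - lo)` and clipped into \[0,1\].
#'
#' @param channels character vector of 1-6 channel names.
#' @param colors one colour per channel (hex, name or RGB triple).
#' @param range `c(lo, hi)` window (recycled, or a list per channel).
#' @param contrast positive multiplier(s), recycled.
#' @param background additive offset(s), recycled.
#' @param gamma positive exponent(s), recycled.
#' @return an object of class `color_spec`.
#' @examples
#' color_spec(c("PIN", "CD4", "CD8a"), c("yellow", "blue", "red"),
#'            contrast = c(10, 8, 10))
#' @export
color_spec <- function(channels, colors, range = c(0, 1), contrast = 1,
                       background = 0, gamma = 1) {
  k <- length(channels)
  if (k < 1L) stop("at least one channel is required", call. = FALSE)
  if (anyDuplicated(channels)) stop("duplicate channels in colour spec", call. = FALSE)
  colmat <- as_rgb_matrix(colors)
  if (nrow(colmat) == 1L && k > 1L) colmat <- colmat[rep(1L, k), , drop = FALSE]
  if (nrow(colmat) != k) stop("need one colour per channel", call. = FALSE)
  ranges <- if (is.list(range)) range else rep(list(range), k)
  if (length(ranges) != k) stop("need one range per channel", call. = FALSE)
  for (r in ranges) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] >= r[2L]) {
      stop("each range must be c(lo, hi) with lo < hi", call. = FALSE)
    }
  }
  contrast <- rep_len(contrast, k)
  background <- rep_len(background, k)
  gamma <- rep_len(gamma, k)
  if (any(contrast <= 0)) stop("contrast must be positive", call. = FALSE)
  if (any(gamma <= 0)) stop("gamma must be positive", call. = FALSE)
  structure(list(channels = as.character(channels), colors = colmat,
                 ranges = ranges, contrast = contrast,
                 background = background, gamma = gamma),
            class = "color_spec")
}

#' Blend up to six channels into an RGB composite
#'
#' Each requested channel is bcg-adjusted and windowed into \[0,1\] (see
#' [color_spec()]), multiplied by its colour, and the per-channel
#' contributions are summed and clipped at 1 (additive blending, so
#' overlapping markers mix — yellow over blue reads as their sum). More than
#' six channels is a hard error: beyond six, colour collisions make the
#' composite misleading.
#'
#' @param s an [image_stack].
#' @param spec a [color_spec] naming 1-6 channels of `s`.
#' @return a [rendered_image] with one `legend_entry` per channel.
#' @export
composite_pixels <- function(s, spec) {
  if (!inherits(spec, "color_spec")) stop("spec must be a color_spec", call. = FALSE)
  k <- length(spec$channels)
  if (k > 6L) {
    stop(sprintf("composites support up to six channels, got %d", k),
         call. = FALSE)
  }
  unknown <- setdiff(spec$channels, channel_names(s))
  if (length(unknown)) {
    stop(sprintf("unknown channel(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  d <- dim(s)[1:2]
  acc <- array(0, c(d, 3L))
  for (i in seq_len(k)) {
    x <- s$pixels[, , spec$channels[i]]
    u <- pmax(x * spec$contrast[i] + spec$background[i], 0)^spec$gamma[i]
    r <- spec$ranges[[i]]
    u <- clip01((u - r[1L]) / (r[2L] - r[1L]))
    for (j in 1:3) acc[, , j] <- acc[, , j] + u * spec$colors[i, j]
  }
  ann <- lapply(seq_len(k), function(i) {
    annotation("legend_entry", list(channel = spec$channels[i],
                                    color = as.numeric(spec$colors[i, ]),
                                    lo = spec$ranges[[i]][1L],
                                    hi = spec$ranges[[i]][2L]))
  })
  rendered_image(clip01(acc), ann, s$pixel_size_um)
}

# Boundary pixels of every object: object pixels with an 8-neighbour carrying
# a different label; pixels beyond the image border count as background.
boundary_pixels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  differs <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    differs <- differs | (nb != labels)
  }
  (labels > 0L) & differs
}

# Thicken a boundary by iterative inward dilation: each pass adds object
# pixels 8-adjacent to an already-marked pixel of the same object, so the
# outline never spills outside its object.
thicken_inward <- function(labels, marked, thickness) {
  nr <- nrow(labels); nc <- ncol(labels)
  for (iter in seq_len(thickness - 1L)) {
    padL <- matrix(-1L, nr + 2L, nc + 2L)
    padL[2:(nr + 1L), 2:(nc + 1L)] <- labels
    padM <- matrix(FALSE, nr + 2L, nc + 2L)
    padM[2:(nr + 1L), 2:(nc + 1L)] <- marked
    grow <- matrix(FALSE, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      ri <- (2:(nr + 1L)) + dr; ci <- (2:(nc + 1L)) + dc
      grow <- grow | (padM[ri, ci] & padL[ri, ci] == labels)
    }
    marked <- marked | (grow & labels > 0L)
  }
  marked
}

#' Outline cells on a rendered image
#'
#' Segmentation QC overlay: the boundary pixels of each mask object
#' (8-connectivity, thickened inward) are overwritten on `base` with an
#' outline colour — a single colour, or per-cell colours from a categorical
#' metadata column when `cells`/`column` are given. Interior pixels are
#' untouched, so the underlying composite stays readable.
#'
#' @param base a [rendered_image] with the same dimensions as `m`.
#' @param m a [segmentation_mask].
#' @param cells optional [cell_table] (required with `column`).
#' @param column optional categorical metadata column colouring the outlines.
#' @param palette a [categorical_palette] used with `column`.
#' @param thickness outline thickness in pixels (>= 1).
#' @param color single outline colour used when `column` is absent.
#' @param image_name image name used to subset `cells` (default: the only
#'   image present in `cells`).
#' @return a [rendered_image].
#' @export
outline_cells <- function(base, m, cells = NULL, column = NULL,
                          palette = categorical_palette(character(0)),
                          thickness = 1L, color = "white",
                          image_name = NULL) {
  if (!identical(dim(base)[1:2], dim(m)[1:2])) {
    stop("base image and mask dimensions differ", call. = FALSE)
  }
  if (!is.numeric(thickness) || thickness < 1) {
    stop("thickness must be a positive integer", call. = FALSE)
  }
  thickness <- as.integer(thickness)
  labels <- m$labels
  marked <- boundary_pixels(labels)
  marked <- thicken_inward(labels, marked, thickness)
  if (!any(marked)) return(base)
  ids <- object_ids(m)
  ann <- base$annotations
  if (!is.null(column)) {
    if (is.null(cells)) stop("colouring outlines by metadata needs `cells`", call. = FALSE)
    if (!column %in% names(cells$metadata)) {
      stop(sprintf("unknown metadata column '%s'", column), call. = FALSE)
    }
    if (is.null(image_name)) {
      imgs <- unique(cells$image_name)
      if (length(imgs) > 1L) {
        stop("cells span several images; pass `image_name`", call. = FALSE)
      }
      image_name <- imgs
    }
    sub <- cells[cells_for_image(cells, image_name)]
    lev <- as.character(sub$metadata[[column]])
    pos <- match(ids, sub$object_id)
    colmat <- flat_canvas(length(ids), palette$missing_color)
    # levels without a palette entry fall back to the missing colour: QC
    # overlays should show every boundary, not fail on unlisted types
    known <- !is.na(pos) & !is.na(lev[pos]) &
      lev[pos] %in% rownames(palette$colors)
    known[is.na(known)] <- FALSE
    if (any(known)) {
      colmat[known, ] <- palette$colors[lev[pos[known]], , drop = FALSE]
    }
    ann <- c(ann, lapply(intersect(rownames(palette$colors), unique(lev)),
                         function(lv) annotation("legend_entry", list(
                           level = lv, color = as.numeric(palette$colors[lv, ]),
                           outline = TRUE))))
  } else {
    colmat <- flat_canvas(length(ids), as_rgb(color))
  }
  rgbmat <- matrix(base$rgb, prod(dim(m)), 3L)
  sel <- which(as.vector(marked))
  pos <- match(as.vector(labels)[sel], ids)
  rgbmat[sel, ] <- colmat[pos, , drop = FALSE]
  rendered_image(array(rgbmat, dim(base$rgb)), ann, base$pixel_size_um)
}

#' Draw a physical scale bar
#'
#' Draws a horizontal bar of `round(length_um / pixel_size_um)` pixels in the
#' bottom-left corner and records its physical length as an annotation.
#'
#' @param img a [rendered_image] whose source pixel size is known.
#' @param length_um bar length in micrometres (e.g. 20 or 100).
#' @param color bar colour.
#' @return a [rendered_image] with a `scale_bar` annotation.
#' @export
add_scale_bar <- function(img, length_um, color = "white") {
  if (is.null(img$pixel_size_um)) {
    stop("pixel size unknown; cannot draw a physical scale bar", call. = FALSE)
  }
  if (!is.numeric(length_um) || length_um <= 0) {
    stop("length_um must be positive", call. = FALSE)
  }
  d <- dim(img$rgb)
  bar_px <- as.integer(round(length_um / img$pixel_size_um))
  if (bar_px > d[2L]) {
    stop(sprintf("a %g um bar is %d px, wider than the %d px image",
                 length_um, bar_px, d[2L]), call. = FALSE)
  }
  offset <- 4L
  height <- max(1L, as.integer(round(0.01 * d[1L])))
  r1 <- max(1L, d[1L] - offset - height + 1L)
  r2 <- max(1L, d[1L] - offset)
  c1 <- min(offset + 1L, d[2L])
  c2 <- min(c1 + bar_px - 1L, d[2L])
  col <- as_rgb(color)
  rgb <- img$rgb
  for (j in 1:3) rgb[r1:r2, c1:c2, j] <- col[j]
  rendered_image(rgb, c(img$annotations, list(annotation("scale_bar", list(
    length_um = length_um, length_px = bar_px)))), img$pixel_size_um)
}

#' Tile rendered images into a grid
#'
#' Row-major layout into `ceiling(n / columns)` rows; panels are padded to
#' the largest panel size with the background colour. Deterministic: layout
#' depends only on the input order.
#'
#' @param items non-empty list of [rendered_image]s.
#' @param columns number of grid columns.
#' @param margin_px margin between and around panels, in pixels.
#' @param background margin/padding colour.
#' @return a [rendered_image].
#' @export
render_grid <- function(items, columns, margin_px = 2L, background = "black") {
  if (!length(items)) stop("no panels to lay out", call. = FALSE)
  if (!is.numeric(columns) || columns < 1) {
    stop("columns must be a positive integer", call. = FALSE)
  }
  columns <- as.integer(columns)
  margin_px <- as.integer(margin_px)
  n <- length(items)
  rows <- as.integer(ceiling(n / columns))
  pr <- max(vapply(items, function(i) dim(i$rgb)[1L], integer(1)))
  pc <- max(vapply(items, function(i) dim(i$rgb)[2L], integer(1)))
  H <- rows * pr + (rows + 1L) * margin_px
  W <- columns * pc + (columns + 1L) * margin_px
  bg <- as_rgb(background)
  canvas <- array(rep(bg, each = H * W), c(H, W, 3L))
  for (i in seq_len(n)) {
    gr <- (i - 1L) %/% columns
    gc <- (i - 1L) %% columns
    r0 <- margin_px + gr * (pr + margin_px)
    c0 <- margin_px + gc * (pc + margin_px)
    di <- dim(items[[i]]$rgb)
    canvas[r0 + seq_len(di[1L]), c0 + seq_len(di[2L]), ] <- items[[i]]$rgb
  }
  ps <- unique(unlist(lapply(items, function(i) i$pixel_size_um)))
  rendered_image(canvas,
                 list(annotation("grid", list(rows = rows, columns = columns,
                                              panel_rows = pr, panel_cols = pc,
                                              margin_px = margin_px))),
                 if (length(ps) == 1L) ps else NULL)
}
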