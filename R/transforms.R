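#' Normalize channel intensities into \[0,1\]
#'
#' Per-channel affine rescaling `v' = clip((v - lo) / (hi - lo), 0, 1)`.
#' With `method = "minmax"` the bounds are the channel minimum and maximum;
#' with `method = "percentile"` they are the `percentiles` of the channel
#' values (linear interpolation between order statistics, i.e.
#' `quantile(type = 7)` — pinned for reproducibility). Bounds are computed per
#' image (`scope = "separate"`, the default) or pooled across all images
#' (`"joint"`, for cross-image comparability). A degenerate channel
#' (`hi == lo`) maps to all zeros.
#'
#' @param collection an [image_collection] of stacks.
#' @param method `"minmax"` or `"percentile"`.
#' @param percentiles length-2 vector `c(p_lo, p_hi)`, `0 <= p_lo < p_hi <=
#'   100`; used by the percentile method. Default `c(0, 99)` suppresses the
#'   hot-pixel tail typical of ion-count data.
#' @param scope `"separate"` or `"joint"`.
#' @return an [image_collection] with every intensity in \[0,1\].
#' @export
normalize <- function(collection, method = c("minmax", "percentile"),
                      percentiles = c(0, 99),
                      scope = c("separate", "joint")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (!length(collection)) stop("empty collection", call. = FALSE)
  if (length(percentiles) != 2L || !all(is.finite(percentiles)) ||
      percentiles[1L] < 0 || percentiles[2L] > 100 ||
      percentiles[1L] >= percentiles[2L]) {
    stop("percentiles must satisfy 0 <= p_lo < p_hi <= 100", call. = FALSE)
  }
  kinds <- vapply(collection$entries, function(e) class(e)[1L], character(1))
  if (any(kinds != "image_stack")) {
    stop("normalize() operates on collections of stacks", call. = FALSE)
  }
  chans <- channel_names(collection[[1L]])
  bounds_of <- function(values) {
    if (method == "minmax") range(values)
    else stats::quantile(values, percentiles / 100, names = FALSE, type = 7)
  }
  joint_bounds <- NULL
  if (scope == "joint") {
    joint_bounds <- lapply(seq_along(chans), function(ch) {
      bounds_of(unlist(lapply(collection$entries,
                              function(s) as.vector(s$pixels[, , ch])),
                use.names = FALSE))
    })
  }
  entries <- lapply(collection$entries, function(s) {
    px <- s$pixels
    for (ch in seq_along(chans)) {
      b <- if (scope == "joint") joint_bounds[[ch]] else bounds_of(px[, , ch])
      px[, , ch] <- if (b[2L] > b[1L]) {
        clip01((px[, , ch] - b[1L]) / (b[2L] - b[1L]))
      } else 0
    }
    image_stack(px, chans, pixel_size_um = s$pixel_size_um)
  })
  image_collection(entries, collection$element_metadata)
}

#' Multiply selected channels by constant contrast factors
#'
#' Elementwise multiplication of named channels (e.g. x10 for PIN, x8 for CD4,
#' x10 for CD8a to bring faint ion counts into a visible range); unnamed
#' channels pass through untouched. No clipping happens here — clipping is a
#' render-time decision.
#'
#' @param s an [image_stack].
#' @param factors named numeric vector or list, channel name -> positive
#'   factor.
#' @return an [image_stack].
#' @export
scale_intensity <- function(s, factors) {
  factors <- unlist(factors)
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    stop("factors must be named by channel", call. = FALSE)
  }
  unknown <- setdiff(names(factors), channel_names(s))
  if (length(unknown)) {
    stop(sprintf("unknown channel(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("factors must be positive and finite", call. = FALSE)
  }
  px <- s$pixels
  for (ch in names(factors)) px[, , ch] <- px[, , ch] * factors[[ch]]
  image_stack(px, channel_names(s), pixel_size_um = s$pixel_size_um)
}

#' Measure per-cell mean intensities from a stack and a mask
#'
#' The measurement step of the mask/stack pairing: for every object id in the
#' mask, the arithmetic mean of each channel over that object's pixels (the
#' "mean ion count per marker" readout), plus morphology metadata: `area_px`
#' (pixel count) and the centroid (`centroid_row`, `centroid_col`; mean
#' member-pixel position, 0-based).
#'
#' @param s an [image_stack].
#' @param m a [segmentation_mask] with the same row/col dimensions.
#' @param image_name image name to stamp on the resulting rows.
#' @return a [cell_table] with one row per mask object.
#' @export
measure_cells <- function(s, m, image_name = "image") {
  if (!identical(dim(s)[1:2], dim(m)[1:2])) {
    stop(sprintf("dimension mismatch: stack %dx%d vs mask %dx%d",
                 dim(s)[1L], dim(s)[2L], dim(m)[1L], dim(m)[2L]), call. = FALSE)
  }
  lab <- as.vector(m$labels)
  keep <- lab > 0L
  ids <- sort(unique(lab[keep]))
  chans <- channel_names(s)
  if (!length(ids)) {
    return(cell_table(character(0), integer(0),
                      matrix(0, 0, length(chans), dimnames = list(NULL, chans)),
                      data.frame(area_px = integer(0),
                                 centroid_row = numeric(0),
                                 centroid_col = numeric(0))))
  }
  f <- factor(lab[keep], levels = ids)
  area <- tabulate(f, nbins = length(ids))
  expr <- vapply(seq_along(chans), function(ch) {
    rowsum(as.vector(s$pixels[, , ch])[keep], f)[, 1L] / area
  }, numeric(length(ids)))
  expr <- matrix(expr, length(ids), length(chans), dimnames = list(NULL, chans))
  ri <- as.vector(row(m$labels))[keep] - 1
  ci <- as.vector(col(m$labels))[keep] - 1
  md <- data.frame(area_px = area,
                   centroid_row = rowsum(ri, f)[, 1L] / area,
                   centroid_col = rowsum(ci, f)[, 1L] / area)
  cell_table(image_name, ids, expr, md)
}

#' Cell density of selected types on one image
#'
#' Count of the image's cells whose `type_column` value falls in `types`,
#' divided by the full image area. Reported per mm^2 when the mask knows its
#' pixel size, per megapixel otherwise. The denominator is the whole image,
#' not a tissue area.
#'
#' @param cells a [cell_table].
#' @param image_name the image to score.
#' @param mask that image's [segmentation_mask] (supplies area and pixel size).
#' @param types set of `type_column` values to count.
#' @param type_column name of the metadata column holding the types.
#' @return density (scalar), with attribute `unit` (`"per_mm2"` or
#'   `"per_megapixel"`).
#' @export
cell_density <- function(cells, image_name, mask, types,
                         type_column = "cell_type") {
  if (!type_column %in% names(cells$metadata)) {
    stop(sprintf("unknown type column '%s'", type_column), call. = FALSE)
  }
  idx <- cells_for_image(cells, image_name)
  count <- sum(as.character(cells$metadata[[type_column]][idx]) %in%
                 as.character(types))
  area_px <- prod(dim(mask)[1:2])
  if (!is.null(mask$pixel_size_um)) {
    d <- count / (area_px * mask$pixel_size_um^2 / 1e6)
    attr(d, "unit") <- "per_mm2"
  } else {
    d <- count / area_px * 1e6
    attr(d, "unit") <- "per_megapixel"
  }
  d
}

#' Rank images by cell-type density
#'
#' The image-selection step: per group (a column of the mask collection's
#' `element_metadata`, e.g. disease condition; one global group when absent),
#' images are ordered by descending density of the requested types and the
#' densest image is flagged `selected`. Ties break by ascending image name so
#' the output is deterministic.
#'
#' @param cells a [cell_table].
#' @param masks an [image_collection] of masks covering every image in
#'   `cells`.
#' @param types set of type values, e.g. `c("Tc", "Th")`.
#' @param type_column metadata column holding the types.
#' @param group_column optional `element_metadata` column defining groups;
#'   images with a missing value land in group `"NA"` (with a warning).
#' @return a `density_ranking` data.frame: `image_name`, `group`, `n_cells`,
#'   `area_px`, `density`, `unit`, `rank`, `selected`.
#' @export
rank_images <- function(cells, masks, types, type_column = "cell_type",
                        group_column = NULL) {
  nms <- names(masks)
  missing_masks <- setdiff(unique(cells$image_name), nms)
  if (length(missing_masks)) {
    stop(sprintf("no mask for image(s): %s",
                 paste(missing_masks, collapse = ", ")), call. = FALSE)
  }
  group <- if (is.null(group_column)) {
    rep("all", length(nms))
  } else {
    if (!group_column %in% names(masks$element_metadata)) {
      stop(sprintf("unknown group column '%s'", group_column), call. = FALSE)
    }
    as.character(masks$element_metadata[[group_column]])
  }
  if (anyNA(group)) {
    warning(sprintf("image(s) without a group value placed in group \"NA\": %s",
                    paste(nms[is.na(group)], collapse = ", ")))
    group[is.na(group)] <- "NA"
  }
  rows <- lapply(seq_along(nms), function(i) {
    mask <- masks[[i]]
    idx <- cells_for_image(cells, nms[i])
    n <- sum(as.character(cells$metadata[[type_column]][idx]) %in%
               as.character(types))
    d <- cell_density(cells, nms[i], mask, types, type_column)
    data.frame(image_name = nms[i], group = group[i], n_cells = n,
               area_px = prod(dim(mask)[1:2]), density = as.numeric(d),
               unit = attr(d, "unit"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, -out$density, out$image_name), ]
  out$rank <- stats::ave(out$density, out$group,
                         FUN = function(x) seq_along(x))
  out$selected <- out$rank == 1
  rownames(out) <- NULL
  class(out) <- c("density_ranking", "data.frame")
  out
}

#' @export
print.density_ranking <- function(x, ...) {
  cat(sprintf("<density_ranking> %d image(s) in %d group(s); densities in %s\n",
              nrow(x), length(unique(x$group)), x$unit[1L]))
  print.data.frame(x, digits = 4)
  invisible(x)
}
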