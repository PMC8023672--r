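#' Multi-channel image stack
#'
#' An `image_stack` holds co-registered single-marker intensity planes for one
#' tissue region: a rows x cols x channels array of finite, non-negative
#' intensities (arbitrary units, e.g. ion counts) with ordered, unique channel
#' names. The coordinate convention throughout the package is (row, col),
#' 0-based, origin at the top-left, matching raster storage order.
#'
#' @param pixels numeric matrix (single channel) or 3-D array
#'   (rows x cols x channels) of finite values >= 0.
#' @param channel_names character vector of unique, non-empty channel (marker)
#'   names, one per plane.
#' @param pixel_size_um optional positive scalar: physical edge length of one
#'   pixel in micrometres.
#' @return an object of class `image_stack`.
#' @examples
#' s <- image_stack(array(runif(32), c(4, 4, 2)), c("PIN", "CD4"))
#' channel_names(s)
#' @export
image_stack <- function(pixels, channel_names, pixel_size_um = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("pixels must be a matrix or a rows x cols x channels array", call. = FALSE)
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(pixels)[3L]) {
    stop(sprintf("got %d channel names for %d planes",
                 length(channel_names), dim(pixels)[3L]), call. = FALSE)
  }
  if (anyDuplicated(channel_names) || any(!nzchar(channel_names))) {
    stop("channel names must be unique and non-empty", call. = FALSE)
  }
  if (any(!is.finite(pixels))) stop("intensities must be finite", call. = FALSE)
  if (any(pixels < 0)) stop("intensities must be >= 0", call. = FALSE)
  check_pixel_size(pixel_size_um)
  storage.mode(pixels) <- "double"
  dimnames(pixels) <- list(NULL, NULL, channel_names)
  structure(list(pixels = pixels, channel_names = channel_names,
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

check_pixel_size <- function(pixel_size_um) {
  if (!is.null(pixel_size_um) &&
      (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
       !is.finite(pixel_size_um) || pixel_size_um <= 0)) {
    stop("pixel_size_um must be a positive scalar", call. = FALSE)
  }
  invisible(pixel_size_um)
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
channel_names <- function(x) x$channel_names

#' @export
dim.image_stack <- function(x) dim(x$pixels)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d x %d px, %d channel(s): %s\n", d[1], d[2], d[3],
              paste(x$channel_names, collapse = ", ")))
  if (!is.null(x$pixel_size_um)) cat(sprintf("  pixel size: %g um\n", x$pixel_size_um))
  invisible(x)
}

#' Integer-labelled segmentation mask
#'
#' A single-channel image in which each positive integer value labels the
#' pixels of one cell object and 0 denotes background. Object ids need not be
#' consecutive.
#'
#' @param labels numeric or integer matrix of non-negative, integer-valued
#'   labels.
#' @param pixel_size_um optional positive scalar, micrometres per pixel edge.
#' @return an object of class `segmentation_mask`.
#' @examples
#' m <- segmentation_mask(matrix(c(0, 1, 1, 2), 2, 2))
#' object_ids(m)
#' @export
segmentation_mask <- function(labels, pixel_size_um = NULL) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  if (any(!is.finite(labels))) stop("labels must be finite", call. = FALSE)
  frac <- labels != floor(labels)
  if (any(frac)) {
    bad <- which(frac, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer label %g at pixel (row=%d, col=%d)",
                 labels[bad[1L], bad[2L]], bad[1L] - 1L, bad[2L] - 1L),
         call. = FALSE)
  }
  if (any(labels < 0)) {
    bad <- which(labels < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative label at pixel (row=%d, col=%d)",
                 bad[1L] - 1L, bad[2L] - 1L), call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  check_pixel_size(pixel_size_um)
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "segmentation_mask")
}

#' @rdname segmentation_mask
#' @param m a `segmentation_mask`.
#' @return `object_ids()`: sorted integer vector of the positive labels present.
#' @export
object_ids <- function(m) {
  ids <- sort(unique(as.vector(m$labels)))
  ids[ids > 0L]
}

#' @export
dim.segmentation_mask <- function(x) dim(x$labels)

#' @export
print.segmentation_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<segmentation_mask> %d x %d px, %d object(s)\n",
              d[1], d[2], length(object_ids(x))))
  invisible(x)
}

#' Ordered, named collection of images
#'
#' The shared multi-image container: an ordered mapping from unique image
#' names to entries that are either all `image_stack`s or all
#' `segmentation_mask`s, with a per-image metadata table (e.g. condition,
#' donor). Stacks in one collection must share identical channel names in
#' identical order.
#'
#' @param entries named list of `image_stack` or `segmentation_mask` objects.
#' @param element_metadata optional data.frame with one row per entry
#'   (matched by position; an `image_name` column is added/overwritten).
#' @param validate if `TRUE` (default) invariants are checked and violations
#'   raise an error; `FALSE` builds the object unchecked so that
#'   [validate_collection()] can report on it.
#' @return an object of class `image_collection`.
#' @seealso [validate_collection()], [pair_by_name()]
#' @export
image_collection <- function(entries, element_metadata = NULL, validate = TRUE) {
  if (!is.list(entries)) stop("entries must be a named list", call. = FALSE)
  nms <- names(entries)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every entry must have a non-empty image name", call. = FALSE)
  }
  if (is.null(element_metadata)) {
    element_metadata <- data.frame(image_name = nms, stringsAsFactors = FALSE)
  } else {
    element_metadata <- as.data.frame(element_metadata)
    element_metadata$image_name <- nms
  }
  rownames(element_metadata) <- NULL
  obj <- structure(list(entries = entries, element_metadata = element_metadata),
                   class = "image_collection")
  if (validate) {
    bad <- validate_collection(obj)
    if (length(bad)) {
      stop(paste(c("invalid image collection:", bad), collapse = "\n  "),
           call. = FALSE)
    }
  }
  obj
}

#' Report violations of the image-collection invariants
#'
#' A reporting (never failing) check: duplicate image names, mixed entry kinds
#' (stacks and masks in one collection), channel-name/order mismatches across
#' stacks, and metadata row-count mismatch.
#'
#' @param x an `image_collection` (possibly built with `validate = FALSE`).
#' @return character vector of violation messages; `character(0)` iff valid.
#' @export
validate_collection <- function(x) {
  out <- character(0)
  nms <- names(x$entries)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    out <- c(out, sprintf("duplicate image name(s): %s", paste(dup, collapse = ", ")))
  }
  kinds <- vapply(x$entries, function(e) class(e)[1L], character(1))
  known <- kinds %in% c("image_stack", "segmentation_mask")
  if (any(!known)) {
    out <- c(out, sprintf("entries of unsupported class: %s",
                          paste(unique(kinds[!known]), collapse = ", ")))
  }
  if (length(unique(kinds[known])) > 1L) {
    out <- c(out, "mixed kinds: collection holds both stacks and masks")
  }
  stacks <- x$entries[kinds == "image_stack"]
  if (length(stacks) > 1L) {
    ref <- channel_names(stacks[[1L]])
    for (i in seq_along(stacks)[-1L]) {
      if (!identical(channel_names(stacks[[i]]), ref)) {
        out <- c(out, sprintf(
          "channel names of '%s' differ from '%s' (names and order must match)",
          names(stacks)[i], names(stacks)[1L]))
      }
    }
  }
  if (nrow(x$element_metadata) != length(x$entries)) {
    out <- c(out, "element_metadata rows do not correspond 1:1 to entries")
  }
  out
}

#' @export
length.image_collection <- function(x) length(x$entries)

#' @export
names.image_collection <- function(x) names(x$entries)

#' @export
`[[.image_collection` <- function(x, i) x$entries[[i]]

#' @export
`[.image_collection` <- function(x, i) {
  if (is.character(i)) i <- match(i, names(x$entries))
  image_collection(x$entries[i], x$element_metadata[i, , drop = FALSE],
                   validate = FALSE)
}

#' @export
c.image_collection <- function(...) {
  parts <- list(...)
  entries <- do.call(c, lapply(parts, function(p) p$entries))
  md <- do.call(rbind, lapply(parts, function(p) {
    m <- p$element_metadata
    for (col in setdiff(unique(unlist(lapply(parts, function(q) names(q$element_metadata)))),
                        names(m))) m[[col]] <- NA
    m
  }))
  image_collection(entries, md)
}

#' @export
print.image_collection <- function(x, ...) {
  kinds <- unique(vapply(x$entries, function(e) class(e)[1L], character(1)))
  cat(sprintf("<image_collection> %d image(s) [%s]\n", length(x$entries),
              paste(kinds, collapse = "+")))
  cat(" ", paste(utils::head(names(x$entries), 8), collapse = ", "),
      if (length(x$entries) > 8) "..." else "", "\n")
  invisible(x)
}

#' Per-cell expression and metadata table
#'
#' Rows are cells, keyed by (`image_name`, `object_id`); `expression` is a
#' cells x markers matrix of finite values, and `metadata` holds per-cell
#' categorical or numeric columns (e.g. `cell_type`, `area_px`).
#'
#' @param image_name character vector, one entry per cell.
#' @param object_id positive integer vector, one entry per cell; the pair
#'   (`image_name`, `object_id`) must be unique.
#' @param expression numeric matrix, one row per cell, with unique column
#'   (marker) names.
#' @param metadata optional data.frame of per-cell columns.
#' @return an object of class `cell_table`.
#' @examples
#' ct <- cell_table("a", 1:2, matrix(1:4, 2, 2, dimnames = list(NULL, c("PIN", "CD4"))))
#' marker_names(ct)
#' @export
cell_table <- function(image_name, object_id, expression, metadata = NULL) {
  n <- length(object_id)
  image_name <- rep_len(as.character(image_name), n)
  if (!is.matrix(expression)) expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  if (nrow(expression) != n) {
    stop("expression must have one row per cell", call. = FALSE)
  }
  mk <- colnames(expression)
  if (is.null(mk) || anyDuplicated(mk) || any(!nzchar(mk))) {
    stop("expression columns must carry unique, non-empty marker names", call. = FALSE)
  }
  if (any(!is.finite(expression))) stop("expression values must be finite", call. = FALSE)
  if (anyNA(object_id) || any(object_id < 1) || any(object_id != floor(object_id))) {
    stop("object_id must be positive integers", call. = FALSE)
  }
  object_id <- as.integer(object_id)
  key <- paste(image_name, object_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (image_name, object_id) pairs", call. = FALSE)
  }
  if (is.null(metadata)) {
    metadata <- data.frame(row.names = seq_len(n))
  } else {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != n) stop("metadata must have one row per cell", call. = FALSE)
    rownames(metadata) <- NULL
  }
  structure(list(image_name = image_name, object_id = object_id,
                 expression = expression, metadata = metadata),
            class = "cell_table")
}

#' @rdname cell_table
#' @param x a `cell_table`.
#' @export
marker_names <- function(x) colnames(x$expression)

#' @rdname cell_table
#' @export
n_cells <- function(x) length(x$object_id)

#' @export
`[.cell_table` <- function(x, i, ...) {
  cell_table(x$image_name[i], x$object_id[i],
             x$expression[i, , drop = FALSE],
             x$metadata[i, , drop = FALSE])
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cell(s) x %d marker(s) across %d image(s)\n",
              n_cells(x), ncol(x$expression), length(unique(x$image_name))))
  if (ncol(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

# Extract the numeric value of `feature` (marker column, else numeric metadata
# column) for every cell.
feature_values <- function(cells, feature) {
  if (feature %in% marker_names(cells)) {
    return(cells$expression[, feature])
  }
  if (feature %in% names(cells$metadata)) {
    v <- cells$metadata[[feature]]
    if (!is.numeric(v)) {
      stop(sprintf("metadata column '%s' is not numeric", feature), call. = FALSE)
    }
    return(v)
  }
  stop(sprintf("feature '%s' is neither a marker nor a metadata column", feature),
       call. = FALSE)
}

# Row indices of the cells belonging to one image.
cells_for_image <- function(cells, image_name) {
  which(cells$image_name == image_name)
}

#' Pair stacks, masks and cell rows by image name
#'
#' Matches entries of an image collection of stacks against one of masks and a
#' cell table by exact image-name equality, the cross-container link the whole
#' toolkit relies on. Names present in only one container are reported, not
#' dropped silently. Cell rows whose object id is absent from the paired mask
#' are tolerated here but surfaced in the report (rendering decides their
#' fate).
#'
#' @param images `image_collection` of stacks, or `NULL`.
#' @param masks `image_collection` of masks, or `NULL`.
#' @param cells optional `cell_table`; its image names must exist in `masks`
#'   (or in `images` when no masks are given).
#' @return a `paired_set`: list with `pairs` (per image name: `stack`, `mask`,
#'   `cells`), `images_only`, `masks_only`, and `unmatched_objects` (per image,
#'   object ids referenced by cells but missing from the mask).
#' @export
pair_by_name <- function(images = NULL, masks = NULL, cells = NULL) {
  img_names <- if (is.null(images)) character(0) else names(images)
  msk_names <- if (is.null(masks)) character(0) else names(masks)
  shared <- intersect(img_names, msk_names)
  for (nm in shared) {
    ds <- dim(images[[nm]])[1:2]
    dm <- dim(masks[[nm]])[1:2]
    if (!identical(ds, dm)) {
      stop(sprintf("image '%s': entries are %dx%d and %dx%d (dimension mismatch)",
                   nm, ds[1], ds[2], dm[1], dm[2]), call. = FALSE)
    }
  }
  ref_names <- if (length(msk_names)) msk_names else img_names
  if (!is.null(cells)) {
    missing_ref <- setdiff(unique(cells$image_name), ref_names)
    if (length(missing_ref)) {
      stop(sprintf("cell rows reference image name(s) absent from the collections: %s",
                   paste(missing_ref, collapse = ", ")), call. = FALSE)
    }
  }
  all_names <- union(img_names, msk_names)
  pairs <- list()
  unmatched <- list()
  for (nm in all_names) {
    # slot entries by what they are, not by which argument carried them, so
    # that swapping the two collections only swaps the orphan report
    got <- c(if (nm %in% img_names) list(images[[nm]]),
             if (nm %in% msk_names) list(masks[[nm]]))
    stack <- Filter(function(e) inherits(e, "image_stack"), got)
    mask <- Filter(function(e) inherits(e, "segmentation_mask"), got)
    stack <- if (length(stack)) stack[[1L]] else NULL
    mask <- if (length(mask)) mask[[1L]] else NULL
    sub <- if (is.null(cells)) NULL else cells[cells_for_image(cells, nm)]
    pairs[[nm]] <- list(stack = stack, mask = mask, cells = sub)
    if (!is.null(mask) && !is.null(sub) && n_cells(sub)) {
      extra <- setdiff(sub$object_id, object_ids(mask))
      if (length(extra)) unmatched[[nm]] <- extra
    }
  }
  structure(list(pairs = pairs,
                 images_only = setdiff(img_names, msk_names),
                 masks_only = setdiff(msk_names, img_names),
                 unmatched_objects = unmatched),
            class = "paired_set")
}

#' @export
print.paired_set <- function(x, ...) {
  cat(sprintf("<paired_set> %d image name(s); %d stack-only, %d mask-only\n",
              length(x$pairs), length(x$images_only), length(x$masks_only)))
  if (length(x$unmatched_objects)) {
    cat(sprintf("  %d image(s) with cell rows lacking a mask object\n",
                length(x$unmatched_objects)))
  }
  invisible(x)
}
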