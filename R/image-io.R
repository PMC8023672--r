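#' Read a multi-channel TIFF stack
#'
#' Reads a plane-per-channel (page-ordered) TIFF into an [image_stack].
#' Interleaved RGB TIFFs are rejected: IMC-style tooling writes one page per
#' marker. Integer pixel data is read unscaled; pass `on_read_scale` to divide
#' raw values on ingest (e.g. `65535` for 16-bit data meant to land in
#' \[0,1\]).
#'
#' @param path path to a TIFF file.
#' @param channel_names character vector naming the planes, in stored order.
#' @param on_read_scale optional positive divisor applied to every raw value.
#' @param pixel_size_um optional positive scalar, micrometres per pixel edge.
#' @return an [image_stack].
#' @export
read_stack <- function(path, channel_names, on_read_scale = NULL,
                       pixel_size_um = NULL) {
  pages <- read_tiff_pages(path)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop(sprintf("'%s': interleaved multi-sample TIFF; stacks must be one page per channel",
                 basename(path)), call. = FALSE)
  }
  if (length(pages) != length(channel_names)) {
    stop(sprintf("'%s' holds %d plane(s) but %d channel name(s) were given",
                 basename(path), length(pages), length(channel_names)),
         call. = FALSE)
  }
  px <- array(unlist(pages, use.names = FALSE),
              c(dim(pages[[1L]]), length(pages)))
  if (!is.null(on_read_scale)) {
    if (!is.numeric(on_read_scale) || on_read_scale <= 0) {
      stop("on_read_scale must be a positive number", call. = FALSE)
    }
    px <- px / on_read_scale
  }
  if (any(!is.finite(px)) || any(px < 0)) {
    stop(sprintf("'%s': negative or non-finite pixel values", basename(path)),
         call. = FALSE)
  }
  image_stack(px, channel_names, pixel_size_um = pixel_size_um)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  # 32 bits/sample means float data (the only 32-bit layout the TIFF dialect
  # here uses); float pages are read natively, integer pages unscaled
  probe <- tiff::readTIFF(path, info = TRUE)
  is_float <- identical(attr(probe, "bits.per.sample"), 32L)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  if (!is.list(pages)) pages <- list(pages)
  pages
}

#' Write a stack as a multi-page float TIFF
#'
#' Stores one 32-bit float page per channel. The float TIFF codec stores
#' values in \[0,1\], so intensities outside that range must be brought into
#' it with `scale` (a divisor); reading back with
#' `read_stack(on_read_scale = 1/scale)` recovers the original values to
#' 32-bit float precision.
#'
#' @param s an [image_stack].
#' @param path output file path.
#' @param scale optional positive divisor applied before writing.
#' @return `path`, invisibly.
#' @export
write_stack <- function(s, path, scale = NULL) {
  px <- s$pixels
  if (!is.null(scale)) px <- px / scale
  if (any(px > 1)) {
    stop("float TIFF stores values in [0,1]; pass a suitable `scale` divisor",
         call. = FALSE)
  }
  pages <- lapply(seq_len(dim(px)[3L]), function(i) px[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a segmentation mask TIFF
#'
#' Reads a single-page TIFF of integer labels. Values are never rescaled:
#' rescaling a label image corrupts object ids. Multi-page files and values
#' with a fractional part are errors.
#'
#' @param path path to a single-page TIFF.
#' @param pixel_size_um optional positive scalar, micrometres per pixel edge.
#' @return a [segmentation_mask].
#' @export
read_mask <- function(path, pixel_size_um = NULL) {
  pages <- read_tiff_pages(path)
  if (length(pages) != 1L) {
    stop(sprintf("'%s': masks must be single-plane, got %d planes",
                 basename(path), length(pages)), call. = FALSE)
  }
  plane <- pages[[1L]]
  if (length(dim(plane)) != 2L) {
    stop(sprintf("'%s': masks must be single-channel", basename(path)), call. = FALSE)
  }
  segmentation_mask(plane, pixel_size_um = pixel_size_um)
}

#' Write a segmentation mask as a 16-bit TIFF
#'
#' @param m a [segmentation_mask] with labels <= 65535.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path) {
  if (max(m$labels) > 65535L) {
    stop("16-bit mask TIFF cannot store labels > 65535", call. = FALSE)
  }
  tiff::writeTIFF(m$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Load a directory of TIFFs into an image collection
#'
#' One entry per matched file; the image name is the filename stem up to the
#' first extension (collisions are an error, never silently suffixed); entries
#' are sorted by name and `element_metadata` records file provenance.
#'
#' @param dir directory to scan (ignored when `files` is given).
#' @param pattern regular expression filtering filenames.
#' @param kind `"stack"` or `"mask"`.
#' @param channel_names required for stacks: names for the stored planes.
#' @param on_read_scale optional divisor for stack intensities, see
#'   [read_stack()].
#' @param pixel_size_um optional micrometres per pixel, applied to all entries.
#' @param files explicit file list overriding `dir`/`pattern`.
#' @return an [image_collection].
#' @export
load_collection <- function(dir = ".", pattern = NULL,
                            kind = c("stack", "mask"),
                            channel_names = NULL, on_read_scale = NULL,
                            pixel_size_um = NULL, files = NULL) {
  kind <- match.arg(kind)
  if (is.null(files)) {
    files <- list.files(dir, pattern = pattern, full.names = TRUE)
  }
  if (!length(files)) {
    stop("no files matched the load specification", call. = FALSE)
  }
  stems <- sub("\\..*$", "", basename(files))
  files <- files[order(stems)]
  stems <- sort(stems)
  dup <- unique(stems[duplicated(stems)])
  if (length(dup)) {
    stop(sprintf("duplicate image name(s) from filename stems: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  entries <- if (kind == "mask") {
    lapply(files, read_mask, pixel_size_um = pixel_size_um)
  } else {
    if (is.null(channel_names)) {
      stop("channel_names are required to load stacks", call. = FALSE)
    }
    planes <- vapply(files, function(f) length(read_tiff_pages(f)), integer(1))
    if (length(unique(planes)) > 1L) {
      stop("mixed plane counts across stack files", call. = FALSE)
    }
    lapply(files, read_stack, channel_names = channel_names,
           on_read_scale = on_read_scale, pixel_size_um = pixel_size_um)
  }
  names(entries) <- stems
  image_collection(entries,
                   data.frame(image_name = stems, file = files,
                              stringsAsFactors = FALSE))
}

#' Read a cell table from CSV
#'
#' Comma-separated, UTF-8, header required, "." decimal. Marker columns are
#' parsed as finite numbers; character metadata columns become factors with
#' their observed levels.
#'
#' @param path CSV file path.
#' @param marker_cols character vector of expression column names.
#' @param metadata_cols character vector of metadata column names (default:
#'   every non-key, non-marker column).
#' @param key_cols the two key columns, image name then object id.
#' @return a [cell_table].
#' @export
read_cell_table <- function(path, marker_cols, metadata_cols = NULL,
                            key_cols = c("image_name", "object_id")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  need <- c(key_cols, marker_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(metadata_cols)) {
    metadata_cols <- setdiff(names(df), c(key_cols, marker_cols))
  }
  expr <- matrix(NA_real_, nrow(df), length(marker_cols),
                 dimnames = list(NULL, marker_cols))
  for (mc in marker_cols) {
    v <- df[[mc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric expression value in column '%s', row %d",
                     mc, bad[1L]), call. = FALSE)
      }
      v <- vn
    }
    expr[, mc] <- v
  }
  md <- df[, metadata_cols, drop = FALSE]
  for (col in names(md)) if (is.character(md[[col]])) md[[col]] <- factor(md[[col]])
  cell_table(df[[key_cols[1L]]], df[[key_cols[2L]]], expr, md)
}

#' Export a cell table to CSV
#'
#' Writes keys, expression and metadata columns so that
#' [read_cell_table()] round-trips the table: keys exactly, expression to
#' better than 1e-9 relative, factor metadata with its observed levels.
#'
#' @param t a [cell_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_cells <- function(t, path) {
  df <- data.frame(image_name = t$image_name, object_id = t$object_id,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (mk in marker_names(t)) df[[mk]] <- t$expression[, mk]
  for (col in names(t$metadata)) df[[col]] <- t$metadata[[col]]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write '%s': %s", path,
                                conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Write a rendered image as an 8-bit PNG
#'
#' Values are quantized to 8 bits per channel (`round(v * 255)`); re-reading
#' therefore reproduces each channel to within 1/255. Out-of-range values are
#' an error — clipping is the caller's explicit decision.
#'
#' @param img a [rendered_image].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_rendered <- function(img, path) {
  rgb <- img$rgb
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 1)) {
    stop("rendered values must lie in [0,1]; clip before writing", call. = FALSE)
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' @rdname write_rendered
#' @return `read_rendered()`: the rows x cols x 3 array stored in a PNG.
#' @export
read_rendered <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  arr
}
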