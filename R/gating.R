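#' Interval gate on one marker
#'
#' A closed-interval filter: a cell passes iff
#' `lower <= expression[, marker] <= upper`. Bounds are inclusive — values
#' exactly at a threshold are kept, the convention that keeps ties after
#' transform-induced clumping well defined.
#'
#' @param marker marker name.
#' @param lower lower bound (default `-Inf`).
#' @param upper upper bound (default `Inf`).
#' @return an object of class `gate`.
#' @examples
#' gate("CD4", lower = 0.5)
#' @export
gate <- function(marker, lower = -Inf, upper = Inf) {
  if (!is.character(marker) || length(marker) != 1L || !nzchar(marker)) {
    stop("marker must be a single non-empty string", call. = FALSE)
  }
  if (is.na(lower) || is.na(upper) || lower > upper) {
    stop("gate bounds must satisfy lower <= upper", call. = FALSE)
  }
  structure(list(marker = marker, lower = as.numeric(lower),
                 upper = as.numeric(upper)), class = "gate")
}

#' @export
print.gate <- function(x, ...) {
  cat(sprintf("<gate> %s in [%g, %g]\n", x$marker, x$lower, x$upper))
  invisible(x)
}

#' Ordered sequence of gates defining a population
#'
#' Hierarchical gating applies the gates in order, each filtering the
#' previous survivors; markers may repeat (tightening an earlier gate). More
#' than 24 gates triggers a warning — 24 markers is the practical ceiling of
#' interactive gating panels, not a mathematical limit — but the sequence
#' still runs.
#'
#' @param gates a list of [gate]s (or several gates as `...`).
#' @param label name for the resulting population.
#' @return an object of class `gate_sequence`.
#' @examples
#' gate_sequence(list(gate("CD45", 1), gate("CD8a", 2)), label = "Tc")
#' @export
gate_sequence <- function(gates = list(), label = "selection") {
  if (inherits(gates, "gate")) gates <- list(gates)
  if (!all(vapply(gates, inherits, logical(1), "gate"))) {
    stop("gates must be a list of gate objects", call. = FALSE)
  }
  if (length(gates) > 24L) {
    warning(sprintf("gating on %d markers; panels beyond 24 markers are unwieldy to verify",
                    length(gates)))
  }
  structure(list(gates = gates, label = as.character(label)),
            class = "gate_sequence")
}

#' @export
length.gate_sequence <- function(x) length(x$gates)

#' @export
print.gate_sequence <- function(x, ...) {
  cat(sprintf("<gate_sequence> '%s', %d gate(s)\n", x$label, length(x$gates)))
  for (g in x$gates) cat(sprintf("  %s in [%g, %g]\n", g$marker, g$lower, g$upper))
  invisible(x)
}

#' Apply a gate sequence to a cell table
#'
#' Filters cells gate by gate, recording the survivor count after each gate
#' (non-increasing by construction). The final subset keeps the input row
#' order.
#'
#' @param cells a [cell_table].
#' @param gs a [gate_sequence]; every gate marker must exist in `cells`.
#' @return a `selection`: list with `cells` (the surviving subset),
#'   `sequence` (the applied gates) and `counts` (survivors after each gate).
#' @export
apply_gate_sequence <- function(cells, gs) {
  if (!inherits(gs, "gate_sequence")) gs <- gate_sequence(gs)
  mks <- vapply(gs$gates, function(g) g$marker, character(1))
  unknown <- setdiff(mks, marker_names(cells))
  if (length(unknown)) {
    stop(sprintf("unknown marker(s) in gate sequence: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  keep <- seq_len(n_cells(cells))
  counts <- integer(0)
  for (g in gs$gates) {
    v <- cells$expression[keep, g$marker]
    keep <- keep[v >= g$lower & v <= g$upper]
    counts <- c(counts, length(keep))
  }
  names(counts) <- if (length(mks)) mks else NULL
  structure(list(cells = cells[keep], sequence = gs, counts = counts),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection> '%s': %d cell(s) kept\n",
              x$sequence$label, n_cells(x$cells)))
  if (length(x$counts)) {
    for (i in seq_along(x$counts)) {
      cat(sprintf("  after gate %d (%s): %d\n", i, names(x$counts)[i],
                  x$counts[i]))
    }
  }
  invisible(x)
}

#' Render a gated selection on its images
#'
#' Image-backed verification of a gate: selected cells are shown either as
#' coloured objects on the segmentation masks (`mode = "mask_objects"`) or as
#' outlines on channel composites (`mode = "outlines"`, which requires
#' stacks). Only images containing at least one selected cell are rendered,
#' in collection order; an empty selection returns an empty list with a
#' warning.
#'
#' @param sel a `selection` from [apply_gate_sequence()].
#' @param masks an [image_collection] of masks.
#' @param stacks optional [image_collection] of stacks (required for
#'   outlines).
#' @param mode `"mask_objects"` or `"outlines"`.
#' @param palette palette for selected objects (default: selected cells red,
#'   all other cells white on black).
#' @param spec optional [color_spec] for the composite underlay; default: the
#'   first (up to six) channels on a standard colour cycle, windowed to each
#'   channel's observed maximum.
#' @param color outline colour for `mode = "outlines"`.
#' @param thickness outline thickness in pixels.
#' @return named list of [rendered_image]s.
#' @export
visualize_selection <- function(sel, masks, stacks = NULL,
                                mode = c("mask_objects", "outlines"),
                                palette = categorical_palette(c(yes = "red")),
                                spec = NULL, color = "white", thickness = 1L) {
  mode <- match.arg(mode)
  if (mode == "outlines" && is.null(stacks)) {
    stop("outline visualization needs the stacks the outlines are drawn on",
         call. = FALSE)
  }
  imgs <- intersect(names(masks), unique(sel$cells$image_name))
  if (!length(imgs)) {
    warning("selection is empty on every image; nothing to render")
    return(list())
  }
  out <- list()
  for (nm in imgs) {
    mask <- masks[[nm]]
    sub <- sel$cells[cells_for_image(sel$cells, nm)]
    if (mode == "mask_objects") {
      tagged <- cell_table(sub$image_name, sub$object_id, sub$expression,
                           data.frame(selected = factor(rep("yes", n_cells(sub)),
                                                        levels = "yes")))
      out[[nm]] <- colorize_mask_by_metadata(mask, tagged, nm, "selected",
                                             palette)
    } else {
      stack <- stacks[[nm]]
      if (is.null(stack)) {
        stop(sprintf("no stack named '%s' for outline rendering", nm),
             call. = FALSE)
      }
      sp <- if (is.null(spec)) default_color_spec(stack) else spec
      base <- composite_pixels(stack, sp)
      lab <- mask$labels
      lab[!(lab %in% sub$object_id)] <- 0L
      sel_mask <- segmentation_mask(lab, mask$pixel_size_um)
      out[[nm]] <- outline_cells(base, sel_mask, color = color,
                                 thickness = thickness)
    }
  }
  out
}

# Fallback composite spec: first <= 6 channels on a fixed colour cycle,
# windowed to [0, observed channel max].
default_color_spec <- function(stack) {
  chans <- utils::head(channel_names(stack), 6L)
  cycle <- c("red", "green", "blue", "cyan", "magenta", "yellow")
  ranges <- lapply(chans, function(ch) {
    hi <- max(stack$pixels[, , ch])
    c(0, if (hi > 0) hi else 1)
  })
  color_spec(chans, cycle[seq_along(chans)], range = ranges)
}

#' Export a selection with its gate provenance
#'
#' Writes the selected cells as CSV (via [export_cells()]) plus a YAML
#' sidecar (`<path>.gates.yaml`) recording the gate sequence and survivor
#' counts, so a reader can re-apply the exact gates to the source table and
#' reproduce the subset.
#'
#' @param sel a `selection`.
#' @param path output CSV path; the sidecar lands at `paste0(path,
#'   ".gates.yaml")`.
#' @return invisibly, `c(cells = path, provenance = sidecar_path)`.
#' @export
export_selection <- function(sel, path) {
  export_cells(sel$cells, path)
  sidecar <- paste0(path, ".gates.yaml")
  yaml::write_yaml(list(
    label = sel$sequence$label,
    gates = lapply(sel$sequence$gates, function(g) {
      list(marker = g$marker, min = g$lower, max = g$upper)
    }),
    counts = as.list(unname(sel$counts))
  ), sidecar)
  invisible(c(cells = path, provenance = sidecar))
}

#' Read a gate sequence from YAML
#'
#' Parses the schema used by gate files and provenance sidecars: a `label`
#' plus a list of `{marker, min, max}` entries; absent bounds default to
#' infinite.
#'
#' @param path YAML file path.
#' @return a [gate_sequence].
#' @export
read_gate_sequence <- function(path) {
  doc <- yaml::read_yaml(path)
  gates <- lapply(doc$gates, function(g) {
    gate(g$marker,
         lower = if (is.null(g$min)) -Inf else as.numeric(g$min),
         upper = if (is.null(g$max)) Inf else as.numeric(g$max))
  })
  gate_sequence(gates, label = if (is.null(doc$label)) "selection" else doc$label)
}
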