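default_signature <- function() {
  # type x marker mean intensities (ion-count scale); each type carries one
  # defining marker well separated from the rest
  matrix(c(
    # PIN, CD4, CD8a, SYP, CD45
    5.0, 0.0, 0.0, 3.0, 0.0,   # beta
    0.0, 4.0, 0.0, 0.0, 3.0,   # Th
    0.0, 0.0, 4.0, 0.0, 3.0,   # Tc
    0.0, 0.0, 0.0, 0.5, 0.5    # other
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("beta", "Th", "Tc", "other"),
                  c("PIN", "CD4", "CD8a", "SYP", "CD45")))
}

#' Specification for the synthetic multiplexed-imaging simulator
#'
#' Defines a deterministic, seeded scenario: per image, `n_cells`
#' non-overlapping disc-shaped cells with radii uniform in `radius_range`,
#' cell types drawn from `proportions`, and pixel intensities
#' `background + signature[type, marker]` inside each cell, optionally
#' perturbed by zero-truncated Gaussian or Poisson noise. Discs are placed
#' fully inside the image so each object's pixel support is an exact lattice
#' disc.
#'
#' @param n_images number of images.
#' @param image_size `c(rows, cols)` in pixels.
#' @param n_cells cells per image.
#' @param radius_range `c(r_min, r_max)` disc radii in pixels, `r_min >= 1`.
#' @param proportions named probabilities per cell type, summing to 1.
#' @param signature type x marker matrix of mean intensities (>= 0); row
#'   names must cover `names(proportions)`.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param sigma Gaussian noise standard deviation.
#' @param background baseline intensity added to every pixel.
#' @param pixel_size_um physical pixel size (IMC ablates 1 um spots, the
#'   default).
#' @param seed integer seed; fixing it makes every generator bit-reproducible.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_images = 3L, image_size = c(128L, 128L),
                            n_cells = 50L, radius_range = c(3, 6),
                            proportions = c(beta = 0.4, Th = 0.15,
                                            Tc = 0.15, other = 0.3),
                            signature = default_signature(),
                            noise = c("none", "gaussian", "poisson"),
                            sigma = 0.5, background = 0,
                            pixel_size_um = 1, seed = 1L) {
  noise <- match.arg(noise)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("cell type proportions must sum to 1", call. = FALSE)
  }
  if (is.null(names(proportions)) || any(!nzchar(names(proportions)))) {
    stop("proportions must be named by cell type", call. = FALSE)
  }
  if (radius_range[1L] < 1) stop("minimum radius must be >= 1 px", call. = FALSE)
  if (radius_range[1L] > radius_range[2L]) stop("radius_range out of order", call. = FALSE)
  if (any(signature < 0)) stop("signature intensities must be >= 0", call. = FALSE)
  missing_types <- setdiff(names(proportions), rownames(signature))
  if (length(missing_types)) {
    stop(sprintf("signature lacks row(s) for type(s): %s",
                 paste(missing_types, collapse = ", ")), call. = FALSE)
  }
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 n_cells = as.integer(n_cells),
                 radius_range = as.numeric(radius_range),
                 proportions = proportions, signature = signature,
                 noise = noise, sigma = sigma, background = background,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Stamp one lattice disc into a label matrix. Centre is (row, col), 1-based
# internally; membership is (r - cr)^2 + (c - cc)^2 <= radius^2.
stamp_disc <- function(labels, cr, cc, radius, id) {
  r0 <- max(1L, floor(cr - radius)); r1 <- min(nrow(labels), ceiling(cr + radius))
  c0 <- max(1L, floor(cc - radius)); c1 <- min(ncol(labels), ceiling(cc + radius))
  rr <- r0:r1; cc2 <- c0:c1
  dr2 <- (rr - cr)^2
  dc2 <- (cc2 - cc)^2
  inside <- outer(dr2, dc2, `+`) <= radius^2
  block <- labels[rr, cc2, drop = FALSE]
  block[inside] <- id
  labels[rr, cc2] <- block
  labels
}

#' Generate segmentation masks with planted ground truth
#'
#' Rejection-samples `n_cells` pairwise-disjoint discs per image (centres at
#' integer pixels, margin >= radius from the border, centre separation
#' strictly greater than the radius sum plus one pixel gap) and labels them
#' 1..n in placement order. Deterministic for a fixed seed.
#'
#' @param spec a [simulation_spec].
#' @return list with `masks` (an [image_collection]) and `truth`
#'   (data.frame: `image_name`, `object_id`, `cell_type`, `centre_row`,
#'   `centre_col` (0-based), `radius`).
#' @export
generate_masks <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_size[1L]; nc <- spec$image_size[2L]
    types <- names(spec$proportions)
    entries <- list()
    truth <- list()
    for (img in seq_len(spec$n_images)) {
      nm <- sprintf("sim_%02d", img)
      labels <- matrix(0L, nr, nc)
      placed_r <- placed_c <- placed_rad <- numeric(0)
      cell_types <- if (spec$n_cells > 0) {
        sample(types, spec$n_cells, replace = TRUE, prob = spec$proportions)
      } else character(0)
      max_attempts <- 2000L * max(spec$n_cells, 1L)
      attempts <- 0L
      i <- 1L
      while (i <= spec$n_cells) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop(sprintf(
            "could not place %d cells of radius %g-%g on a %dx%d image; reduce n_cells or the radii",
            spec$n_cells, spec$radius_range[1L], spec$radius_range[2L], nr, nc),
            call. = FALSE)
        }
        rad <- stats::runif(1, spec$radius_range[1L], spec$radius_range[2L])
        margin <- ceiling(rad)
        if (nr - 2L * margin < 1L || nc - 2L * margin < 1L) next
        cr <- sample(seq.int(margin + 1L, nr - margin), 1L)
        cc <- sample(seq.int(margin + 1L, nc - margin), 1L)
        if (length(placed_r)) {
          d <- sqrt((placed_r - cr)^2 + (placed_c - cc)^2)
          if (any(d <= placed_rad + rad + 1)) next
        }
        labels <- stamp_disc(labels, cr, cc, rad, i)
        placed_r <- c(placed_r, cr); placed_c <- c(placed_c, cc)
        placed_rad <- c(placed_rad, rad)
        i <- i + 1L
      }
      entries[[nm]] <- segmentation_mask(labels, spec$pixel_size_um)
      truth[[nm]] <- data.frame(
        image_name = rep(nm, spec$n_cells),
        object_id = seq_len(spec$n_cells),
        cell_type = cell_types,
        centre_row = placed_r - 1, centre_col = placed_c - 1,
        radius = placed_rad, stringsAsFactors = FALSE)
    }
    list(masks = image_collection(entries),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Generate intensity stacks over planted masks
#'
#' Pixel intensity for channel `ch` is `background + signature[type, ch]`
#' inside each object and `background` elsewhere, then noise: Gaussian noise
#' adds `N(0, sigma^2)` truncated at 0 (preserving non-negativity); Poisson
#' noise replaces each pixel by a Poisson draw with that mean (the
#' ion-count model); `"none"` is exact.
#'
#' @param masks the mask collection from [generate_masks()].
#' @param truth the matching ground-truth table.
#' @param spec the [simulation_spec].
#' @return an [image_collection] of stacks.
#' @export
generate_stacks <- function(masks, truth, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  planted <- unique(truth$cell_type)
  missing_types <- setdiff(planted, rownames(spec$signature))
  if (length(missing_types)) {
    stop(sprintf("signature lacks row(s) for planted type(s): %s",
                 paste(missing_types, collapse = ", ")), call. = FALSE)
  }
  chans <- colnames(spec$signature)
  with_seed(spec$seed + 1L, {
    entries <- lapply(names(masks), function(nm) {
      mask <- masks[[nm]]
      lab <- as.vector(mask$labels)
      tr <- truth[truth$image_name == nm, ]
      type_of <- tr$cell_type[match(lab, tr$object_id)]  # NA for background
      type_idx <- match(type_of, rownames(spec$signature))
      d <- dim(mask)
      px <- array(spec$background, c(d, length(chans)))
      for (ch in seq_along(chans)) {
        add <- spec$signature[cbind(type_idx, ch)]
        add[is.na(add)] <- 0
        px[, , ch] <- px[, , ch] + matrix(add, d[1L], d[2L])
      }
      if (spec$noise == "gaussian") {
        px <- pmax(px + stats::rnorm(length(px), 0, spec$sigma), 0)
        px <- array(px, c(d, length(chans)))
      } else if (spec$noise == "poisson") {
        px <- array(stats::rpois(length(px), px), c(d, length(chans)))
      }
      image_stack(px, chans, pixel_size_um = spec$pixel_size_um)
    })
    names(entries) <- names(masks)
    image_collection(entries, masks$element_metadata)
  })
}

#' Measure a cell table from generated masks and stacks
#'
#' Runs [measure_cells()] over every mask/stack pair and attaches the planted
#' `cell_type` from the ground truth, yielding the table a real pipeline
#' would extract.
#'
#' @param masks mask [image_collection].
#' @param stacks stack [image_collection].
#' @param truth ground-truth table from [generate_masks()].
#' @return a [cell_table] with `cell_type`, `area_px` and centroid metadata.
#' @export
generate_cell_table <- function(masks, stacks, truth) {
  parts <- lapply(names(masks), function(nm) {
    measure_cells(stacks[[nm]], masks[[nm]], image_name = nm)
  })
  combined <- Reduce(rbind_cell_tables, parts)
  key <- paste(combined$image_name, combined$object_id)
  tkey <- paste(truth$image_name, truth$object_id)
  md <- combined$metadata
  md$cell_type <- factor(truth$cell_type[match(key, tkey)])
  cell_table(combined$image_name, combined$object_id, combined$expression, md)
}

rbind_cell_tables <- function(a, b) {
  stopifnot(identical(marker_names(a), marker_names(b)))
  cell_table(c(a$image_name, b$image_name), c(a$object_id, b$object_id),
             rbind(a$expression, b$expression),
             rbind(a$metadata, b$metadata))
}

#' Build a T1D-like three-condition scenario
#'
#' Emulates the structure of a type 1 diabetes progression study: three
#' condition groups (`healthy`, `recent_onset`, `long_duration`) of islet
#' images in which the beta-cell proportion falls monotonically with disease
#' duration (0.5, 0.3, 0.1) while the cytotoxic/helper T cell fraction peaks
#' at recent onset (0.10, 0.40, 0.20 combined) — beta-cell loss with a wave
#' of immune infiltration. The group label sits in the collections'
#' `element_metadata` (`condition`), and `gates` carries per-type
#' ground-truth gate sequences at the midpoints between the planted
#' signature levels.
#'
#' @param seed integer seed.
#' @param n_images_per_group images per condition.
#' @param n_cells cells per image.
#' @param image_size `c(rows, cols)`.
#' @param radius_range disc radii; the default `c(4, 6)` keeps every cell
#'   above ~45 px.
#' @param noise,sigma noise model forwarded to [simulation_spec()].
#' @param background baseline intensity.
#' @return list with `masks`, `stacks`, `cells`, `truth`, `gates`,
#'   `signature`, `proportions` (per condition) and `background`.
#' @export
make_t1d_like_scenario <- function(seed = 1L, n_images_per_group = 3L,
                                   n_cells = 40L, image_size = c(128L, 128L),
                                   radius_range = c(4, 6),
                                   noise = "none", sigma = 0.5,
                                   background = 0.1) {
  conditions <- c("healthy", "recent_onset", "long_duration")
  props <- list(
    healthy       = c(beta = 0.50, Th = 0.05, Tc = 0.05, other = 0.40),
    recent_onset  = c(beta = 0.30, Th = 0.20, Tc = 0.20, other = 0.30),
    long_duration = c(beta = 0.10, Th = 0.10, Tc = 0.10, other = 0.70))
  sig <- default_signature()
  masks_parts <- list(); stacks_parts <- list(); truth_parts <- list()
  for (gi in seq_along(conditions)) {
    cond <- conditions[gi]
    spec <- simulation_spec(
      n_images = n_images_per_group, image_size = image_size,
      n_cells = n_cells, radius_range = radius_range,
      proportions = props[[cond]], signature = sig, noise = noise,
      sigma = sigma, background = background, pixel_size_um = 1,
      seed = seed + 101L * gi)
    gen <- generate_masks(spec)
    stk <- generate_stacks(gen$masks, gen$truth, spec)
    # prefix names with the condition so the pooled collection stays unique
    nms <- sprintf("%s_%02d", cond, seq_len(n_images_per_group))
    ent_m <- gen$masks$entries; names(ent_m) <- nms
    ent_s <- stk$entries; names(ent_s) <- nms
    md <- data.frame(image_name = nms, condition = cond,
                     stringsAsFactors = FALSE)
    masks_parts[[cond]] <- image_collection(ent_m, md)
    stacks_parts[[cond]] <- image_collection(ent_s, md)
    tr <- gen$truth
    tr$image_name <- nms[match(tr$image_name, names(gen$masks))]
    tr$condition <- cond
    truth_parts[[cond]] <- tr
  }
  masks <- do.call(c, unname(masks_parts))
  stacks <- do.call(c, unname(stacks_parts))
  truth <- do.call(rbind, c(unname(truth_parts), list(make.row.names = FALSE)))
  cells <- generate_cell_table(masks, stacks, truth)
  cells$metadata$condition <- factor(
    truth$condition[match(paste(cells$image_name, cells$object_id),
                          paste(truth$image_name, truth$object_id))])
  # half the defining signature level separates positives from the rest
  gates <- list(
    beta = gate_sequence(list(gate("PIN", lower = background + sig["beta", "PIN"] / 2)),
                         label = "beta"),
    Th = gate_sequence(list(gate("CD45", lower = background + 1.5),
                            gate("CD4", lower = background + sig["Th", "CD4"] / 2)),
                       label = "Th"),
    Tc = gate_sequence(list(gate("CD45", lower = background + 1.5),
                            gate("CD8a", lower = background + sig["Tc", "CD8a"] / 2)),
                       label = "Tc"))
  list(masks = masks, stacks = stacks, cells = cells, truth = truth,
       gates = gates, signature = sig, proportions = props,
       background = background)
}
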