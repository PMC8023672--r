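# Independent brute-force oracles and tiny fixture builders shared across
# the test files. The oracles deliberately use naive per-pixel / per-row
# loops so they share no code path with the implementation they check.

# Exhaustive per-pixel accumulation of per-object channel means.
oracle_measure <- function(stack, mask) {
  lab <- mask$labels
  ids <- sort(unique(lab[lab > 0]))
  chans <- channel_names(stack)
  out <- matrix(0, length(ids), length(chans), dimnames = list(ids, chans))
  area <- setNames(numeric(length(ids)), ids)
  for (r in seq_len(nrow(lab))) {
    for (c in seq_len(ncol(lab))) {
      id <- lab[r, c]
      if (id > 0) {
        key <- as.character(id)
        area[key] <- area[key] + 1
        for (ch in seq_along(chans)) {
          out[key, ch] <- out[key, ch] + stack$pixels[r, c, ch]
        }
      }
    }
  }
  sweep(out, 1, area, "/")
}

# Double-loop 8-neighbourhood boundary: an object pixel is boundary iff any
# of its 8 neighbours has a different label; pixels beyond the image border
# count as background.
oracle_boundary <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (labels[r, c] == 0) next
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; cc <- c + dc
          nb <- if (rr < 1 || rr > nr || cc < 1 || cc > nc) 0L else labels[rr, cc]
          if (nb != labels[r, c]) out[r, c] <- TRUE
        }
      }
    }
  }
  out
}

# Row-by-row exhaustive interval filter (closed bounds, sequential).
oracle_gate <- function(cells, gates) {
  keep <- logical(n_cells(cells))
  counts <- integer(0)
  alive <- rep(TRUE, n_cells(cells))
  for (g in gates) {
    for (i in seq_len(n_cells(cells))) {
      if (!alive[i]) next
      v <- cells$expression[i, g$marker]
      if (!(v >= g$lower && v <= g$upper)) alive[i] <- FALSE
    }
    counts <- c(counts, sum(alive))
  }
  list(keep = which(alive), counts = counts)
}

# Random cell table spanning two images, with per-image consecutive ids.
random_table <- function(n = 200, markers = c("A", "B", "C", "D")) {
  im <- sample(c("i1", "i2"), n, replace = TRUE)
  oid <- stats::ave(seq_len(n), im, FUN = seq_along)
  cell_table(im, oid,
             matrix(runif(n * length(markers), 0, 10), n, length(markers),
                    dimnames = list(NULL, markers)))
}

# Random closed-interval gates over the given markers.
random_gates <- function(markers, k) {
  lapply(seq_len(k), function(i) {
    b <- sort(runif(2, 0, 10))
    gate(sample(markers, 1), b[1], b[2])
  })
}

# Random label matrix (not necessarily contiguous objects; the boundary
# definition only needs labels).
random_labels <- function(nr = 32, nc = 32, n_ids = 4) {
  matrix(sample(0:n_ids, nr * nc, replace = TRUE), nr, nc)
}

# Small deterministic cell table.
tiny_cells <- function(image_name = "a", n = 3,
                       markers = c("PIN", "CD4"),
                       values = NULL, metadata = NULL) {
  if (is.null(values)) {
    values <- matrix(seq_len(n * length(markers)), n, length(markers))
  }
  colnames(values) <- markers
  cell_table(image_name, seq_len(n), values, metadata)
}

# A mask with one k x k square object at (r0, c0) (1-based corner).
square_mask <- function(nr = 8, nc = 8, r0 = 3, c0 = 3, k = 3, id = 1L,
                        pixel_size_um = NULL) {
  lab <- matrix(0L, nr, nc)
  lab[r0:(r0 + k - 1), c0:(c0 + k - 1)] <- id
  segmentation_mask(lab, pixel_size_um)
}

# Uniform random stack with named channels.
random_stack <- function(nr = 16, nc = 16, chans = c("A", "B"), max_val = 1) {
  image_stack(array(runif(nr * nc * length(chans), 0, max_val),
                    c(nr, nc, length(chans))), chans)
}
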