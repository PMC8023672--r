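two_cell_mask <- function() {
  lab <- matrix(0L, 6, 6)
  lab[2:3, 2:3] <- 1L
  lab[5, 5] <- 2L
  segmentation_mask(lab)
}

pixel_color <- function(img, r, c) as.vector(img$rgb[r, c, ])

test_that("feature colouring hits ramp endpoints and interpolates linearly", {
  m <- two_cell_mask()
  ct <- tiny_cells("a", 2, markers = "v", values = matrix(c(0, 10), 2, 1))
  img <- colorize_mask_by_feature(m, ct, "a", "v", ramp = c("black", "red"))
  expect_equal(pixel_color(img, 2, 2), c(0, 0, 0))      # value 0 -> black
  expect_equal(pixel_color(img, 5, 5), c(1, 0, 0))      # value 10 -> pure red
  expect_equal(pixel_color(img, 1, 1), c(0, 0, 0))      # background
  leg <- img$annotations[[1]]
  expect_identical(leg$kind, "legend_entry")
  expect_equal(c(leg$payload$lo, leg$payload$hi), c(0, 10))

  # three values: the middle cell sits halfway along the ramp
  lab <- matrix(0L, 3, 9)
  lab[2, c(2, 5, 8)] <- c(1L, 2L, 3L)
  ct3 <- tiny_cells("a", 3, markers = "v", values = matrix(c(0, 5, 10), 3, 1))
  img3 <- colorize_mask_by_feature(segmentation_mask(lab), ct3, "a", "v",
                                   ramp = c("black", "red"))
  expect_equal(pixel_color(img3, 2, 5), c(0.5, 0, 0))
})

test_that("feature colouring handles degenerate range, missing objects and explicit range", {
  m <- two_cell_mask()
  # single cell: degenerate range -> first ramp colour
  one <- tiny_cells("a", 1, markers = "v", values = matrix(7, 1, 1))
  img <- colorize_mask_by_feature(m, one, "a", "v", ramp = c("blue", "red"))
  expect_equal(pixel_color(img, 2, 2), c(0, 0, 1))
  # object 2 has no cell row -> missing colour (white)
  expect_equal(pixel_color(img, 5, 5), c(1, 1, 1))
  # cells referencing absent objects warn via annotation, not error
  ghost <- tiny_cells("a", 3, markers = "v", values = matrix(c(1, 2, 3), 3, 1))
  img2 <- colorize_mask_by_feature(m, ghost, "a", "v")
  kinds <- vapply(img2$annotations, `[[`, character(1), "kind")
  expect_true("warning" %in% kinds)
  # explicit range clips
  ct <- tiny_cells("a", 2, markers = "v", values = matrix(c(0, 100), 2, 1))
  img3 <- colorize_mask_by_feature(m, ct, "a", "v", ramp = c("black", "red"),
                                   range = c(0, 10))
  expect_equal(pixel_color(img3, 5, 5), c(1, 0, 0))
  expect_error(colorize_mask_by_feature(m, ct, "a", "nope"), "nope")
})

test_that("monotone ramp preserves the ordering of feature values in the red channel", {
  set.seed(51)
  n <- 12
  lab <- matrix(0L, 4, 3 * n)
  for (i in seq_len(n)) lab[2, 3 * i - 1] <- i
  v <- runif(n, 0, 50)
  ct <- tiny_cells("a", n, markers = "v", values = matrix(v, n, 1))
  img <- colorize_mask_by_feature(segmentation_mask(lab), ct, "a", "v",
                                  ramp = c("black", "red"))
  red <- vapply(seq_len(n), function(i) img$rgb[2, 3 * i - 1, 1], numeric(1))
  expect_identical(order(red), order(v))
})

test_that("metadata colouring maps levels via palette, subset to white elsewhere", {
  lab <- matrix(0L, 3, 12)
  lab[2, c(2, 5, 8, 11)] <- 1:4
  m <- segmentation_mask(lab)
  md <- data.frame(cell_type = factor(c("beta", "Tc", "Th", "other")))
  ct <- tiny_cells("a", 4, markers = "m", values = matrix(0, 4, 1), metadata = md)
  pal <- categorical_palette(list(beta = c(1, 0, 0), Tc = c(0, 0, 1),
                                  Th = c(0, 1, 0)))
  img <- colorize_mask_by_metadata(m, ct, "a", "cell_type", pal,
                                   subset = c("beta", "Tc", "Th"))
  expect_equal(pixel_color(img, 2, 2), c(1, 0, 0))
  expect_equal(pixel_color(img, 2, 5), c(0, 0, 1))
  expect_equal(pixel_color(img, 2, 8), c(0, 1, 0))
  expect_equal(pixel_color(img, 2, 11), c(1, 1, 1))  # outside subset -> white
  expect_equal(pixel_color(img, 1, 1), c(0, 0, 0))   # background -> black
  # empty subset: every object takes the missing colour
  img0 <- colorize_mask_by_metadata(m, ct, "a", "cell_type", pal,
                                    subset = character(0))
  expect_equal(pixel_color(img0, 2, 2), c(1, 1, 1))
  # plotted level without a palette colour is an error naming the level
  expect_error(colorize_mask_by_metadata(m, ct, "a", "cell_type", pal),
               "other")
})

test_that("distinct output colours are a subset of palette, missing and background", {
  set.seed(52)
  lab <- random_labels(24, 24, n_ids = 6)
  m <- segmentation_mask(lab)
  ids <- object_ids(m)
  md <- data.frame(grp = factor(sample(c("x", "y"), length(ids), TRUE)))
  ct <- cell_table("a", ids, matrix(0, length(ids), 1,
                                    dimnames = list(NULL, "m")), md)
  pal <- categorical_palette(list(x = c(1, 0, 0), y = c(0, 1, 0)))
  img <- colorize_mask_by_metadata(m, ct, "a", "grp", pal)
  seen <- unique(matrix(img$rgb, ncol = 3))
  allowed <- rbind(pal$colors, pal$missing_color, pal$background_color)
  for (i in seq_len(nrow(seen))) {
    expect_true(any(apply(allowed, 1, function(a) all(a == seen[i, ]))))
  }
  # a mask object absent from the table -> missing colour plus a warning annotation
  ct2 <- ct[-1]
  img2 <- colorize_mask_by_metadata(m, ct2, "a", "grp", pal)
  kinds <- vapply(img2$annotations, `[[`, character(1), "kind")
  expect_true("warning" %in% kinds)
})

test_that("composite blending is additive with clipping and order-invariant", {
  set.seed(53)
  s <- random_stack(8, 8, c("A", "B", "C", "D"), max_val = 1)
  spec1 <- color_spec(c("A", "B", "C"), c("red", "green", "blue"))
  spec2 <- color_spec(c("C", "A", "B"), c("blue", "red", "green"))
  img1 <- composite_pixels(s, spec1)
  img2 <- composite_pixels(s, spec2)
  expect_equal(img1$rgb, img2$rgb, tolerance = 0)
  expect_true(all(img1$rgb >= 0 & img1$rgb <= 1))

  # single red channel leaves green/blue identically zero and equals u
  u <- 0.4
  flat <- image_stack(array(u, c(2, 2, 1)), "A")
  img <- composite_pixels(flat, color_spec("A", "red"))
  expect_equal(pixel_color(img, 1, 1), c(0.4, 0, 0))
  expect_true(all(img$rgb[, , 2:3] == 0))

  # two channels both red at 0.7 and 0.6 clip to pure red
  s2 <- image_stack(array(c(rep(0.7, 4), rep(0.6, 4)), c(2, 2, 2)), c("A", "B"))
  img2c <- composite_pixels(s2, color_spec(c("A", "B"), c("red", "red")))
  expect_equal(pixel_color(img2c, 1, 1), c(1, 0, 0))
})

test_that("composite applies contrast, background, gamma then range window, in that order", {
  x <- 0.03
  s <- image_stack(array(x, c(1, 1, 1)), "PIN")
  # contrast 10 -> 0.3; background 0.1 -> 0.4; gamma 2 -> 0.16; window [0.06, 0.26] -> 0.5
  spec <- color_spec("PIN", "red", contrast = 10, background = 0.1,
                     gamma = 2, range = c(0.06, 0.26))
  img <- composite_pixels(s, spec)
  expect_equal(img$rgb[1, 1, 1], 0.5, tolerance = 1e-12)
})

test_that("composites refuse more than six channels and unknown channels", {
  s <- random_stack(4, 4, sprintf("ch%d", 1:8))
  spec7 <- color_spec(sprintf("ch%d", 1:7), rep("red", 7))
  expect_error(composite_pixels(s, spec7), "six")
  expect_error(composite_pixels(s, color_spec("nope", "red")), "nope")
  spec6 <- color_spec(sprintf("ch%d", 1:6),
                      c("red", "green", "blue", "cyan", "magenta", "yellow"))
  expect_s3_class(composite_pixels(s, spec6), "rendered_image")
})

test_that("outline of a 3x3 square recolours its 8 border pixels, centre untouched", {
  m <- square_mask(8, 8, 3, 3, 3)
  base <- rendered_image(array(0, c(8, 8, 3)))
  out <- outline_cells(base, m, color = "white")
  marked <- out$rgb[, , 1] == 1
  want <- matrix(FALSE, 8, 8)
  want[3:5, 3:5] <- TRUE
  want[4, 4] <- FALSE
  expect_identical(marked, want)
  expect_equal(pixel_color(out, 4, 4), c(0, 0, 0))
  # empty mask -> base unchanged
  empty <- segmentation_mask(matrix(0L, 8, 8))
  expect_identical(outline_cells(base, empty)$rgb, base$rgb)
  expect_error(outline_cells(base, m, thickness = 0), "thickness")
})

test_that("outline pixels match the brute-force 8-neighbourhood oracle on random masks", {
  set.seed(54)
  for (rep in 1:8) {
    lab <- random_labels(32, 32, n_ids = 5)
    m <- segmentation_mask(lab)
    base <- rendered_image(array(0, c(32, 32, 3)))
    out <- outline_cells(base, m, color = "white")
    marked <- out$rgb[, , 1] == 1 & out$rgb[, , 2] == 1 & out$rgb[, , 3] == 1
    expect_identical(marked, oracle_boundary(lab))
    # every outline pixel belongs to its object (never spills outside)
    expect_true(all(lab[marked] > 0))
  }
})

test_that("thickness dilates inward: thicker outlines stay inside their object", {
  set.seed(55)
  lab <- matrix(0L, 16, 16)
  lab[3:10, 3:10] <- 1L
  lab[12:15, 12:15] <- 2L
  m <- segmentation_mask(lab)
  base <- rendered_image(array(0, c(16, 16, 3)))
  t1 <- outline_cells(base, m, color = "white")$rgb[, , 1] == 1
  t2 <- outline_cells(base, m, color = "white", thickness = 2)$rgb[, , 1] == 1
  expect_true(all(t2[t1]))          # thickness 1 outline is contained in 2
  expect_gt(sum(t2), sum(t1))
  expect_true(all(lab[t2] > 0))     # still inside objects
})

test_that("outlines can be coloured by cell type metadata", {
  lab <- matrix(0L, 8, 16)
  lab[3:5, 3:5] <- 1L
  lab[3:5, 10:12] <- 2L
  m <- segmentation_mask(lab)
  md <- data.frame(cell_type = factor(c("beta", "Tc")))
  ct <- tiny_cells("a", 2, markers = "m", values = matrix(0, 2, 1), metadata = md)
  pal <- categorical_palette(list(beta = c(1, 0, 0), Tc = c(0, 0, 1)))
  base <- rendered_image(array(0, c(8, 16, 3)))
  out <- outline_cells(base, m, ct, "cell_type", pal)
  expect_equal(pixel_color(out, 3, 3), c(1, 0, 0))
  expect_equal(pixel_color(out, 3, 10), c(0, 0, 1))
  expect_equal(pixel_color(out, 4, 4), c(0, 0, 0))  # interior untouched
})

test_that("scale bars convert physical length to pixels and respect image width", {
  img <- rendered_image(array(0, c(64, 128, 3)), pixel_size_um = 1)
  sb20 <- add_scale_bar(img, 20)
  ann <- sb20$annotations[[length(sb20$annotations)]]
  expect_identical(ann$kind, "scale_bar")
  expect_identical(ann$payload$length_px, 20L)
  expect_equal(sum(sb20$rgb[, , 1] == 1) %% 20, 0)  # bar rows are 20 px long
  sb100 <- add_scale_bar(img, 100)
  expect_identical(sb100$annotations[[1]]$payload$length_px, 100L)
  # half-micron pixels double the bar length
  img2 <- rendered_image(array(0, c(64, 128, 3)), pixel_size_um = 0.5)
  expect_identical(add_scale_bar(img2, 20)$annotations[[1]]$payload$length_px, 40L)
  # bar longer than the image is an error, as is an unknown pixel size
  small <- rendered_image(array(0, c(64, 80, 3)), pixel_size_um = 1)
  expect_error(add_scale_bar(small, 100), "wider")
  expect_error(add_scale_bar(rendered_image(array(0, c(4, 4, 3))), 20),
               "pixel size")
})

test_that("render_grid lays out panels row-major with padding and margins", {
  mk <- function(v, nr = 5, nc = 4) rendered_image(array(v, c(nr, nc, 3)))
  g <- render_grid(list(mk(0.2), mk(0.4), mk(0.6), mk(0.8), mk(1)), 3,
                   margin_px = 1)
  expect_identical(dim(g$rgb)[1:2], c(2L * 5L + 3L, 3L * 4L + 4L))
  # panel 4 starts the second row
  expect_equal(g$rgb[1 + 5 + 1 + 1, 2, 1], 0.8)
  layout <- g$annotations[[1]]$payload
  expect_identical(c(layout$rows, layout$columns), c(2L, 3L))
  # single panel: itself plus margin
  g1 <- render_grid(list(mk(0.5)), 1, margin_px = 2)
  expect_identical(dim(g1$rgb)[1:2], c(9L, 8L))
  # 100 panels in 10 columns -> 10x10
  g100 <- render_grid(rep(list(mk(0.1, 2, 2)), 100), 10, margin_px = 0)
  expect_identical(dim(g100$rgb)[1:2], c(20L, 20L))
  # smaller panels are padded with background
  gpad <- render_grid(list(mk(1, 4, 4), mk(1, 2, 2)), 2, margin_px = 0)
  expect_equal(gpad$rgb[4, 8, 1], 0)
  expect_error(render_grid(list(), 2), "panels")
})

test_that("every rendered output stays inside [0,1]", {
  set.seed(56)
  sc <- make_t1d_like_scenario(seed = 13, n_images_per_group = 1, n_cells = 10)
  nm <- names(sc$masks)[1]
  pal <- categorical_palette(list(beta = "red", Tc = "blue", Th = "green",
                                  other = "grey50"))
  renders <- list(
    colorize_mask_by_metadata(sc$masks[[nm]], sc$cells, nm, "cell_type", pal),
    colorize_mask_by_feature(sc$masks[[nm]], sc$cells, nm, "PIN"),
    composite_pixels(scale_intensity(sc$stacks[[nm]], c(PIN = 10, CD4 = 8, CD8a = 10)),
                     color_spec(c("PIN", "CD4", "CD8a"),
                                c("yellow", "blue", "red"))))
  for (r in renders) expect_true(all(r$rgb >= 0 & r$rgb <= 1))
})
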