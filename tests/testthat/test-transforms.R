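collection_of <- function(...) {
  stacks <- list(...)
  if (is.null(names(stacks))) names(stacks) <- sprintf("img%d", seq_along(stacks))
  image_collection(stacks)
}

test_that("minmax normalization maps channel extremes to 0/1 and constants to 0", {
  s <- image_stack(array(c(0, 5, 10, 7, 7, 7), c(3, 1, 2)), c("A", "B"))
  out <- normalize(collection_of(s))[[1]]
  expect_equal(as.vector(out$pixels[, , "A"]), c(0, 0.5, 1))
  expect_equal(as.vector(out$pixels[, , "B"]), c(0, 0, 0))
  expect_error(normalize(image_collection(list())), "empty")
})

test_that("joint scope pools bounds across images, separate scope does not", {
  s1 <- image_stack(array(c(0, 10), c(2, 1, 1)), "A")
  s2 <- image_stack(array(c(0, 20), c(2, 1, 1)), "A")
  joint <- normalize(collection_of(a = s1, b = s2), scope = "joint")
  expect_equal(max(joint[["a"]]$pixels), 0.5)   # 10 / pooled hi 20
  expect_equal(max(joint[["b"]]$pixels), 1)
  sep <- normalize(collection_of(a = s1, b = s2), scope = "separate")
  expect_equal(max(sep[["a"]]$pixels), 1)
})

test_that("minmax/separate normalization is idempotent and stays in [0,1]", {
  set.seed(41)
  col <- collection_of(random_stack(8, 8, c("A", "B"), max_val = 40),
                       random_stack(8, 8, c("A", "B"), max_val = 7))
  once <- normalize(col)
  twice <- normalize(once)
  for (nm in names(once)) {
    expect_true(all(once[[nm]]$pixels >= 0 & once[[nm]]$pixels <= 1))
    expect_equal(twice[[nm]]$pixels, once[[nm]]$pixels, tolerance = 1e-12)
  }
})

test_that("percentile normalization uses interpolated order statistics and clips", {
  v <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 100)
  s <- image_stack(array(v, c(10, 1, 1)), "A")
  out <- normalize(collection_of(s), method = "percentile",
                   percentiles = c(10, 90))
  lo <- unname(quantile(v, 0.1, type = 7))
  hi <- unname(quantile(v, 0.9, type = 7))
  expect_equal(as.vector(out[[1]]$pixels),
               pmin(pmax((v - lo) / (hi - lo), 0), 1))
  expect_error(normalize(collection_of(s), method = "percentile",
                         percentiles = c(90, 10)), "p_lo < p_hi")
})

test_that("scale_intensity multiplies named channels only, with the documented factors", {
  px <- array(0.03, c(2, 2, 4))
  s <- image_stack(px, c("PIN", "CD4", "CD8a", "SYP"))
  out <- scale_intensity(s, c(PIN = 10, CD4 = 8, CD8a = 10))
  expect_equal(unique(as.vector(out$pixels[, , "PIN"])), 0.3)
  expect_equal(unique(as.vector(out$pixels[, , "CD4"])), 0.24)
  expect_equal(unique(as.vector(out$pixels[, , "CD8a"])), 0.3)
  expect_equal(out$pixels[, , "SYP"], s$pixels[, , "SYP"])  # untouched
  expect_equal(scale_intensity(s, c(PIN = 1))$pixels, s$pixels)
  expect_error(scale_intensity(s, c(CD3 = 2)), "CD3")
  expect_error(scale_intensity(s, c(PIN = 0)), "positive")
})

test_that("scale_intensity composes multiplicatively", {
  set.seed(42)
  s <- random_stack(6, 6, c("A", "B"))
  ab <- scale_intensity(scale_intensity(s, c(A = 2)), c(A = 3, B = 5))
  direct <- scale_intensity(s, c(A = 6, B = 5))
  expect_equal(ab$pixels, direct$pixels, tolerance = 1e-12)
})

test_that("measure_cells equals the brute-force per-pixel oracle on random instances", {
  set.seed(43)
  for (rep in 1:5) {
    lab <- random_labels(16, 16, n_ids = 5)
    m <- segmentation_mask(lab)
    s <- random_stack(16, 16, c("A", "B", "C"), max_val = 10)
    got <- measure_cells(s, m, "x")
    want <- oracle_measure(s, m)
    expect_identical(got$object_id, as.integer(rownames(want)))
    expect_equal(unname(got$expression), unname(want), tolerance = 1e-12)
  }
})

test_that("measure_cells reports exact means, areas and centroids on a known object", {
  lab <- matrix(0L, 4, 4); lab[2:3, 2:3] <- 1L
  s <- image_stack(array(c(rep(0, 16)), c(4, 4, 1)), "A")
  s$pixels[2:3, 2:3, 1] <- c(1, 1, 3, 3)
  ct <- measure_cells(s, segmentation_mask(lab))
  expect_equal(as.vector(ct$expression), 2)
  expect_identical(ct$metadata$area_px, 4L)
  # centroid in 0-based (row, col): pixels at rows 1,2 cols 1,2
  expect_equal(ct$metadata$centroid_row, 1.5)
  expect_equal(ct$metadata$centroid_col, 1.5)
  # empty mask -> 0-row table
  empty <- measure_cells(s, segmentation_mask(matrix(0L, 4, 4)))
  expect_identical(n_cells(empty), 0L)
  expect_error(measure_cells(s, segmentation_mask(matrix(0L, 5, 4))), "mismatch")
})

test_that("cell_density uses full image area, per megapixel or per mm2", {
  md <- data.frame(cell_type = factor(c("Tc", "Tc", "Th", "beta", "Tc")))
  ct <- tiny_cells("a", 5, markers = "m", values = matrix(1:5, 5, 1), metadata = md)
  mask_px <- segmentation_mask(matrix(0L, 100, 100))
  d <- cell_density(ct, "a", mask_px, c("Tc", "Th"), "cell_type")
  expect_equal(as.numeric(d), 4 / 1e4 * 1e6)  # 400 per megapixel
  expect_identical(attr(d, "unit"), "per_megapixel")
  # 1 um pixels: 100x100 px = 0.01 mm2
  mask_um <- segmentation_mask(matrix(0L, 100, 100), pixel_size_um = 1)
  d2 <- cell_density(ct, "a", mask_um, "Tc", "cell_type")
  expect_equal(as.numeric(d2), 3 / 0.01)
  expect_identical(attr(d2, "unit"), "per_mm2")
  expect_equal(as.numeric(cell_density(ct, "a", mask_um, character(0), "cell_type")), 0)
  expect_error(cell_density(ct, "a", mask_um, "Tc", "nope"), "nope")
})

test_that("rank_images sorts by descending density with lexicographic tie-break", {
  md <- data.frame(cell_type = factor(rep("Tc", 10)))
  ct <- cell_table(c(rep("i1", 2), rep("i2", 5), rep("i3", 3)),
                   c(1:2, 1:5, 1:3),
                   matrix(0, 10, 1, dimnames = list(NULL, "m")), md)
  mk <- function() segmentation_mask(matrix(0L, 10, 10))
  masks <- image_collection(list(i1 = mk(), i2 = mk(), i3 = mk()))
  r <- rank_images(ct, masks, "Tc")
  expect_identical(r$image_name, c("i2", "i3", "i1"))
  expect_identical(r$image_name[r$selected], "i2")

  # tie: equal densities order by name, deterministically
  ct2 <- cell_table(c("b", "a"), c(1, 1),
                    matrix(0, 2, 1, dimnames = list(NULL, "m")),
                    data.frame(cell_type = factor(c("Tc", "Tc"))))
  masks2 <- image_collection(list(b = mk(), a = mk()))
  r2 <- rank_images(ct2, masks2, "Tc")
  expect_identical(r2$image_name, c("a", "b"))
  expect_identical(r2$image_name[r2$selected], "a")
})

test_that("rank_images grouping selects one image per group and reports NA groups", {
  mk <- function() segmentation_mask(matrix(0L, 10, 10))
  masks <- image_collection(list(g1 = mk(), g2 = mk(), g3 = mk()),
                            data.frame(condition = c("h", "t1d", NA)))
  ct <- cell_table(c("g1", "g2", "g3"), c(1, 1, 1),
                   matrix(0, 3, 1, dimnames = list(NULL, "m")),
                   data.frame(cell_type = factor(rep("Tc", 3))))
  expect_warning(r <- rank_images(ct, masks, "Tc", group_column = "condition"),
                 "NA")
  expect_identical(sum(r$selected), 3L)  # one per group incl. "NA"
  expect_setequal(r$group, c("h", "t1d", "NA"))
})

test_that("rank_images ordering is invariant under permutation of cell rows", {
  set.seed(44)
  sc <- make_t1d_like_scenario(seed = 9, n_images_per_group = 2, n_cells = 15)
  r1 <- rank_images(sc$cells, sc$masks, c("Tc", "Th"),
                    group_column = "condition")
  perm <- sample(n_cells(sc$cells))
  r2 <- rank_images(sc$cells[perm], sc$masks, c("Tc", "Th"),
                    group_column = "condition")
  expect_identical(r1$image_name, r2$image_name)
  expect_identical(r1$density, r2$density)
})
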