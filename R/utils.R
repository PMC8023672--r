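#' @keywords internal
"_PACKAGE"

# Clamp numeric values into [0, 1].
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Convert a colour specification to an RGB triple
#'
#' Accepts a numeric triple in \[0,1\], a hex string ("#RRGGBB") or any colour
#' name understood by [grDevices::col2rgb()].
#'
#' @param color numeric length-3 vector in \[0,1\], or a single character
#'   colour ("#RRGGBB" or an R colour name).
#' @return numeric length-3 RGB vector in \[0,1\].
#' @export
as_rgb <- function(color) {
  if (is.numeric(color)) {
    if (length(color) != 3L || anyNA(color) || any(color < 0) || any(color > 1)) {
      stop("numeric colours must be RGB triples in [0, 1]", call. = FALSE)
    }
    return(as.numeric(color))
  }
  if (is.character(color) && length(color) == 1L) {
    return(as.numeric(grDevices::col2rgb(color)) / 255)
  }
  stop("cannot interpret colour specification", call. = FALSE)
}

# Convert a list/vector of colour specs to an n x 3 matrix.
as_rgb_matrix <- function(colors) {
  if (is.matrix(colors)) {
    stopifnot(ncol(colors) == 3L)
    return(colors)
  }
  if (is.numeric(colors) && length(colors) == 3L) colors <- list(colors)
  if (is.character(colors)) colors <- as.list(colors)
  out <- t(vapply(colors, as_rgb, numeric(3)))
  dimnames(out) <- list(names(colors), c("r", "g", "b"))
  out
}

# Piecewise-linear interpolation of t in [0,1] along a colour ramp.
# ramp: k x 3 matrix, colours evenly spaced at t = 0 ... 1. Interpolation is
# linear in RGB space (pinned for reproducibility).
ramp_interpolate <- function(t, ramp) {
  k <- nrow(ramp)
  anchors <- seq(0, 1, length.out = k)
  out <- matrix(0, length(t), 3L)
  for (j in 1:3) {
    out[, j] <- stats::approx(anchors, ramp[, j], xout = t, rule = 2)$y
  }
  out
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's random
# state afterwards (no global state leakage from generators).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stable md5 hash of an R object via its canonical JSON serialization.
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), f)
  unname(tools::md5sum(f))
}
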