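#' @import data.table
#' @importFrom stats rnorm rpois rgeom runif dnorm pnorm optimize qgeom ks.test sd
#' @importFrom utils head tail modifyList
NULL

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

# Linear pixel indices of an ellipse on an h x w matrix (row = y, col = x).
# Pixel (ix, iy) is 1-based with its centre at ((ix - 0.5), (iy - 0.5)) px.
ellipse_pixels <- function(h, w, cx, cy, rx, ry = rx) {
  x0 <- max(1L, floor(cx - rx)); x1 <- min(w, ceiling(cx + rx))
  y0 <- max(1L, floor(cy - ry)); y1 <- min(h, ceiling(cy + ry))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  inside <- ((gx - 0.5 - cx) / rx)^2 + ((gy - 0.5 - cy) / ry)^2 <= 1
  (gx[inside] - 1L) * h + gy[inside]
}

# Jittered square-grid placement with guaranteed pairwise separation.
# Returns a data.frame of centres; errors when n does not fit.
place_on_grid <- function(width, height, n, radius, what = "objects") {
  spacing <- 2 * max(radius) + 6
  margin <- max(radius) + 3
  xs <- seq(margin, width - margin, by = spacing)
  ys <- seq(margin, height - margin, by = spacing)
  if (length(xs) < 1L || length(ys) < 1L || length(xs) * length(ys) < n) {
    stop(sprintf("cannot place %d %s of radius %.0f px in a %dx%d field without overlap",
                 n, what, max(radius), width, height), call. = FALSE)
  }
  slots <- expand.grid(x = xs, y = ys)
  idx <- sample.int(nrow(slots), n)
  jit <- pmax(0, spacing / 2 - radius - 2)
  data.frame(
    x = slots$x[idx] + runif(n, -1, 1) * jit,
    y = slots$y[idx] + runif(n, -1, 1) * jit
  )
}
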