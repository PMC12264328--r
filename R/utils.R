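#' @importFrom rlang abort warn %||% .data
#' @importFrom stats var sd median quantile rnorm runif setNames plogis
#'   pnorm glm binomial predict coef dsignrank psignrank cor cov
#' @importFrom utils head tail
NULL

# Volumes are plain 3-D arrays dim = c(H, W, S) (rows, columns, slices) with a
# "spacing" attribute c(dx, dy, dz) in mm: dx/dy in-plane, dz slice thickness.

#' Attach voxel spacing to a volume array
#'
#' @param x 3-D numeric/logical array.
#' @param spacing numeric length-3, voxel spacing in mm (in-plane x, y, slice z).
#' @return `x` with a `spacing` attribute.
#' @export
with_spacing <- function(x, spacing) {
  stopifnot(is.array(x), length(dim(x)) == 3L, length(spacing) == 3L, all(spacing > 0))
  attr(x, "spacing") <- as.numeric(spacing)
  x
}

#' Voxel spacing of a volume
#' @param x array with a `spacing` attribute.
#' @param default spacing returned when `x` carries none.
#' @return numeric length-3 spacing (mm).
#' @export
spacing_of <- function(x, default = c(1, 1, 1)) {
  s <- attr(x, "spacing")
  if (is.null(s)) as.numeric(default) else as.numeric(s)
}

voxel_volume <- function(spacing) prod(spacing)

check_same_grid <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s must share the same dimensions (%s vs %s)", what,
                  paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
          class = "radstab_input_error")
  }
  invisible(TRUE)
}

check_probability <- function(p, what = "probabilities") {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(sprintf("%s must lie in [0, 1] with no missing values", what),
          class = "radstab_input_error")
  }
  invisible(TRUE)
}

check_binary <- function(m, what = "mask") {
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1, TRUE, FALSE))) {
    abort(sprintf("%s must be binary (0/1)", what), class = "radstab_input_error")
  }
  invisible(TRUE)
}

# Deterministic child seeds: one stream per (seed, index), kept below 2^31.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}
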