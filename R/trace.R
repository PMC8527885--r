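#' Epithelium trace
#'
#' An ordered polyline (in microns) marking the epithelial border of a
#' section, against which bacterial adherence and per-length rates are
#' measured. The arc length is the sum of Euclidean segment lengths.
#'
#' @param x_um,y_um Numeric vectors of ordered vertex coordinates (microns),
#'   at least two vertices, no repeated consecutive vertices.
#' @return An object of class `epithelium_trace` with fields `x_um`, `y_um`
#'   and `length_um`.
#' @examples
#' epithelium_trace(c(0, 3, 3), c(0, 4, 104))$length_um  # 5 + 100
#' @export
epithelium_trace <- function(x_um, y_um) {
  stopifnot(is.numeric(x_um), is.numeric(y_um), length(x_um) == length(y_um))
  if (length(x_um) < 2) stop("an epithelium trace needs at least 2 vertices")
  if (anyNA(x_um) || anyNA(y_um)) stop("trace vertices must be numeric")
  seg <- sqrt(diff(x_um)^2 + diff(y_um)^2)
  if (any(seg == 0)) stop("repeated consecutive vertices in trace")
  structure(list(x_um = x_um, y_um = y_um, length_um = sum(seg)),
            class = "epithelium_trace")
}

#' @export
print.epithelium_trace <- function(x, ...) {
  cat(sprintf("epithelium_trace: %d vertices, arc length %.2f um\n",
              length(x$x_um), x$length_um))
  invisible(x)
}

#' Load an epithelium trace from CSV
#'
#' Expects columns `x_um` and `y_um` (or takes the first two numeric columns
#' of a headerless/odd-named file) of ordered vertices.
#'
#' @param path CSV path.
#' @return An [epithelium_trace()].
#' @export
load_epithelium <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (all(c("x_um", "y_um") %in% names(df))) {
    x <- df$x_um; y <- df$y_um
  } else if (ncol(df) >= 2) {
    x <- df[[1]]; y <- df[[2]]
  } else {
    stop("trace CSV needs two coordinate columns")
  }
  if (!is.numeric(x) || !is.numeric(y)) stop("non-numeric rows in trace CSV")
  epithelium_trace(x, y)
}

#' Minimum distance from points to a polyline
#'
#' Euclidean distance from each point to the nearest point on any segment of
#' the trace (not just to its vertices).
#'
#' @param x_um,y_um Point coordinates (microns).
#' @param trace An [epithelium_trace()].
#' @return Numeric vector of distances in microns.
#' @export
dist_to_trace <- function(x_um, y_um, trace) {
  stopifnot(inherits(trace, "epithelium_trace"))
  n <- length(x_um)
  if (n == 0) return(numeric(0))
  vx <- trace$x_um; vy <- trace$y_um
  dmin <- rep(Inf, n)
  for (s in seq_len(length(vx) - 1)) {
    ax <- vx[s]; ay <- vy[s]
    bx <- vx[s + 1]; by <- vy[s + 1]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((x_um - ax) * dx + (y_um - ay) * dy) / len2))
    d2 <- (x_um - (ax + t * dx))^2 + (y_um - (ay + t * dy))^2
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}
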