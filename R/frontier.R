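#' Binned lower-percentile frontier of a point cloud
#'
#' X is split into contiguous equal-width bins spanning its observed range;
#' in every bin holding at least `min_bin_count` points, the frontier value
#' is the `percentile` (type-7) quantile of that bin's Y. Bins below the
#' count threshold are omitted. With the default 10th percentile this is the
#' empirical lower frontier summarising the best-observed speed-effort
#' trade-off.
#'
#' @param X,Y numeric vectors (e.g. reduced coordinates, or raw net transport
#'   speed and mean VeDBA).
#' @param percentile lower-quantile level, in (0, 0.5); default 0.10.
#' @param bin_width bin width in X units, default 0.1.
#' @param min_bin_count minimum points per retained bin, default 25.
#' @return object of class `frontier_curve`: data.frame `x_center`,
#'   `y_frontier`, `count`, with attributes `percentile` and `bin_width`.
#' @export
lower_frontier <- function(X, Y, percentile = 0.10, bin_width = 0.1,
                           min_bin_count = 25) {
  stopifnot(length(X) == length(Y), percentile > 0, percentile < 0.5,
            bin_width > 0)
  ok <- is.finite(X) & is.finite(Y)
  X <- X[ok]; Y <- Y[ok]
  if (!length(X)) stop("no finite points for frontier estimation")
  edges <- seq(min(X), max(X) + bin_width, by = bin_width)
  bin <- findInterval(X, edges, rightmost.closed = FALSE)
  rows <- lapply(sort(unique(bin)), function(b) {
    y <- Y[bin == b]
    if (length(y) < min_bin_count) return(NULL)
    data.frame(x_center = edges[b] + bin_width / 2,
               y_frontier = quantile(y, percentile, type = 7, names = FALSE),
               count = length(y))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no bin reaches min_bin_count = ", min_bin_count,
            "; empty frontier")
    out <- data.frame(x_center = numeric(), y_frontier = numeric(),
                      count = integer())
  }
  attr(out, "percentile") <- percentile
  attr(out, "bin_width") <- bin_width
  class(out) <- c("frontier_curve", "data.frame")
  out
}

#' @export
print.frontier_curve <- function(x, ...) {
  cat("<frontier_curve> ", nrow(x), " bins, ",
      100 * attr(x, "percentile"), "th percentile, bin width ",
      attr(x, "bin_width"), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Residual profile of a frontier against the reduced bound
#'
#' deltaY_k = y_frontier_k - Y_bound(x_center_k) for every retained bin.
#' Positive values place the empirical frontier above the bound; negative
#' values (possible where the fitted curve turns up) are retained as-is.
#'
#' @param curve a [lower_frontier()] result.
#' @param params an [hjb_params()] or fitted [fit_hjb()] object.
#' @return object of class `residual_profile`: data.frame `x_center`,
#'   `delta_y`, with a `summary` attribute (mean, median, range).
#' @export
frontier_residual <- function(curve, params) {
  if (!nrow(curve)) stop("empty frontier curve")
  dy <- curve$y_frontier - hjb_eval(curve$x_center, params)
  out <- data.frame(x_center = curve$x_center, delta_y = dy)
  attr(out, "summary") <- c(mean = mean(dy), median = median(dy),
                            min = min(dy), max = max(dy))
  class(out) <- c("residual_profile", "data.frame")
  out
}

#' @export
print.residual_profile <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<residual_profile> ", nrow(x), " bins; mean deltaY = ",
      signif(s["mean"], 4), ", median = ", signif(s["median"], 4),
      ", range [", signif(s["min"], 4), ", ", signif(s["max"], 4), "]\n",
      sep = "")
  invisible(x)
}
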