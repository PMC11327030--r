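#' Convert z positions to invasion depths
#'
#' Depth is measured from the top of the gel downwards:
#' `depth = orientation * (z - gel_top)`. Cells found above the gel top
#' (negative depth) are clamped to 0 with a warning; they sit on the gel
#' surface and have not invaded.
#'
#' @param z_positions Numeric vector of z positions, um.
#' @param gel_top z position of the gel surface, um.
#' @param orientation +1 when z increases downwards into the gel (default),
#'   -1 when the axis points up.
#' @return Numeric vector of depths (um, >= 0).
#' @export
depths_from_positions <- function(z_positions, gel_top, orientation = 1) {
  if (!all(is.finite(z_positions)))
    stop("z positions must be finite", call. = FALSE)
  depths <- orientation * (z_positions - gel_top)
  n_above <- sum(depths < 0)
  if (n_above > 0) {
    warning(n_above, " cell(s) above the gel top clamped to depth 0",
            call. = FALSE)
    depths[depths < 0] <- 0
  }
  depths
}

#' Invasion depth profile in fixed-width quartile bins
#'
#' Divides the invasion distance into consecutive bins of `bin_width` um
#' (default 250 um over a 0--750 um range, i.e. four equal 250-um quartile
#' bands over a ~1,000-um gel with the last analysed band closing at 750).
#' Bins are half-open `[a, b)`, except the final bin which is closed at
#' `max_depth`; depths beyond `max_depth` are clamped into the final bin
#' (and counted in `n_clamped`) so cells are conserved.
#'
#' @param depths Numeric vector of depths, um (>= 0).
#' @param bin_width Bin width, um (default 250).
#' @param max_depth Upper edge of the final bin, um (default 750); must be
#'   a multiple of `bin_width`.
#' @return An object of class `invasion_profile`: list with `counts`,
#'   `fractions`, `bin_edges`, `n_cells`, `n_clamped`, `median_depth`,
#'   `median_ci` (95% order-statistic interval), `mean_depth` and an
#'   `undefined_median` flag for empty input.
#' @examples
#' quartile_counts(c(100, 300, 600))$counts  # 1 1 1
#' @export
quartile_counts <- function(depths, bin_width = 250, max_depth = 750) {
  if (bin_width <= 0 || max_depth <= 0)
    stop("`bin_width` and `max_depth` must be > 0", call. = FALSE)
  n_bins <- max_depth / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("`max_depth` must be a multiple of `bin_width`", call. = FALSE)
  n_bins <- as.integer(round(n_bins))
  edges <- seq(0, max_depth, by = bin_width)
  if (any(depths < 0)) stop("depths must be >= 0", call. = FALSE)
  n_clamped <- sum(depths > max_depth)
  if (n_clamped > 0)
    message(n_clamped, " depth(s) beyond ", max_depth,
            " um clamped into the final bin")
  clamped <- pmin(depths, max_depth)
  if (length(clamped)) {
    bin <- pmin(findInterval(clamped, edges, rightmost.closed = TRUE), n_bins)
    counts <- tabulate(bin, n_bins)
  } else {
    counts <- integer(n_bins)
  }
  med <- if (length(depths)) median_depth(depths) else
    list(median = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  structure(
    list(counts = counts,
         fractions = if (length(depths)) counts / length(depths)
                     else rep(NA_real_, n_bins),
         bin_edges = edges, n_cells = length(depths), n_clamped = n_clamped,
         median_depth = med$median,
         median_ci = c(med$ci_low, med$ci_high),
         mean_depth = if (length(depths)) mean(depths) else NA_real_,
         undefined_median = length(depths) == 0),
    class = "invasion_profile"
  )
}

#' @export
print.invasion_profile <- function(x, ...) {
  cat(sprintf("<invasion_profile> %d cells, median %.0f um (95%% CI %.0f-%.0f)\n",
              x$n_cells, x$median_depth, x$median_ci[1], x$median_ci[2]))
  labs <- sprintf("[%g,%g%s", head(x$bin_edges, -1), tail(x$bin_edges, -1),
                  c(rep(")", length(x$counts) - 1), "]"))
  for (i in seq_along(x$counts))
    cat(sprintf("  %-12s %5d  (%.1f%%)\n", labs[i], x$counts[i],
                100 * x$fractions[i]))
  invisible(x)
}

#' Median invasion depth with order-statistic confidence interval
#'
#' Sample median plus the standard distribution-free confidence interval
#' from the binomial distribution of order statistics: the interval
#' `(x_(l), x_(u))` with `l = qbinom(alpha/2, n, 1/2)` and
#' `u = qbinom(1 - alpha/2, n, 1/2) + 1`.
#'
#' @param depths Numeric vector with at least one value.
#' @param conf Confidence level (default 0.95).
#' @return A list with `median`, `ci_low`, `ci_high`, `conf`, `n`.
#' @export
median_depth <- function(depths, conf = 0.95) {
  n <- length(depths)
  if (n < 1) stop("`depths` must contain at least one value", call. = FALSE)
  s <- sort(depths)
  alpha <- 1 - conf
  l <- max(1, qbinom(alpha / 2, n, 0.5))
  u <- min(n, qbinom(1 - alpha / 2, n, 0.5) + 1)
  list(median = median(s), ci_low = s[l], ci_high = s[u], conf = conf, n = n)
}
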