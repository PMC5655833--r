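#' Build a PAcIFIC-style precursor inclusion list
#'
#' Tiles a precursor m/z range with evenly stepped isolation-window centers.
#' With the instrument defaults (1.5 m/z step, 2.5 m/z isolation width)
#' consecutive windows overlap by 1 m/z, so every precursor falls inside at
#' least one window; the 501-552 m/z range yields 35 centers.
#'
#' @param range_start,range_end First and last precursor m/z of the assayed
#'   range. `range_end` must be >= `range_start`.
#' @param step Spacing between consecutive centers (m/z), default 1.5.
#' @param isolation_width Width of each isolation window (m/z), default 2.5.
#' @return An object of class `inclusion_list`: a list with `centers` (numeric
#'   vector), `isolation_width`, `step`, `overlap` (= width - step), and the
#'   window bounds `lower`/`upper`.
#' @examples
#' il <- build_inclusion_list(501, 552)
#' length(il$centers)  # 35
#' il$overlap          # 1
#' @export
build_inclusion_list <- function(range_start, range_end, step = 1.5,
                                 isolation_width = 2.5) {
  if (!is.numeric(range_start) || !is.numeric(range_end) ||
      range_start < 0 || range_end < 0)
    stop("m/z range bounds must be non-negative numbers")
  if (range_end < range_start)
    stop("range_end must be >= range_start")
  if (!is.numeric(step) || step <= 0)
    stop("step must be > 0")
  if (!is.numeric(isolation_width) || isolation_width <= 0)
    stop("isolation_width must be > 0")
  if (step > isolation_width + 1e-9)
    warning("step exceeds isolation width: consecutive windows leave gaps")

  n <- floor((range_end - range_start) / step) + 1L
  centers <- range_start + step * (seq_len(n) - 1L)
  structure(
    list(centers = centers,
         isolation_width = isolation_width,
         step = step,
         overlap = isolation_width - step,
         lower = centers - isolation_width / 2,
         upper = centers + isolation_width / 2),
    class = "inclusion_list")
}

#' @export
print.inclusion_list <- function(x, ...) {
  cat(sprintf("Inclusion list: %d centers, %.4g-%.4g m/z, step %.3g, width %.3g (overlap %.3g)\n",
              length(x$centers), min(x$centers), max(x$centers),
              x$step, x$isolation_width, x$overlap))
  invisible(x)
}
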