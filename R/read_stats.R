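#' Read-length summary statistics
#'
#' Computes the five per-file read-length statistics reported in the results
#' document: minimum, maximum, mean, median and mode. Two choices make the
#' output deterministic and directly usable as aligner parameters: the median
#' of an even-sized sample is the lower-middle *observed* length (no
#' interpolation), and mode ties resolve to the smallest length.
#'
#' @param lengths Non-empty vector of positive integer read lengths,
#'   typically `nchar(records$sequence)`.
#' @return A list of class `read_length_stats` with elements `min`, `max`,
#'   `mean`, `median`, `mode`.
#' @examples
#' compute_length_stats(c(50, 50, 75))
#' @export
compute_length_stats <- function(lengths) {
  if (length(lengths) == 0L) {
    abort_usage("cannot compute read-length statistics of an empty library")
  }
  if (any(lengths < 1)) abort_usage("read lengths must be positive")
  lengths <- as.integer(lengths)
  sorted <- sort(lengths)
  n <- length(sorted)
  tab <- tabulate(sorted)                       # counts indexed by length
  mode_len <- which.max(tab)                    # ties -> smallest length
  structure(
    list(min = sorted[1L],
         max = sorted[n],
         mean = mean(sorted),
         median = as.numeric(sorted[ceiling(n / 2)]),
         mode = as.integer(mode_len)),
    class = "read_length_stats")
}

#' @export
print.read_length_stats <- function(x, ...) {
  cat(sprintf("read length: min %d, max %d, mean %.3f, median %g, mode %d\n",
              x$min, x$max, x$mean, x$median, x$mode))
  invisible(x)
}
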