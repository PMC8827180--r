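#' Derive a deterministic child seed
#'
#' All stochastic stages draw their RNG streams from child seeds derived from
#' a single user-supplied seed, so that a run is reproducible end to end and
#' stages do not share (or disturb) a global stream.
#'
#' @param seed Integer master seed.
#' @param tag Character tag naming the consumer (e.g. `"stability"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, keeps results inside R's integer range
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# complete-case filter on a set of columns; returns the filtered data plus the
# number of rows dropped (logged by callers, per the complete-case-per-analysis
# policy)
complete_cases_on <- function(data, columns) {
  keep <- stats::complete.cases(data[, columns, drop = FALSE])
  list(data = data[keep, , drop = FALSE], n_dropped = sum(!keep))
}
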