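#' Per-window snapshot series of active nodes and edges
#'
#' The sole data structure the inference consumes: one row per aggregation
#' window with the window start time, the observed number of active nodes
#' `n_active` (nodes with at least one contact) and the number of distinct
#' contact pairs `m_edges`.
#'
#' @param window_start Numeric vector of window start times (seconds).
#' @param n_active Integer-valued vector of active-node counts N_t, >= 0.
#' @param m_edges Integer-valued vector of edge counts M_t, >= 0.
#' @return A data frame of class `"snapshot_series"`.
#' @export
snapshot_series <- function(window_start, n_active, m_edges) {
  if (length(n_active) != length(m_edges) ||
      length(window_start) != length(n_active))
    stop("window_start, n_active and m_edges must have equal length",
         call. = FALSE)
  if (any(n_active < 0) || any(m_edges < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any((n_active == 0) != (m_edges == 0)))
    stop("N_t = 0 must hold exactly when M_t = 0", call. = FALSE)
  if (any(m_edges > n_active * (n_active - 1) / 2))
    stop("M_t exceeds the complete-graph bound N_t(N_t-1)/2", call. = FALSE)
  structure(
    data.frame(window_start = as.numeric(window_start),
               n_active = as.integer(round(n_active)),
               m_edges = as.integer(round(m_edges))),
    class = c("snapshot_series", "data.frame"))
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat("Snapshot series:", nrow(x), "windows\n")
  if (nrow(x) > 0)
    cat(sprintf("  N in [%d, %d], M in [%d, %d]\n",
                min(x$n_active), max(x$n_active),
                min(x$m_edges), max(x$m_edges)))
  NextMethod()
}

.as_series <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("n_active", "m_edges") %in% names(series)))
    stop("series must be a snapshot_series (columns n_active, m_edges)",
         call. = FALSE)
  series
}
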