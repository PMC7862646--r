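## Readers and writers: SocioPatterns-style tij contact event lists,
## windowed snapshot series, and the CSV result tables.

#' Read a contact event list in tij format
#'
#' Parses whitespace-separated lines of `t i j` (timestamp in seconds, two
#' node identifiers). The `"tij"` dialect requires exactly three columns;
#' `"tij_meta"` uses the first three of at least three. Node identifiers are
#' opaque strings; pairs are unordered. Gzip-compressed files are accepted.
#'
#' @param path Path to a plain-text (optionally gzipped) event list.
#' @param dialect `"tij"` or `"tij_meta"`.
#' @return Data frame of class `"contact_events"` with numeric `t` and
#'   character `i`, `j`, sorted by time; duplicate lines are preserved
#'   (deduplication happens at windowing).
#' @export
read_contacts <- function(path, dialect = c("tij", "tij_meta")) {
  dialect <- match.arg(dialect)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no events in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  bad <- if (dialect == "tij") which(nf != 3) else which(nf < 3)
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path, ": '", lines[bad[1]], "'",
         call. = FALSE)
  t <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1)))
  if (anyNA(t))
    stop("non-numeric timestamp at line ", which(is.na(t))[1], " in ", path,
         call. = FALSE)
  i <- vapply(fields, `[[`, "", 2)
  j <- vapply(fields, `[[`, "", 3)
  self <- which(i == j)
  if (length(self))
    stop("self-contact at line ", self[1], " in ", path, call. = FALSE)
  ord <- order(t)
  structure(data.frame(t = t[ord], i = i[ord], j = j[ord],
                       stringsAsFactors = FALSE),
            class = c("contact_events", "data.frame"))
}

#' Aggregate contact events into a windowed snapshot series
#'
#' Windows are half-open intervals `[origin + k*width, origin + (k+1)*width)`.
#' Within a window an edge exists for each unordered node pair with at least
#' `min_events` events; N_t counts the nodes incident to at least one edge
#' and M_t the distinct pairs. Independent of input event ordering.
#'
#' @param events A `"contact_events"` data frame (or any data frame with
#'   columns t, i, j).
#' @param width Window length in seconds (default 600, i.e. 10 minutes).
#' @param origin First window start; default: the earliest event time
#'   floored to a multiple of `width`. Events before `origin` are dropped.
#' @param drop_empty Drop windows with no edges (default `TRUE`); when
#'   `FALSE` they appear as (0, 0) rows.
#' @param time_range Optional `c(start, end)` restriction, half-open; also
#'   fixes the window span when `drop_empty = FALSE`.
#' @param min_events Minimum events per pair per window for an edge
#'   (default 1).
#' @return A [snapshot_series()].
#' @export
build_snapshot_series <- function(events, width = 600, origin = NULL,
                                  drop_empty = TRUE, time_range = NULL,
                                  min_events = 1) {
  stopifnot(is.data.frame(events), all(c("t", "i", "j") %in% names(events)),
            width > 0, min_events >= 1)
  if (nrow(events) == 0) stop("empty event list", call. = FALSE)
  t <- as.numeric(events$t)
  i <- as.character(events$i)
  j <- as.character(events$j)
  if (!is.null(time_range)) {
    keep <- t >= time_range[1] & t < time_range[2]
    t <- t[keep]; i <- i[keep]; j <- j[keep]
    if (length(t) == 0) stop("no events inside time_range", call. = FALSE)
  }
  if (is.null(origin)) origin <- floor(min(t) / width) * width
  keep <- t >= origin
  t <- t[keep]; i <- i[keep]; j <- j[keep]
  win <- floor((t - origin) / width)
  a <- pmin(i, j)
  b <- pmax(i, j)
  key <- paste(win, a, b, sep = "\r")
  cnt <- table(key)
  kept <- names(cnt)[cnt >= min_events]
  parts <- strsplit(kept, "\r", fixed = TRUE)
  ewin <- as.numeric(vapply(parts, `[[`, "", 1))
  ea <- vapply(parts, `[[`, "", 2)
  eb <- vapply(parts, `[[`, "", 3)
  last_win <- if (!is.null(time_range))
    ceiling((time_range[2] - origin) / width) - 1 else max(win)
  all_win <- 0:last_win
  m <- as.integer(table(factor(ewin, levels = all_win)))
  n <- vapply(all_win, function(w) {
    sel <- ewin == w
    length(unique(c(ea[sel], eb[sel])))
  }, integer(1))
  if (drop_empty) {
    nz <- m > 0
    all_win <- all_win[nz]; m <- m[nz]; n <- n[nz]
  }
  snapshot_series(window_start = origin + all_win * width,
                  n_active = n, m_edges = m)
}

## ---- result tables --------------------------------------------------------

.schemas <- list(
  series = c("window_start", "n_active", "m_edges"),
  summary = c("parameter", "mean", "ci_low", "ci_high", "prior"),
  report = c("window_start", "N", "M", "prob_regime1_mean", "prob_ci_low",
             "prob_ci_high", "label", "np_hat", "np_lo", "np_hi",
             "kappa_hat", "kappa_lo", "kappa_hi", "density"),
  truth = c("window_start", "state", "np_true", "kappa_true", "N", "M"),
  draws = c("chain", "iter", "n_potential", "kappa", "sigma1", "sigma2",
            "p11", "p22"))

.check_schema <- function(df, what, path) {
  missing <- setdiff(.schemas[[what]], names(df))
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df[, .schemas[[what]], drop = FALSE]
}

#' Write a snapshot series to CSV
#' @param series A [snapshot_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_snapshot_series <- function(series, path) {
  utils::write.csv(as.data.frame(.as_series(series)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a snapshot series from CSV
#'
#' Columns are matched by header name, so column order is free; a missing
#' column is an error naming it.
#'
#' @param path CSV path with columns window_start, n_active, m_edges.
#' @return A [snapshot_series()].
#' @export
read_snapshot_series <- function(path) {
  df <- .check_schema(utils::read.csv(path), "series", path)
  snapshot_series(df$window_start, df$n_active, df$m_edges)
}

#' Write posterior draws to CSV
#'
#' Long format, one row per draw: chain, iter and the six parameters.
#'
#' @param samples A `"posterior_samples"` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(samples, path) {
  stopifnot(inherits(samples, "posterior_samples"))
  tab <- do.call(rbind, lapply(seq_along(samples$chains), function(ch)
    data.frame(chain = ch, iter = seq_len(nrow(samples$chains[[ch]])),
               samples$chains[[ch]])))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read posterior draws from CSV
#'
#' Reconstructs a `"posterior_samples"` object from a [write_draws()] file.
#' The prior specification is not stored in the CSV and must be supplied
#' (typically [default_priors()] of the fitted series); acceptance rates
#' are not recoverable and are set to `NA`.
#'
#' @param path CSV path.
#' @param priors A [prior_spec()].
#' @return A `"posterior_samples"` object.
#' @export
read_draws <- function(path, priors) {
  stopifnot(inherits(priors, "prior_spec"))
  df <- .check_schema(utils::read.csv(path), "draws", path)
  chains <- unname(lapply(split(df, df$chain), function(d) {
    m <- as.matrix(d[order(d$iter), .theta_names])
    rownames(m) <- NULL
    m
  }))
  rhat <- vapply(seq_along(.theta_names), function(k)
    .split_rhat(lapply(chains, function(m) m[, k])), numeric(1))
  names(rhat) <- .theta_names
  structure(list(chains = chains, rhat = rhat,
                 acceptance = rep(NA_real_, length(chains)),
                 priors = priors, seed = NA_integer_,
                 n_chains = length(chains),
                 n_keep = nrow(chains[[1]]), n_burn = NA_integer_,
                 sampler = "unknown",
                 converged = all(rhat < 1.05, na.rm = TRUE)),
            class = "posterior_samples")
}

#' Write a named list of result tables to a directory
#'
#' Each element is written as `<name>.csv`. Recognised names (series,
#' summary, report, truth, draws) round-trip through [read_results()].
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_results <- function(tables, path) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables))
    utils::write.csv(as.data.frame(tables[[nm]]),
                     file.path(path, paste0(nm, ".csv")), row.names = FALSE)
  invisible(path)
}

#' Read result tables from a directory
#'
#' Reads every `*.csv` in the directory; files whose names match a known
#' schema are validated (an error names any missing column) and selected
#' by header, so column order in the file does not matter.
#'
#' @param path Directory written by [write_results()].
#' @return Named list of data frames.
#' @export
read_results <- function(path) {
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no CSV files in ", path, call. = FALSE)
  out <- lapply(files, function(f) {
    df <- utils::read.csv(f)
    what <- sub("\\.csv$", "", basename(f))
    if (what %in% names(.schemas)) df <- .check_schema(df, what, f)
    df
  })
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}
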