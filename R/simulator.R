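## Generative simulator for regime-switching temporal contact networks.
## Ground truth is the two-state Markov sequence plus the latent
## (N_p,t, kappa_t) paths; observations are per-window (N_t, M_t) counts
## realised from per-pair Bernoulli contacts.

#' Simulation configuration
#'
#' Study conditions for the regime-switching generator. In a Regime-1 window
#' the potential population decays multiplicatively (`np_t = decay * np_{t-1}`)
#' while kappa sits at its base value; in a Regime-2 window kappa decays and
#' the population sits at its base. The decay default 0.95 per window matches
#' the validation design the model is calibrated against.
#'
#' @param n_potential_base Base potential population, integer >= 2.
#' @param kappa_base Base overall activity, in (0, 1].
#' @param p11,p22 Regime stay-probabilities, in (0, 1).
#' @param decay Per-window multiplicative decay of the active latent
#'   parameter, in (0, 1]; default 0.95.
#' @param n_windows Number of windows T >= 1.
#' @param init_p1 Initial probability of Regime 1; default 0.5.
#' @param seed Optional integer seed; `simulate_series()` sets it when given.
#' @param redraw_activities If `TRUE` (default) node activities are redrawn
#'   independently every window, matching the ensemble expectations exactly;
#'   if `FALSE` a fixed activity vector persists across windows.
#' @param window_width Window length in seconds used for timestamps and
#'   optional tij output; default 600.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_potential_base, kappa_base, p11, p22,
                       decay = 0.95, n_windows = 200, init_p1 = 0.5,
                       seed = NULL, redraw_activities = TRUE,
                       window_width = 600) {
  stopifnot(n_potential_base >= 2, kappa_base > 0, kappa_base <= 1,
            p11 >= 0, p11 <= 1, p22 >= 0, p22 <= 1,
            decay > 0, decay <= 1, n_windows >= 1,
            init_p1 >= 0, init_p1 <= 1, window_width > 0)
  structure(list(n_potential_base = n_potential_base,
                 kappa_base = kappa_base, p11 = p11, p22 = p22,
                 decay = decay, n_windows = as.integer(n_windows),
                 init_p1 = init_p1, seed = seed,
                 redraw_activities = isTRUE(redraw_activities),
                 window_width = window_width),
            class = "sim_config")
}

#' Sample a two-state Markov regime sequence
#'
#' First state is Regime 1 with probability `init_p1`; subsequent states stay
#' in the current regime with probability `p11` (from 1) or `p22` (from 2).
#'
#' @inheritParams sim_config
#' @return Integer vector of states in \{1, 2\}, length `n_windows`.
#' @export
sample_state_sequence <- function(p11, p22, n_windows, init_p1 = 0.5) {
  stopifnot(p11 >= 0, p11 <= 1, p22 >= 0, p22 <= 1,
            init_p1 >= 0, init_p1 <= 1, n_windows >= 1)
  s <- integer(n_windows)
  s[1] <- if (stats::runif(1) < init_p1) 1L else 2L
  u <- stats::runif(n_windows)
  for (t in seq_len(n_windows)[-1]) {
    stay <- if (s[t - 1] == 1L) p11 else p22
    s[t] <- if (u[t] < stay) s[t - 1] else 3L - s[t - 1]
  }
  s
}

#' Evolve the latent population and activity paths
#'
#' Applies the regime rule window by window, starting from the base values:
#' a Regime-1 window multiplies the population by `decay` and resets kappa to
#' its base; a Regime-2 window multiplies kappa by `decay` and resets the
#' population. Paths are kept as real numbers; rounding happens only when a
#' snapshot graph is realised.
#'
#' @param states Integer vector of regimes in \{1, 2\}.
#' @inheritParams sim_config
#' @return List with numeric `np_path` and `kappa_path`, same length as
#'   `states`.
#' @export
evolve_latent_parameters <- function(states, n_potential_base, kappa_base,
                                     decay = 0.95) {
  stopifnot(all(states %in% c(1L, 2L)), decay > 0, decay <= 1)
  n <- length(states)
  np <- numeric(n)
  kap <- numeric(n)
  np_prev <- n_potential_base
  kap_prev <- kappa_base
  for (t in seq_len(n)) {
    if (states[t] == 1L) {
      np[t] <- decay * np_prev
      kap[t] <- kappa_base
    } else {
      kap[t] <- decay * kap_prev
      np[t] <- n_potential_base
    }
    np_prev <- np[t]
    kap_prev <- kap[t]
  }
  list(np_path = np, kappa_path = kap)
}

## Row/column indices of the upper triangle of an np x np matrix,
## i.e. all unordered node pairs.
.pair_indices <- function(np) {
  if (np < 2) return(list(i = integer(0), j = integer(0)))
  list(i = rep.int(seq_len(np - 1L), rev(seq_len(np - 1L))),
       j = sequence(rev(seq_len(np - 1L)), from = seq_len(np - 1L) + 1L))
}

#' Realise one snapshot network
#'
#' Draws (or takes) uniform activities, realises each unordered pair as an
#' independent Bernoulli contact with probability `kappa * a_i * a_j`, and
#' counts active nodes and distinct edges.
#'
#' @param n_potential Potential population; rounded to an integer >= 1.
#' @param kappa Overall activity, in (0, 1].
#' @param activities Optional fixed activity vector of length >=
#'   `round(n_potential)`; drawn uniform on \[0, 1\] when `NULL`.
#' @param return_edges If `TRUE`, also return the realised edge list.
#' @return List with `n_active`, `m_edges`, and (optionally) a two-column
#'   `edges` matrix of node indices.
#' @export
sample_snapshot <- function(n_potential, kappa, activities = NULL,
                            return_edges = FALSE) {
  .check_kappa(kappa, max = 1)
  np <- max(1L, as.integer(round(n_potential)))
  if (np == 1L) {
    out <- list(n_active = 0L, m_edges = 0L)
    if (return_edges) out$edges <- matrix(integer(0), 0, 2,
                                          dimnames = list(NULL, c("i", "j")))
    return(out)
  }
  a <- if (is.null(activities)) stats::runif(np) else activities[seq_len(np)]
  idx <- .pair_indices(np)
  hit <- stats::runif(length(idx$i)) < kappa * a[idx$i] * a[idx$j]
  i <- idx$i[hit]
  j <- idx$j[hit]
  out <- list(n_active = length(unique(c(i, j))), m_edges = length(i))
  if (return_edges) out$edges <- cbind(i = i, j = j)
  out
}

#' Simulate a regime-switching snapshot series with ground truth
#'
#' Composes [sample_state_sequence()], [evolve_latent_parameters()] and
#' [sample_snapshot()] into a full synthetic dataset: the realised
#' [snapshot_series()] plus the true state sequence and latent parameter
#' paths. Reproducible under the seed recorded in the configuration.
#'
#' @param config A [sim_config()].
#' @param keep_edges Keep per-window edge lists (needed by [write_tij()]).
#' @return A list of class `"synthetic_dataset"` with elements `states`,
#'   `np_path`, `kappa_path`, `series`, `config` and optionally `edges`.
#' @export
simulate_series <- function(config, keep_edges = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  states <- sample_state_sequence(config$p11, config$p22,
                                  config$n_windows, config$init_p1)
  paths <- evolve_latent_parameters(states, config$n_potential_base,
                                    config$kappa_base, config$decay)
  acts <- if (!config$redraw_activities)
    stats::runif(config$n_potential_base)
  n <- integer(config$n_windows)
  m <- integer(config$n_windows)
  edges <- if (keep_edges) vector("list", config$n_windows)
  for (t in seq_len(config$n_windows)) {
    snap <- sample_snapshot(paths$np_path[t], paths$kappa_path[t],
                            activities = acts, return_edges = keep_edges)
    n[t] <- snap$n_active
    m[t] <- snap$m_edges
    if (keep_edges) edges[[t]] <- snap$edges
  }
  out <- list(states = states,
              np_path = paths$np_path,
              kappa_path = paths$kappa_path,
              series = snapshot_series(
                window_start = (seq_len(config$n_windows) - 1) *
                  config$window_width,
                n_active = n, m_edges = m),
              config = config)
  if (keep_edges) out$edges <- edges
  structure(out, class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic regime-switching dataset:", length(x$states), "windows\n")
  cat(sprintf("  regime 1 in %d windows; base N_p = %g, base kappa = %g\n",
              sum(x$states == 1L), x$config$n_potential_base,
              x$config$kappa_base))
  invisible(x)
}

#' Write a synthetic dataset as a tij contact event list
#'
#' Emits one 20-second contact tick per realised edge per window, timestamped
#' at the window start, in whitespace-separated `t i j` format. Windowing the
#' file back with the same width and origin reproduces the simulated
#' (N_t, M_t) exactly.
#'
#' @param dataset A `"synthetic_dataset"` produced with `keep_edges = TRUE`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tij <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (is.null(dataset$edges))
    stop("dataset was simulated without keep_edges = TRUE", call. = FALSE)
  ws <- dataset$series$window_start
  rows <- lapply(seq_along(dataset$edges), function(t) {
    e <- dataset$edges[[t]]
    if (is.null(e) || nrow(e) == 0) return(NULL)
    data.frame(t = ws[t], i = e[, 1], j = e[, 2])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(t = numeric(0), i = integer(0),
                                      j = integer(0))
  utils::write.table(tab, path, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulator ground truth as CSV
#'
#' @param dataset A `"synthetic_dataset"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  utils::write.csv(
    data.frame(window_start = dataset$series$window_start,
               state = dataset$states,
               np_true = dataset$np_path,
               kappa_true = dataset$kappa_path,
               N = dataset$series$n_active,
               M = dataset$series$m_edges),
    path, row.names = FALSE)
  invisible(path)
}
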