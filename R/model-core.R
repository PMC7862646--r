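## Closed-form moments of the dynamic hidden-variable model and the two
## regime curves. All functions are vectorised and treat the potential
## population N_p as a continuous real >= 1: the inverse map from an edge
## count returns non-integers and the likelihood is evaluated at real N_p.

.check_kappa <- function(kappa, max = 2) {
  if (any(!is.finite(kappa)) || any(kappa <= 0) || any(kappa > max))
    stop("kappa must lie in (0, ", max, "]", call. = FALSE)
  invisible(kappa)
}

.check_np <- function(n_potential, min = 1) {
  if (any(!is.finite(n_potential)) || any(n_potential < min))
    stop("n_potential must be >= ", min, call. = FALSE)
  invisible(n_potential)
}

## (1 - kappa/2)^n_potential, computed through exp(n*log1p(-kappa/2)) so that
## large real exponents do not lose precision.
.decay_pow <- function(kappa, n_potential) {
  exp(n_potential * log1p(-kappa / 2))
}

#' Pairwise contact probability in the hidden-variable model
#'
#' The probability that two nodes with intrinsic activities (fitness values)
#' `a_i` and `a_j` are in contact within a snapshot window is
#' `kappa * a_i * a_j`, where `kappa` modulates the overall activity rhythm
#' of the whole system (schedule, circadian effects).
#'
#' @param kappa Overall activity modulator, in (0, 1].
#' @param a_i,a_j Node activities, in \[0, 1\].
#' @return Contact probability in \[0, 1\]; vectorised with recycling.
#' @examples
#' edge_probability(0.3, 0.5, 0.5) # 0.075
#' @export
edge_probability <- function(kappa, a_i, a_j) {
  .check_kappa(kappa, max = 1)
  if (any(a_i < 0 | a_i > 1) || any(a_j < 0 | a_j > 1))
    stop("activities must lie in [0, 1]", call. = FALSE)
  kappa * a_i * a_j
}

#' Expected fraction of isolated nodes
#'
#' Fraction q0 of the potential population with no contact in a window, under
#' uniform activities on \[0, 1\]:
#' `q0 = (2/(kappa*N_p)) * (1 - (1 - kappa/2)^N_p)`.
#'
#' @param kappa Overall activity modulator, in (0, 2\] (the physical model
#'   uses (0, 1]; values up to 2 keep the base `1 - kappa/2` non-negative).
#' @param n_potential Potential population N_p, real, >= 1.
#' @return q0 in \[0, 1\].
#' @examples
#' isolated_fraction(1, 2) # 0.75
#' @export
isolated_fraction <- function(kappa, n_potential) {
  .check_kappa(kappa)
  .check_np(n_potential)
  2 / (kappa * n_potential) * (1 - .decay_pow(kappa, n_potential))
}

#' Expected number of active nodes
#'
#' Expected number of nodes with at least one contact,
#' `N = N_p * (1 - q0(kappa, N_p))`. A single potential node is always
#' isolated, so `n_potential = 1` gives 0.
#'
#' @inheritParams isolated_fraction
#' @return Expected active-node count N, with 0 <= N <= N_p.
#' @export
expected_active_nodes <- function(kappa, n_potential) {
  n_potential * (1 - isolated_fraction(kappa, n_potential))
}

#' Expected number of edges
#'
#' `M = kappa * N_p * (N_p - 1) / 8`: each of the N_p(N_p-1)/2 pairs is
#' realised with probability kappa * E[a]^2 = kappa/4.
#'
#' @inheritParams isolated_fraction
#' @return Expected edge count M >= 0, zero iff `n_potential = 1`.
#' @examples
#' expected_edges(0.3, 126) # 590.625
#' @export
expected_edges <- function(kappa, n_potential) {
  .check_kappa(kappa)
  .check_np(n_potential)
  kappa * n_potential * (n_potential - 1) / 8
}

#' Mean degree over the potential population
#'
#' Average degree including isolated nodes,
#' `kbar = (kappa/4) * (N_p - 1) = 2 M / N_p`.
#'
#' @inheritParams isolated_fraction
#' @return Mean degree >= 0.
#' @export
mean_degree <- function(kappa, n_potential) {
  .check_kappa(kappa)
  .check_np(n_potential)
  kappa / 4 * (n_potential - 1)
}

#' Potential population implied by an edge count
#'
#' Inverts the expected-edge relation in N_p at fixed activity:
#' `N_p(M, kappa) = (1 + sqrt(1 + 32 M / kappa)) / 2`.
#'
#' @param m_edges Observed (or expected) edge count, >= 0.
#' @param kappa Overall activity modulator, in (0, 1].
#' @return Real N_p >= 1; exact inverse of [expected_edges()] in its second
#'   argument.
#' @export
invert_population <- function(m_edges, kappa) {
  .check_kappa(kappa, max = 1)
  if (any(m_edges < 0)) stop("m_edges must be >= 0", call. = FALSE)
  (1 + sqrt(1 + 32 * m_edges / kappa)) / 2
}

#' Overall activity implied by an edge count
#'
#' Inverts the expected-edge relation in kappa at fixed population:
#' `kappa(M, N_p) = 8 M / (N_p (N_p - 1))`. The raw value is returned even
#' when it exceeds 1 (inconsistent input); callers decide validity, which
#' lets the likelihood be evaluated slightly outside the physical region.
#'
#' @param m_edges Edge count, >= 0.
#' @param n_potential Potential population, > 1.
#' @return Implied kappa >= 0, not clamped.
#' @export
invert_activity <- function(m_edges, n_potential) {
  if (any(m_edges < 0)) stop("m_edges must be >= 0", call. = FALSE)
  if (any(n_potential <= 1))
    stop("n_potential must be > 1 to invert for kappa", call. = FALSE)
  8 * m_edges / (n_potential * (n_potential - 1))
}

#' Regime-1 (population-driven) densification curve
#'
#' Expected number of active nodes as a function of the edge count when the
#' population N_p varies and the activity kappa is constant:
#' `h1(M; kappa) = N(kappa, N_p(M, kappa))`. Strictly increasing in M.
#'
#' @inheritParams invert_population
#' @return Expected active-node count on the population-driven curve.
#' @export
regime1_curve <- function(m_edges, kappa) {
  expected_active_nodes(kappa, invert_population(m_edges, kappa))
}

#' Regime-2 (activity-driven) densification curve
#'
#' Expected number of active nodes as a function of the edge count when the
#' activity kappa varies and the population N_p is constant:
#' `h2(M; N_p) = N(kappa(M, N_p), N_p)`. Bounded above by N_p. The implied
#' kappa must keep the base `1 - kappa/2` non-negative; larger edge counts
#' are a domain error.
#'
#' @inheritParams invert_activity
#' @return Expected active-node count on the activity-driven curve.
#' @export
regime2_curve <- function(m_edges, n_potential) {
  k <- invert_activity(m_edges, n_potential)
  if (any(k > 2))
    stop("implied kappa = 8M/(Np(Np-1)) exceeds 2; h2 not evaluable",
         call. = FALSE)
  out <- numeric(length(k))
  pos <- k > 0
  if (any(pos))
    out[pos] <- expected_active_nodes(k[pos],
                                      rep_len(n_potential, length(k))[pos])
  out
}

#' Expected network density
#'
#' Expected density 2M/(N(N-1)) in closed form:
#' `(kappa/4) * (1/(1-q0))^2 * (1 + q0/(N-1))`.
#' At fixed kappa the density approaches kappa/4 monotonically as N_p grows;
#' at fixed N_p it is unbounded above in kappa (non-monotonic behaviour).
#'
#' @inheritParams isolated_fraction
#' @return Expected density; requires the expected active-node count to
#'   exceed 1.
#' @export
expected_density <- function(kappa, n_potential) {
  q0 <- isolated_fraction(kappa, n_potential)
  n <- (1 - q0) * n_potential
  if (any(n <= 1))
    stop("expected active nodes must exceed 1 for density", call. = FALSE)
  kappa / 4 * (1 / (1 - q0))^2 * (1 + q0 / (n - 1))
}
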