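#' Specification of a bounded momentum random walk
#'
#' Defines a one-dimensional Markov-chain random walk on a path graph
#' \code{A - h_1 - ... - h_k - B} used to emulate spontaneous task-switching
#' dynamics. The walker never stays in place: at every step it moves to an
#' adjacent state, continuing its previous direction of movement with
#' probability \code{p_trans} and reversing otherwise. At an extreme state
#' (\code{A} or \code{B}) the single inward move is forced and becomes the
#' new direction.
#'
#' @param n_hidden Number of hidden states between the two extremes
#'   (typically 1 to 5).
#' @param p_trans Probability of repeating the previous movement direction;
#'   0.5 gives the most random walk, values near 1 a regular sweep.
#' @param n_steps Total number of steps to simulate.
#' @param seed Integer seed controlling the simulation.
#' @return An object of class \code{walk_spec}.
#' @export
walk_spec <- function(n_hidden, p_trans, n_steps = 1e5, seed = 1L) {
  if (!is.numeric(n_hidden) || length(n_hidden) != 1L || n_hidden < 1 ||
      n_hidden != round(n_hidden))
    stop("'n_hidden' must be a positive integer")
  if (!is.numeric(p_trans) || length(p_trans) != 1L || p_trans < 0 ||
      p_trans > 1)
    stop("'p_trans' must be a probability in [0, 1]")
  if (!is.numeric(n_steps) || n_steps < 1)
    stop("'n_steps' must be a positive count")
  structure(list(n_hidden = as.integer(n_hidden), p_trans = p_trans,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "walk_spec")
}

#' Simulate a bounded momentum random walk
#'
#' Positions are integer chain indices: 0 is extreme \code{A},
#' \code{n_hidden + 1} is extreme \code{B}. The walk starts at \code{A};
#' the first move (inward) is forced, as is every move taken from an
#' extreme, and a forced move resets the momentum direction.
#'
#' @param spec A \code{\link{walk_spec}}.
#' @return Integer vector of length \code{n_steps + 1} of positions.
#' @export
simulate_walk <- function(spec) {
  stopifnot(inherits(spec, "walk_spec"))
  k <- spec$n_hidden
  top <- k + 1L
  n <- spec$n_steps
  set.seed(spec$seed)
  keep <- stats::runif(n) < spec$p_trans
  pos <- integer(n + 1L)
  cur <- 0L
  dir <- 1L
  for (i in seq_len(n)) {
    if (cur == 0L) {
      dir <- 1L
    } else if (cur == top) {
      dir <- -1L
    } else if (!keep[i]) {
      dir <- -dir
    }
    cur <- cur + dir
    pos[i + 1L] <- cur
  }
  pos
}

#' Extreme-to-extreme passage durations of a walk
#'
#' Scans a position sequence and, for each crossing from one extreme to the
#' opposite one, returns the number of steps taken since the walker first
#' occupied the source extreme after the previous crossing. Intermediate
#' returns to the source extreme do not reset the count.
#'
#' @param positions Integer vector of chain positions as returned by
#'   \code{\link{simulate_walk}} (extremes are the minimum and maximum of
#'   the chain; position 0 and \code{max(positions)} by construction).
#' @param top Index of extreme B; defaults to the maximum observed position.
#' @return Integer vector of passage durations in steps (possibly empty).
#' @export
passage_durations <- function(positions, top = max(positions)) {
  ext <- positions == 0L | positions == top
  idx <- which(ext)
  if (length(idx) < 2L) return(integer(0))
  labs <- positions[idx]
  # keep only arrivals where the extreme differs from the previous extreme
  change <- c(TRUE, labs[-1L] != labs[-length(labs)])
  # segment starts at the FIRST occupation of each source extreme
  starts <- idx[change]
  if (length(starts) < 2L) return(integer(0))
  diff(starts)
}

#' Exact expected first-passage time between the extremes
#'
#' Solves the linear system of the direction-augmented Markov chain for the
#' expected number of steps from departure at one extreme to first arrival
#' at the other. States are (position, last-move direction) pairs; moves
#' from an extreme are forced inward.
#'
#' @param spec A \code{\link{walk_spec}}; only \code{n_hidden} and
#'   \code{p_trans} are used.
#' @return Expected number of steps (a single double).
#' @export
expected_passage_time <- function(spec) {
  stopifnot(inherits(spec, "walk_spec"))
  k <- spec$n_hidden
  p <- spec$p_trans
  top <- k + 1L
  # states: positions 0..top crossed with direction in {+1, -1};
  # E(s) = expected steps to reach 'top' from state s
  n_states <- 2L * (top + 1L)
  id <- function(pos, dir) pos + 1L + (if (dir < 0) top + 1L else 0L)
  A <- diag(n_states)
  b <- numeric(n_states)
  add <- function(A, row, pos, dir, w) {
    if (pos != top) A[row, id(pos, dir)] <- A[row, id(pos, dir)] - w
    A
  }
  for (dir in c(1L, -1L)) {
    for (pos in 0:top) {
      row <- id(pos, dir)
      if (pos == top) { b[row] <- 0; next }
      b[row] <- 1
      if (pos == 0L) {
        A <- add(A, row, 1L, 1L, 1)                 # forced inward
      } else {
        A <- add(A, row, pos + dir, dir, p)         # momentum kept
        A <- add(A, row, pos - dir, -dir, 1 - p)    # reversal
      }
    }
  }
  E <- tryCatch(solve(A, b), error = function(e)
    stop("expected passage time system is singular for p_trans = ", p))
  unname(E[id(0L, 1L)])
}

#' Scale-normalized duration distribution
#'
#' Divides durations by their sample mean and histograms them on a fixed
#' common support so distributions from different regimes are directly
#' comparable in shape. Mass beyond the support is folded into the last bin.
#'
#' @param durations Numeric vector of positive durations.
#' @param n_bins Number of histogram bins (default 25).
#' @param support Upper edge of the common support in mean-units
#'   (default 5; the first edge is 0).
#' @return A \code{duration_distribution}: list with \code{bin_edges} and
#'   \code{probabilities} (summing to 1).
#' @export
duration_distribution <- function(durations, n_bins = 25L, support = 5) {
  if (length(durations) < 1L) stop("need at least one duration")
  if (any(durations <= 0)) stop("durations must be positive")
  x <- durations / mean(durations)
  edges <- seq(0, support, length.out = n_bins + 1L)
  x[x >= support] <- support - 1e-12   # fold the tail into the last bin
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  structure(list(bin_edges = edges, probabilities = counts / sum(counts)),
            class = "duration_distribution")
}

#' Kullback-Leibler divergence between two binned distributions
#'
#' Computes \code{sum(p * log((p + eps) / (q + eps)))} after epsilon
#' smoothing and renormalization of both distributions, in nats.
#'
#' @param P,Q \code{duration_distribution} objects (or lists with matching
#'   \code{bin_edges} and \code{probabilities}).
#' @param epsilon Smoothing constant added to every bin before
#'   renormalization (default 1e-10).
#' @return KL divergence D(P || Q) in nats (non-negative).
#' @export
kl_divergence <- function(P, Q, epsilon = 1e-10) {
  if (!isTRUE(all.equal(P$bin_edges, Q$bin_edges)))
    stop("distributions must share identical bin edges")
  p <- P$probabilities + epsilon
  q <- Q$probabilities + epsilon
  p <- p / sum(p)
  q <- q / sum(q)
  ok <- p > 0
  sum(p[ok] * log(p[ok] / q[ok]))
}

#' KL divergence grid over random-walk parameters
#'
#' For every combination of transition probability and hidden-state count,
#' simulates a walk, extracts its passage-duration distribution, and
#' measures the KL divergence from an empirical distribution (empirical as
#' reference: D(empirical || simulated)). Also returns the mean KL per
#' transition probability across hidden-state counts.
#'
#' @param empirical A \code{duration_distribution} of observed run lengths.
#' @param p_trans_grid Numeric vector of transition probabilities.
#' @param n_hidden_grid Integer vector of hidden-state counts.
#' @param n_steps Steps per simulation (default 1e5).
#' @param seed Base seed; each grid cell uses a distinct derived seed.
#' @param epsilon Smoothing for \code{\link{kl_divergence}}.
#' @return List with \code{kl} (matrix, rows = p_trans, cols = n_hidden),
#'   \code{mean_kl} (named vector per p_trans), and the grids.
#' @export
randomness_grid <- function(empirical, p_trans_grid = seq(0.5, 0.9, by = 0.1),
                            n_hidden_grid = 1:5, n_steps = 1e5, seed = 1L,
                            epsilon = 1e-10) {
  if (length(p_trans_grid) < 1L || length(n_hidden_grid) < 1L)
    stop("parameter grids must be non-empty")
  kl <- matrix(NA_real_, length(p_trans_grid), length(n_hidden_grid),
               dimnames = list(p_trans = format(p_trans_grid),
                               n_hidden = format(n_hidden_grid)))
  for (i in seq_along(p_trans_grid)) {
    for (j in seq_along(n_hidden_grid)) {
      cell_seed <- (seed + 7919L * i + 104729L * j) %% .Machine$integer.max
      sp <- walk_spec(n_hidden_grid[j], p_trans_grid[i], n_steps, cell_seed)
      pos <- simulate_walk(sp)
      dur <- passage_durations(pos, top = sp$n_hidden + 1L)
      if (length(dur) == 0L)
        stop(sprintf("no complete crossing at (p_trans = %g, n_hidden = %d)",
                     p_trans_grid[i], n_hidden_grid[j]))
      sim <- duration_distribution(dur,
                                   n_bins = length(empirical$probabilities),
                                   support = max(empirical$bin_edges))
      kl[i, j] <- kl_divergence(empirical, sim, epsilon)
    }
  }
  list(kl = kl, mean_kl = stats::setNames(rowMeans(kl), format(p_trans_grid)),
       p_trans_grid = p_trans_grid, n_hidden_grid = n_hidden_grid,
       n_steps = n_steps, seed = seed)
}
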