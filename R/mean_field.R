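#' One step of the individual-based mean-field approximation
#'
#' The IBMFA tracks, for every node, the marginal probability
#' \eqn{s_i(t) = P(\sigma_i(t) = 1)} and neglects dynamical correlations:
#' the update sums, over all \eqn{2^{k_i}} regulator configurations with
#' \eqn{F_i = 1}, the product of the regulators' marginal probabilities.
#' Pinned nodes keep their imposed probability (0 or 1) exactly.
#'
#' This is the reference R implementation (a direct sum over truth-table
#' rows); \code{\link{ibmfa_run}} uses an equivalent compiled kernel.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param s numeric vector of activation probabilities in \eqn{[0, 1]}.
#' @param pins optional \code{\link{seed_set}}.
#' @return the updated probability state (entries clamped to \eqn{[0, 1]}).
#' @examples
#' net <- boolean_network(c("A", "B", "C"),
#'                        list("A", "B", c("A", "B")),
#'                        list(c(0, 1), c(0, 1), c(0, 0, 0, 1)))
#' ibmfa_step(net, c(0.5, 0.5, 0))["C"]  # AND of two independent 0.5 -> 0.25
#' @export
ibmfa_step <- function(net, s, pins = NULL) {
  s <- check_probability_state(net, s)
  pins <- as_seed_set(net, pins)
  n <- n_nodes(net)
  if (length(pins$node)) s[pins$node] <- pins$state
  nxt <- numeric(n)
  for (i in seq_len(n)) {
    r <- net$regulators[[i]]
    k <- length(r)
    rows_on <- which(net$functions[[i]] == 1L) - 1L
    if (!length(rows_on)) { nxt[i] <- 0; next }
    acc <- 0
    for (row in rows_on) {
      bits <- row_to_bits(row, k)
      acc <- acc + prod(ifelse(bits == 1L, s[r], 1 - s[r]))
    }
    nxt[i] <- min(max(acc, 0), 1)
  }
  if (length(pins$node)) nxt[pins$node] <- pins$state
  names(nxt) <- net$nodes
  nxt
}

check_probability_state <- function(net, s) {
  s <- as.numeric(s)
  if (length(s) == 1L) s <- rep(s, n_nodes(net))
  if (length(s) != n_nodes(net))
    stop(sprintf("probability state must have length %d", n_nodes(net)),
         call. = FALSE)
  if (any(is.na(s)) || any(s < 0 | s > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  s
}

#' Iterate the IBMFA for a fixed horizon
#'
#' Deterministic; per-step cost is \eqn{O(\sum_i 2^{k_i} k_i)}, i.e. linear
#' in the number of nodes and exponential in the in-degree. If the initial
#' state is fully deterministic (all entries 0/1), the mean-field trajectory
#' coincides bit-for-bit with the exact synchronous trajectory.
#'
#' @inheritParams ibmfa_step
#' @param s0 initial probability state (scalar recycled to all nodes).
#' @param t_max horizon \eqn{T \ge 0}.
#' @return numeric matrix \code{(t_max + 1) x N}; row \code{t + 1} is
#'   \eqn{\vec s(t)}.
#' @export
ibmfa_run <- function(net, s0, pins = NULL, t_max) {
  s0 <- check_probability_state(net, s0)
  pins <- as_seed_set(net, pins)
  if (t_max < 0) stop("`t_max` must be >= 0", call. = FALSE)
  traj <- cpp_ibmfa_run(net$regulators, net$functions, s0,
                        pins$node, pins$state, as.integer(t_max))
  colnames(traj) <- net$nodes
  traj
}

#' Probability of a configuration under independent marginals
#'
#' \eqn{P(\vec\sigma | \vec s) = \prod_i s_i^{\sigma_i} (1-s_i)^{1-\sigma_i}}.
#' Over all \eqn{2^N} configurations these probabilities sum to one.
#'
#' @param s probability state.
#' @param config 0/1 configuration of the same length.
#' @return probability in \eqn{[0, 1]}.
#' @export
configuration_probability <- function(s, config) {
  s <- as.numeric(s)
  config <- as.integer(config)
  if (length(s) != length(config))
    stop("`s` and `config` must have the same length", call. = FALSE)
  if (!all(config %in% c(0L, 1L)))
    stop("configuration entries must be 0/1", call. = FALSE)
  prod(ifelse(config == 1L, s, 1 - s))
}

#' Sample initial configurations from independent marginals
#'
#' Independent Bernoulli draws per node; pinned nodes are fixed to their
#' imposed state.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param s0 probability state (scalar recycled).
#' @param pins optional \code{\link{seed_set}}.
#' @param n number of configurations to draw.
#' @param seed optional RNG seed for reproducibility.
#' @return integer 0/1 matrix \code{n x N}.
#' @export
sample_initial_configuration <- function(net, s0, pins = NULL, n = 1L,
                                         seed = NULL) {
  s0 <- check_probability_state(net, s0)
  pins <- as_seed_set(net, pins)
  if (!is.null(seed)) set.seed(seed)
  N <- n_nodes(net)
  if (length(pins$node)) s0[pins$node] <- pins$state
  m <- matrix(as.integer(stats::runif(n * N) < rep(s0, each = n)), n, N,
              dimnames = list(NULL, net$nodes))
  if (length(pins$node)) m[, pins$node] <- rep(pins$state, each = n)
  m
}

#' Ensemble of exact trajectories from random initial conditions
#'
#' Draws \code{reps} initial configurations from the marginals \code{s0}
#' (pinned nodes fixed), simulates each exactly, and records the ensemble
#' mean trajectory \eqn{\bar\sigma_i(t)}.
#'
#' @inheritParams sample_initial_configuration
#' @param t_max horizon.
#' @param reps ensemble size \eqn{R \ge 1} (\eqn{\ge 2} for
#'   \code{\link{baseline_variance}}).
#' @param scheme update scheme, see \code{\link{simulate_trajectory}}.
#' @return an object of class \code{ensemble_run}: list with
#'   \code{trajectories} (array \code{reps x (t_max+1) x N}) and \code{mean}
#'   (matrix \code{(t_max+1) x N}).
#' @export
ensemble_run <- function(net, s0, pins = NULL, t_max, reps = 100L,
                         seed = NULL, scheme = "synchronous") {
  if (!is.null(seed)) set.seed(seed)
  inits <- sample_initial_configuration(net, s0, pins, n = reps)
  N <- n_nodes(net)
  arr <- array(NA_integer_, c(reps, t_max + 1L, N),
               dimnames = list(NULL, NULL, net$nodes))
  for (r in seq_len(reps)) {
    sd_r <- if (identical(scheme, "stochastic-async"))
      sample.int(.Machine$integer.max, 1L) else NULL
    arr[r, , ] <- simulate_trajectory(net, inits[r, ], t_max, pins,
                                      scheme = scheme, seed = sd_r)
  }
  structure(list(trajectories = arr, mean = apply(arr, c(2L, 3L), mean),
                 reps = reps, t_max = t_max), class = "ensemble_run")
}

#' Mean squared error of the IBMFA against an ensemble mean
#'
#' \eqn{e(t) = \frac{1}{N}\sum_i [s_i(t) - \bar\sigma_i(t)]^2}.
#'
#' @param mf IBMFA trajectory matrix from \code{\link{ibmfa_run}}.
#' @param ens an \code{\link{ensemble_run}} over the same horizon.
#' @return numeric vector \code{e} of length \code{t_max + 1}.
#' @export
ibmfa_mse <- function(mf, ens) {
  stopifnot(inherits(ens, "ensemble_run"))
  if (!identical(dim(mf), dim(ens$mean)))
    stop("mean-field and ensemble horizons/sizes do not match", call. = FALSE)
  rowMeans((mf - ens$mean)^2)
}

#' Leave-one-out variance baseline of an ensemble
#'
#' \eqn{b(t) = \frac{1}{RN}\sum_i \sum_r [\sigma_i^{(r)}(t) -
#' \frac{R\bar\sigma_i(t) - \sigma_i^{(r)}(t)}{R - 1}]^2}: the error that an
#' observer of a single realisation would make against the leave-one-out
#' ensemble mean. Zero at \code{t} iff all trajectories agree there.
#'
#' @param ens an \code{\link{ensemble_run}} with \code{reps >= 2}.
#' @return numeric vector \code{b} of length \code{t_max + 1}.
#' @export
baseline_variance <- function(ens) {
  stopifnot(inherits(ens, "ensemble_run"))
  R <- ens$reps
  if (R < 2L) stop("baseline variance requires at least 2 trajectories",
                   call. = FALSE)
  tt <- ens$t_max + 1L
  b <- numeric(tt)
  N <- dim(ens$trajectories)[3L]
  for (t in seq_len(tt)) {
    sig <- ens$trajectories[, t, , drop = TRUE]           # R x N
    sig <- matrix(sig, nrow = R)
    loo <- (R * matrix(colMeans(sig), R, N, byrow = TRUE) - sig) / (R - 1)
    b[t] <- sum((sig - loo)^2) / (R * N)
  }
  b
}
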