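#' Binary entropy function
#'
#' \eqn{h_2(s) = -s \log_2 s - (1-s)\log_2(1-s)} in bits, with the
#' \eqn{0 \log 0 = 0} convention, so \eqn{h_2(0) = h_2(1) = 0}.
#'
#' @param s numeric vector with entries in \eqn{[0, 1]}.
#' @return entropies in \eqn{[0, 1]} bits.
#' @export
binary_entropy <- function(s) {
  s <- as.numeric(s)
  if (any(is.na(s)) || any(s < 0 | s > 1))
    stop("`s` must lie in [0, 1]", call. = FALSE)
  term <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p))
  term(s) + term(1 - s)
}

#' Normalized network entropy of a probability state
#'
#' \eqn{H(\vec s) = \frac{1}{N}\sum_i h_2(s_i)}: the mean per-node binary
#' entropy, in bits per node. Pinned (deterministic) nodes contribute zero
#' but remain in the denominator \eqn{N}. Because independence between
#' nodes is assumed, this upper-bounds the true normalized joint entropy.
#'
#' @param s probability state vector.
#' @return value in \eqn{[0, 1]}; 1 iff all \eqn{s_i = 1/2}, 0 iff all
#'   entries are deterministic.
#' @export
network_entropy <- function(s) {
  mean(binary_entropy(s))
}

#' Residual entropy of a pinned seed set
#'
#' Quantifies the dynamical influence of a seed set: nodes in the set are
#' pinned to their imposed states (\eqn{s_i(0) = \hat\sigma_i}), all other
#' nodes start maximally uncertain (\eqn{s_i(0) = 1/2}); the IBMFA is
#' iterated for \code{t_max} steps and the normalized entropy of
#' \eqn{\vec s(T)} is returned. Zero residual entropy means the seed set
#' drives the network toward a single configuration from every admissible
#' initial condition (within the mean-field approximation).
#'
#' @param net a \code{\link{boolean_network}}.
#' @param seeds a \code{\link{seed_set}} (possibly empty).
#' @param t_max evaluation horizon \eqn{T \ge 1}; the default 10 is past the
#'   entropy plateau of the networks studied here.
#' @return residual entropy in \eqn{[0, 1]} bits per node. Deterministic.
#' @export
residual_entropy <- function(net, seeds = NULL, t_max = 10L) {
  if (t_max < 1L) stop("`t_max` must be >= 1", call. = FALSE)
  seeds <- as_seed_set(net, seeds)
  traj <- ibmfa_run(net, 0.5, pins = seeds, t_max = t_max)
  network_entropy(traj[t_max + 1L, ])
}

#' Entropy trajectory of a pinned seed set
#'
#' As \code{\link{residual_entropy}} but returning the full time series
#' \eqn{H(\vec s(t))} for \eqn{t = 0, \dots, T}. At \eqn{t = 0} the value is
#' exactly \eqn{(N - |\mathcal{X}|) / N}.
#'
#' @inheritParams residual_entropy
#' @return an object of class \code{entropy_trajectory}: numeric vector of
#'   length \code{t_max + 1} with the seed set attached as an attribute.
#' @export
entropy_trajectory <- function(net, seeds = NULL, t_max = 10L) {
  seeds <- as_seed_set(net, seeds)
  traj <- ibmfa_run(net, 0.5, pins = seeds, t_max = t_max)
  h <- apply(traj, 1L, network_entropy)
  structure(h, seed_set = seeds, class = "entropy_trajectory")
}

#' @export
print.entropy_trajectory <- function(x, ...) {
  cat("residual entropy trajectory, seeds",
      format(attr(x, "seed_set")), "\n")
  print(unclass(x))
  invisible(x)
}

#' Ground-truth residual entropy by exact enumeration
#'
#' The exact counterpart of \code{\link{residual_entropy}} for small
#' networks: every pin-compatible initial configuration is propagated
#' \code{t_max} synchronous steps through the state-transition graph, the
#' exact per-node marginals at time \code{t_max} are averaged over the
#' uniform initial ensemble, and their normalized entropy is returned.
#' This is the \eqn{R \to \infty} limit of estimating the entropy from
#' simulated trajectories.
#'
#' @inheritParams residual_entropy
#' @param max_free enumeration cap on the number of free nodes.
#' @return exact marginal-based network entropy in \eqn{[0, 1]}.
#' @export
exact_marginal_entropy <- function(net, seeds = NULL, t_max = 10L,
                                   max_free = 22L) {
  seeds <- as_seed_set(net, seeds)
  stg <- build_stg(net, seeds, max_free = max_free)
  s <- 0:(stg$n_states - 1L)
  for (i in seq_len(t_max)) s <- stg$successor[s + 1L]
  nf <- length(stg$free_nodes)
  marg <- numeric(n_nodes(net))
  if (length(seeds$node)) marg[seeds$node] <- seeds$state
  for (m in seq_len(nf))
    marg[stg$free_nodes[m]] <- mean(bitwAnd(bitwShiftR(s, nf - m), 1L))
  network_entropy(marg)
}

#' Ground-truth joint entropy by exact enumeration
#'
#' Exact Shannon entropy (in bits, not normalized) of the distribution of
#' configurations at time \code{t_max}, starting from the uniform
#' distribution over all pin-compatible initial configurations. Because the
#' network entropy of \code{\link{residual_entropy}} assumes independent
#' marginals, \code{N * network_entropy} always upper-bounds this quantity.
#'
#' @inheritParams exact_marginal_entropy
#' @return joint entropy in bits.
#' @export
exact_joint_entropy <- function(net, seeds = NULL, t_max = 10L,
                                max_free = 22L) {
  seeds <- as_seed_set(net, seeds)
  stg <- build_stg(net, seeds, max_free = max_free)
  s <- 0:(stg$n_states - 1L)
  for (i in seq_len(t_max)) s <- stg$successor[s + 1L]
  p <- tabulate(s + 1L, nbins = stg$n_states) / stg$n_states
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Exhaustive influence scan over all small seed sets
#'
#' Evaluates the residual entropy of every seed set of size up to
#' \code{max_size} (all \eqn{2^m \binom{N}{m}} node/state combinations of
#' each size \eqn{m}) and flags zero-entropy controllers.
#'
#' @inheritParams residual_entropy
#' @param max_size maximal seed-set size \eqn{m}.
#' @param epsilon entropy threshold below which a set counts as a
#'   zero-entropy controller (normalized bits).
#' @param max_sets refusal cap on the number of seed sets enumerated.
#' @return a data frame with columns \code{nodes} (comma-separated names),
#'   \code{states} (comma-separated pinned states), \code{size},
#'   \code{entropy} and \code{zero_entropy}, sorted by ascending entropy
#'   (ties broken by set order).
#' @export
exhaustive_seed_scan <- function(net, max_size = 3L, t_max = 10L,
                                 epsilon = 1e-4, max_sets = 2e5) {
  n <- n_nodes(net)
  max_size <- min(max_size, n)
  total <- sum(vapply(0:max_size, function(m) 2^m * choose(n, m), 0))
  if (total > max_sets)
    stop(sprintf("scan would enumerate %.3g seed sets (cap %.3g)",
                 total, max_sets), call. = FALSE)
  rows <- vector("list", total)
  pos <- 0L
  for (m in 0:max_size) {
    combos <- if (m == 0L) list(integer(0)) else
      utils::combn(n, m, simplify = FALSE)
    for (cmb in combos) {
      n_states <- 2^m
      for (sc in 0:(n_states - 1L)) {
        st <- row_to_bits(sc, m)
        ss <- seed_set(net, st, nodes = cmb)
        h <- residual_entropy(net, ss, t_max = t_max)
        pos <- pos + 1L
        rows[[pos]] <- data.frame(
          nodes = paste(net$nodes[cmb], collapse = ","),
          states = paste(st, collapse = ","),
          size = m, entropy = h, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$zero_entropy <- out$entropy <= epsilon
  out[order(out$entropy, out$nodes, out$states), , drop = FALSE]
}
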