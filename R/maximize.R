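#' Greedy influence maximization (unconstrained)
#'
#' Builds a quasi-minimal driver set one tuple at a time. At stage \eqn{v}
#' every candidate tuple \eqn{(i, \hat\sigma_i)} with \eqn{i} not yet pinned
#' is evaluated by the residual entropy \eqn{H(\vec s(T))} obtained when it
#' is added to the current set, and the minimizer is selected. The search
#' stops when the entropy drops to \code{epsilon} or below, or when
#' \code{max_stages} tuples have been selected. On convergence the set is
#' pruned with \code{\link{prune_driver_set}}.
#'
#' Ties (entropy differences below 1e-12) are broken deterministically by
#' lowest node index, then pinned state 0 before 1.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param t_max entropy evaluation horizon (default 10).
#' @param epsilon zero-entropy tolerance in normalized bits (default 1e-4).
#' @param max_stages maximal number of selections (default \code{N}).
#' @param prune apply post-processing pruning on convergence (default TRUE).
#' @return an object of class \code{greedy_trace}: list with \code{stages}
#'   (data frame of selected node, state, and entropy after selection),
#'   \code{pre_prune} and \code{final} seed sets, and \code{converged}.
#' @export
greedy_unconstrained <- function(net, t_max = 10L, epsilon = 1e-4,
                                 max_stages = n_nodes(net), prune = TRUE) {
  greedy_search(net, target = NULL, t_max = t_max, epsilon = epsilon,
                max_stages = max_stages, prune = prune)
}

#' Greedy influence maximization constrained to a target fixed point
#'
#' As \code{\link{greedy_unconstrained}}, but candidate tuples are
#' restricted to \eqn{(i, \tilde\sigma_i)} with the pinned state read from
#' the target fixed point, so a converged search drives the network to the
#' target. The target must be a true fixed point of the synchronous
#' dynamics.
#'
#' @inheritParams greedy_unconstrained
#' @param target a fixed point: a \code{bn_attractor} of length 1 or a 0/1
#'   configuration vector.
#' @return a \code{greedy_trace}, see \code{\link{greedy_unconstrained}}.
#' @export
greedy_constrained <- function(net, target, t_max = 10L, epsilon = 1e-4,
                               max_stages = n_nodes(net), prune = TRUE) {
  target <- as_fixed_point(net, target, pins = NULL, check = TRUE)
  greedy_search(net, target = target, t_max = t_max, epsilon = epsilon,
                max_stages = max_stages, prune = prune)
}

greedy_search <- function(net, target, t_max, epsilon, max_stages, prune) {
  n <- n_nodes(net)
  if (max_stages > n) max_stages <- n
  # a constrained search has converged only when the (deterministic)
  # mean-field limit actually equals the target fixed point, node by node;
  # zero entropy alone can correspond to a different frozen configuration
  is_converged <- function(seeds, h) {
    if (h > epsilon) return(FALSE)
    if (is.null(target)) return(TRUE)
    s_final <- ibmfa_run(net, 0.5, pins = seeds, t_max = t_max)[t_max + 1L, ]
    all(abs(s_final - target) <= epsilon)
  }
  seeds <- seed_set(net)
  h <- residual_entropy(net, seeds, t_max = t_max)
  stages <- list()
  converged <- is_converged(seeds, h)
  while (!converged && length(seeds) < max_stages) {
    free <- setdiff(seq_len(n), seeds$node)
    cand <- if (is.null(target)) {
      # candidates ordered for deterministic tie-breaking: node asc, state 0<1
      data.frame(node = rep(free, each = 2L), state = rep(c(0L, 1L),
                                                          length(free)))
    } else {
      data.frame(node = free, state = target[free])
    }
    hs <- vapply(seq_len(nrow(cand)), function(j) {
      residual_entropy(net, seed_set_add(net, seeds, cand$node[j],
                                         cand$state[j]), t_max = t_max)
    }, numeric(1))
    best <- which(hs <= min(hs) + 1e-12)[1L]
    seeds <- seed_set_add(net, seeds, cand$node[best], cand$state[best])
    h <- hs[best]
    stages[[length(stages) + 1L]] <- data.frame(
      node = net$nodes[cand$node[best]], state = cand$state[best],
      entropy = h, stringsAsFactors = FALSE)
    converged <- is_converged(seeds, h)
  }
  pre_prune <- seeds
  if (converged && prune && length(seeds))
    seeds <- prune_driver_set(net, seeds, t_max = t_max, epsilon = epsilon,
                              target = target)
  structure(list(
    stages = if (length(stages)) do.call(rbind, stages) else
      data.frame(node = character(0), state = integer(0),
                 entropy = numeric(0)),
    pre_prune = pre_prune, final = seeds, converged = converged,
    entropy = h, t_max = t_max, epsilon = epsilon,
    constrained = !is.null(target), target = target),
    class = "greedy_trace")
}

#' @export
print.greedy_trace <- function(x, ...) {
  cat(sprintf("greedy %s search: %s after %d selection(s)\n",
              if (x$constrained) "constrained" else "unconstrained",
              if (x$converged) "converged" else "NOT converged",
              nrow(x$stages)))
  if (nrow(x$stages)) print(x$stages)
  cat("final driver set:", format(x$final), "\n")
  invisible(x)
}

#' Post-processing pruning of a zero-entropy driver set
#'
#' Repeatedly attempts to remove single tuples (in addition order, with
#' repeated passes until a full pass removes nothing); a tuple is removed
#' only if the residual entropy of the reduced set stays at or below
#' \code{epsilon}. The result is single-removal minimal and idempotent.
#'
#' @inheritParams greedy_unconstrained
#' @param seeds a \code{\link{seed_set}} whose residual entropy is already
#'   \code{<= epsilon} (otherwise an error is thrown).
#' @param target optional fixed point; when given, a tuple may only be
#'   removed if the mean-field limit also stays at the target (node-wise
#'   within \code{epsilon}), matching the convergence criterion of
#'   \code{\link{greedy_constrained}}.
#' @return the pruned \code{seed_set}.
#' @export
prune_driver_set <- function(net, seeds, t_max = 10L, epsilon = 1e-4,
                             target = NULL) {
  seeds <- as_seed_set(net, seeds)
  if (!is.null(target))
    target <- as_fixed_point(net, target, check = FALSE)
  ok <- function(ss) {
    s_final <- ibmfa_run(net, 0.5, pins = ss, t_max = t_max)[t_max + 1L, ]
    if (network_entropy(s_final) > epsilon) return(FALSE)
    is.null(target) || all(abs(s_final - target) <= epsilon)
  }
  if (!ok(seeds))
    stop("`seeds` is not a zero-entropy driver set; nothing to prune",
         call. = FALSE)
  repeat {
    removed <- FALSE
    m <- 1L
    while (m <= length(seeds)) {
      cand <- seed_set_drop(net, seeds, m)
      if (ok(cand)) {
        seeds <- cand
        removed <- TRUE
      } else {
        m <- m + 1L
      }
    }
    if (!removed) break
  }
  seeds
}

#' Validate a candidate driver set against the exact dynamics
#'
#' Pins the seed set, then either enumerates every pin-compatible initial
#' configuration (\code{method = "exact"}, small networks) or samples
#' \code{n_samples} of them (\code{method = "sample"}), simulates the exact
#' synchronous dynamics, and reports the fraction absorbed by the target
#' attractor. Without a target, the attractor reached most often is
#' reported.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param seeds a \code{\link{seed_set}}.
#' @param target optional target: a fixed-point \code{bn_attractor} or 0/1
#'   configuration; \code{NULL} for unconstrained validation.
#' @param method \code{"exact"} (default for small systems) or
#'   \code{"sample"}.
#' @param n_samples number of sampled initial configurations for
#'   \code{method = "sample"}.
#' @param seed RNG seed for sampling.
#' @param max_free enumeration cap for \code{method = "exact"}.
#' @param max_steps cap on the transient length in sampling mode.
#' @return a list with \code{fraction} (fraction of initial configurations
#'   absorbed by \code{reached}), \code{is_exact_driver}
#'   (\code{fraction == 1}), \code{reached} (the target, or the modal
#'   attractor), and \code{n_attractors_reached} (sampling/unconstrained
#'   modes).
#' @export
validate_driver_set <- function(net, seeds, target = NULL,
                                method = c("exact", "sample"),
                                n_samples = 500L, seed = NULL,
                                max_free = 22L, max_steps = 10000L) {
  method <- match.arg(method)
  seeds <- as_seed_set(net, seeds)
  if (!is.null(target))
    target_st <- as_fixed_point(net, target, pins = seeds, check = FALSE)
  if (method == "exact") {
    atts <- find_attractors(net, pins = seeds, max_free = max_free)
    total <- sum(vapply(atts, function(a) a$basin_size, 0L))
    if (is.null(target)) {
      best <- atts[[1L]]  # largest basin
      frac <- best$basin_size / total
      return(list(fraction = frac, is_exact_driver = frac == 1,
                  reached = best, n_attractors_reached = length(atts)))
    }
    frac <- 0
    reached <- NULL
    for (a in atts) {
      if (nrow(a$states) == 1L && all(a$states[1L, ] == target_st)) {
        frac <- a$basin_size / total
        reached <- a
      }
    }
    return(list(fraction = frac, is_exact_driver = frac == 1,
                reached = reached, n_attractors_reached = length(atts)))
  }
  # sampling mode
  inits <- sample_initial_configuration(net, 0.5, pins = seeds,
                                        n = n_samples, seed = seed)
  keys <- character(n_samples)
  cycles <- list()
  for (r in seq_len(n_samples)) {
    walk <- cpp_walk_attractor(net$regulators, net$functions, seeds$node,
                               seeds$state, inits[r, ], max_steps)
    key <- attractor_key(walk$cycle)
    keys[r] <- key
    if (is.null(cycles[[key]])) cycles[[key]] <- walk$cycle
  }
  tab <- sort(table(keys), decreasing = TRUE)
  if (is.null(target)) {
    key <- names(tab)[1L]
  } else {
    key <- attractor_key(matrix(target_st, 1L))
  }
  frac <- if (key %in% names(tab)) as.numeric(tab[[key]]) / n_samples else 0
  reached_states <- cycles[[key]]
  reached <- if (is.null(reached_states)) NULL else {
    colnames(reached_states) <- net$nodes
    structure(list(states = reached_states, basin_size = NA_integer_),
              class = "bn_attractor")
  }
  list(fraction = frac, is_exact_driver = frac == 1, reached = reached,
       n_attractors_reached = length(tab))
}

#' Brute-force minimal driver sets for a target fixed point
#'
#' Enumerates seed sets of increasing size (restricted to pinned states
#' compatible with the target) and validates each one exhaustively; returns
#' all minimum-cardinality sets that drive every pin-compatible initial
#' configuration into the target. This is the ground-truth oracle against
#' which the greedy search is judged.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param target a fixed point (\code{bn_attractor} or 0/1 configuration).
#' @param max_size largest seed-set size to try.
#' @param max_free enumeration cap per validation.
#' @return list of \code{seed_set}s (possibly empty if no driver set of size
#'   \code{<= max_size} exists), all of the same minimal size.
#' @export
brute_force_minimal_driver <- function(net, target, max_size = 4L,
                                       max_free = 22L) {
  target_st <- as_fixed_point(net, target, check = TRUE)
  n <- n_nodes(net)
  for (m in 0:max_size) {
    combos <- if (m == 0L) list(integer(0)) else
      utils::combn(n, m, simplify = FALSE)
    hits <- list()
    for (cmb in combos) {
      ss <- seed_set(net, target_st[cmb], nodes = cmb)
      free_nodes <- setdiff(seq_len(n), cmb)
      if (length(free_nodes) > max_free)
        stop("validation state space exceeds `max_free`", call. = FALSE)
      code <- encode_config(target_st, free_nodes)
      frac <- cpp_fraction_to_target(net$regulators, net$functions,
                                     ss$node, ss$state, code,
                                     early_exit = TRUE)
      if (frac == 1) hits[[length(hits) + 1L]] <- ss
    }
    if (length(hits)) return(hits)
  }
  list()
}
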