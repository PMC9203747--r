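#' Build the synchronous state-transition graph
#'
#' Enumerates every configuration compatible with the pinned seed set and
#' records its unique synchronous successor. Configurations are encoded as
#' integers over the free (non-pinned) nodes, with the first free node (in
#' declaration order) as the most significant bit.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param pins optional \code{\link{seed_set}}; pinned nodes restrict the
#'   enumeration to compatible configurations.
#' @param max_free refusal cap on the number of free nodes (default 22, i.e.
#'   about 4M states); above the cap an error suggests the sampling mode of
#'   \code{\link{validate_driver_set}}.
#' @return an object of class \code{stg}: list with \code{successor}
#'   (integer vector, \code{successor[i + 1]} is the successor code of state
#'   \code{i}), \code{free_nodes}, \code{pins} and \code{n_states}.
#' @export
build_stg <- function(net, pins = NULL, max_free = 22L) {
  stopifnot(inherits(net, "boolean_network"))
  pins <- as_seed_set(net, pins)
  free_nodes <- setdiff(seq_len(n_nodes(net)), pins$node)
  if (length(free_nodes) > max_free)
    stop(sprintf(paste0("%d free nodes exceed the enumeration cap of %d; ",
                        "use sampling-based validation instead"),
                 length(free_nodes), max_free), call. = FALSE)
  succ <- cpp_successors(net$regulators, net$functions,
                         pins$node, pins$state)
  structure(list(successor = succ, free_nodes = free_nodes, pins = pins,
                 n_states = length(succ), nodes = net$nodes),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat(sprintf("state-transition graph: %d states over %d free nodes\n",
              x$n_states, length(x$free_nodes)))
  invisible(x)
}

#' Find all attractors by brute-force STG analysis
#'
#' Every configuration compatible with the pins is enumerated, so the
#' returned attractors carry exact basin sizes which sum to the number of
#' enumerated configurations.
#'
#' @inheritParams build_stg
#' @return a list of class \code{bn_attractors}; each element has
#'   \code{states} (an L x N 0/1 matrix, rows in cycle order; L = 1 for a
#'   fixed point) and \code{basin_size}. Sorted by decreasing basin size.
#' @export
find_attractors <- function(net, pins = NULL, max_free = 22L) {
  stg <- build_stg(net, pins, max_free = max_free)
  res <- cpp_attractors(stg$successor)
  n <- n_nodes(net)
  basin <- tabulate(res$label, nbins = length(res$cycles))
  atts <- lapply(seq_along(res$cycles), function(a) {
    codes <- res$cycles[[a]]
    states <- t(vapply(codes, decode_config, integer(n),
                       which = stg$free_nodes, n = n))
    if (length(stg$pins$node)) {
      states[, stg$pins$node] <- rep(stg$pins$state, each = nrow(states))
    }
    colnames(states) <- net$nodes
    structure(list(states = states, basin_size = basin[a]),
              class = "bn_attractor")
  })
  ord <- order(-basin, vapply(res$cycles, min, integer(1)))
  structure(atts[ord], class = "bn_attractors")
}

#' @export
print.bn_attractor <- function(x, ...) {
  L <- nrow(x$states)
  cat(sprintf("%s (basin %s)\n",
              if (L == 1L) "fixed point" else sprintf("limit cycle (L=%d)", L),
              if (is.null(x$basin_size)) "?" else x$basin_size))
  cat(paste(apply(x$states, 1L, paste, collapse = ""), collapse = " -> "),
      "\n")
  invisible(x)
}

#' @export
print.bn_attractors <- function(x, ...) {
  cat(sprintf("%d attractor(s):\n", length(x)))
  for (a in x) print(a)
  invisible(x)
}

# normalize a target (bn_attractor, 1 x N matrix or 0/1 vector) to a fixed
# point state vector; verifies it against the pinned dynamics
as_fixed_point <- function(net, target, pins = NULL, check = TRUE) {
  if (inherits(target, "bn_attractor")) {
    if (nrow(target$states) != 1L)
      stop("target must be a fixed point (limit cycles are not supported)",
           call. = FALSE)
    st <- target$states[1L, ]
  } else if (is.matrix(target)) {
    if (nrow(target) != 1L)
      stop("target must be a single configuration", call. = FALSE)
    st <- target[1L, ]
  } else {
    st <- target
  }
  st <- check_config(net, st)
  if (check && !identical(synchronous_step(net, st, pins), st))
    stop("target configuration is not a fixed point of the (pinned) dynamics",
         call. = FALSE)
  st
}

#' Fraction of initial configurations absorbed by a target attractor
#'
#' Computed by exact enumeration of all pin-compatible initial
#' configurations. For a fixed-point target a fast memoised walk is used;
#' for a limit cycle the full attractor decomposition is matched.
#'
#' @inheritParams build_stg
#' @param target a \code{bn_attractor}, or a 0/1 configuration (fixed point).
#' @return fraction in \eqn{[0, 1]}; 0 if the target is not an attractor of
#'   the pinned system.
#' @export
basin_fraction <- function(net, pins = NULL, target, max_free = 22L) {
  pins <- as_seed_set(net, pins)
  is_fp <- !inherits(target, "bn_attractor") || nrow(target$states) == 1L
  if (is_fp) {
    st <- as_fixed_point(net, target, pins, check = FALSE)
    if (length(pins$node) && !all(st[pins$node] == pins$state)) return(0)
    free_nodes <- setdiff(seq_len(n_nodes(net)), pins$node)
    if (length(free_nodes) > max_free)
      stop("state space too large for exact enumeration", call. = FALSE)
    code <- encode_config(st, free_nodes)
    return(cpp_fraction_to_target(net$regulators, net$functions,
                                  pins$node, pins$state, code))
  }
  atts <- find_attractors(net, pins, max_free = max_free)
  key <- attractor_key(target$states)
  for (a in atts) {
    if (identical(attractor_key(a$states), key))
      return(a$basin_size / sum(vapply(atts, function(x) x$basin_size, 0L)))
  }
  0
}

# order-invariant key of an attractor cycle
attractor_key <- function(states) {
  rows <- apply(states, 1L, paste, collapse = "")
  shift <- which.min(rows)
  L <- length(rows)
  paste(rows[((seq_len(L) + shift - 2L) %% L) + 1L], collapse = "|")
}

#' Enumerate all fixed points via feedback-vertex-set search
#'
#' Any fixed point of a Boolean network is uniquely determined by its values
#' on a feedback vertex set (FVS) of the regulatory graph: fixing the FVS
#' values, all remaining nodes can be computed in topological order of the
#' acyclic remainder, and the assignment is a fixed point iff it is
#' self-consistent on the FVS. This enumerates \eqn{2^{|FVS|}} candidates
#' and therefore works for networks far beyond the reach of full
#' state-space enumeration, provided a small FVS exists.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param pins optional \code{\link{seed_set}}; pinned nodes keep their value
#'   regardless of their update function.
#' @param max_fvs refusal cap on the FVS size (default 22).
#' @return 0/1 integer matrix with one fixed point per row (possibly 0 rows),
#'   node names as column names, rows sorted by their encoded value.
#' @export
fixed_points <- function(net, pins = NULL, max_fvs = 22L) {
  stopifnot(inherits(net, "boolean_network"))
  pins <- as_seed_set(net, pins)
  n <- n_nodes(net)
  pinned <- pin_mask(net, pins)
  # regulatory graph restricted to free nodes (pinned nodes are constants)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (pinned[i] >= 0L) return(NULL)
    r <- setdiff(net$regulators[[i]], which(pinned >= 0L))
    if (length(r)) cbind(r, i) else NULL
  }))
  if (is.null(edges)) edges <- matrix(integer(0), 0L, 2L)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges), ncol = 2L), directed = TRUE)
  fvs <- integer(0)
  # greedy FVS heuristic: self-loops first, then highest total degree within
  # a cyclic strongly connected component
  repeat {
    if (igraph::vcount(g) == 0L) break
    loop_edges <- igraph::E(g)[igraph::which_loop(g)]
    if (length(loop_edges)) {
      pick <- unique(igraph::ends(g, loop_edges)[, 1L])
    } else {
      comp <- igraph::components(g, mode = "strong")
      cyc <- which(tabulate(comp$membership) > 1L)
      if (!length(cyc)) break
      members <- which(comp$membership == cyc[1L])
      deg <- igraph::degree(g, v = members, mode = "all")
      pick <- igraph::V(g)$name[members[which.max(deg)]]
    }
    fvs <- c(fvs, as.integer(pick))
    g <- igraph::delete_vertices(g, as.character(pick))
  }
  if (length(fvs) > max_fvs)
    stop(sprintf("feedback vertex set of size %d exceeds cap %d",
                 length(fvs), max_fvs), call. = FALSE)
  fvs <- sort(fvs)
  free_rest <- setdiff(which(pinned < 0L), fvs)
  # topological order of the remainder
  if (length(free_rest)) {
    sub_edges <- edges[edges[, 1L] %in% free_rest &
                         edges[, 2L] %in% free_rest, , drop = FALSE]
    gd <- igraph::graph_from_edgelist(
      matrix(as.character(sub_edges), ncol = 2L), directed = TRUE)
    gd <- gd + igraph::vertices(setdiff(as.character(free_rest),
                                        igraph::V(gd)$name))
    topo <- as.integer(igraph::V(gd)$name[igraph::topo_sort(gd)])
  } else topo <- integer(0)
  state <- integer(n)
  if (length(pins$node)) state[pins$node] <- pins$state
  found <- list()
  m <- length(fvs)
  for (code in 0:(2^m - 1L)) {
    if (m) state[fvs] <- row_to_bits(code, m)
    for (i in topo) {
      r <- net$regulators[[i]]
      state[i] <- net$functions[[i]][bits_to_row(state[r]) + 1L]
    }
    ok <- TRUE
    for (i in fvs) {
      r <- net$regulators[[i]]
      if (net$functions[[i]][bits_to_row(state[r]) + 1L] != state[i]) {
        ok <- FALSE
        break
      }
    }
    if (ok) found[[length(found) + 1L]] <- state
  }
  out <- do.call(rbind, found)
  if (is.null(out)) out <- matrix(integer(0), 0L, n)
  colnames(out) <- net$nodes
  out[order(apply(out, 1L, function(b) paste(b, collapse = ""))), ,
      drop = FALSE]
}
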