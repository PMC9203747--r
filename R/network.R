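#' Construct a Boolean function from its truth table
#'
#' A Boolean function of arity \eqn{k} is stored as the bit vector of its
#' \eqn{2^k} outputs. Row \eqn{r \in [0, 2^k)} encodes the input
#' configuration with the first (lowest-index) regulator as the most
#' significant bit, so e.g. the two-input AND is \code{c(0, 0, 0, 1)}.
#'
#' @param outputs integer vector of 0/1 output bits; its length must be a
#'   power of two.
#' @return an object of class \code{boolean_function} with an \code{arity}
#'   attribute.
#' @examples
#' f_and <- boolean_function(c(0, 0, 0, 1))
#' evaluate_function(f_and, c(1, 1))
#' @export
boolean_function <- function(outputs) {
  outputs <- as.integer(outputs)
  if (length(outputs) < 1L || any(is.na(outputs)) || !all(outputs %in% c(0L, 1L)))
    stop("`outputs` must be a vector of 0/1 bits", call. = FALSE)
  k <- log2(length(outputs))
  if (k != floor(k))
    stop("length of `outputs` must be a power of two", call. = FALSE)
  structure(outputs, arity = as.integer(k), class = "boolean_function")
}

#' Evaluate a Boolean function on one input configuration
#'
#' @param f a \code{\link{boolean_function}} (or a bare 0/1 output vector
#'   whose length is a power of two).
#' @param input_bits 0/1 vector of length equal to the arity, ordered by
#'   ascending regulator index (first element is the most significant bit of
#'   the truth-table row).
#' @return a single bit (integer 0 or 1).
#' @export
evaluate_function <- function(f, input_bits) {
  if (!inherits(f, "boolean_function")) f <- boolean_function(f)
  k <- attr(f, "arity")
  input_bits <- as.integer(input_bits)
  if (length(input_bits) != k)
    stop(sprintf("expected %d input bits, got %d", k, length(input_bits)),
         call. = FALSE)
  if (!all(input_bits %in% c(0L, 1L)))
    stop("input bits must be 0/1", call. = FALSE)
  unclass(f)[bits_to_row(input_bits) + 1L]
}

# row index (0-based) of an input configuration, first bit = MSB
bits_to_row <- function(bits) {
  k <- length(bits)
  if (k == 0L) return(0L)
  as.integer(sum(bits * 2^((k - 1L):0L)))
}

# inverse of bits_to_row
row_to_bits <- function(row, k) {
  if (k == 0L) return(integer(0))
  as.integer(bitwAnd(bitwShiftR(as.integer(row), (k - 1L):0L), 1L))
}

#' Construct a Boolean network
#'
#' A Boolean network is a directed graph on \code{length(nodes)} nodes where
#' the next state of node \eqn{i} is a fixed Boolean function of the current
#' states of its regulators. Regulator lists are normalised to ascending node
#' index; if a regulator list is supplied in a different order, the truth
#' table is permuted accordingly so that the stored table always follows the
#' first-regulator-is-MSB convention. Self-loops are allowed. Nodes declared
#' with no regulators (external inputs) are stored as the identity function
#' of a synthetic self-input, which freezes them at their initial state.
#'
#' @param nodes character vector of unique node names.
#' @param regulators list (one element per node) of regulator node indices or
#'   names; may be \code{NULL}/empty for input nodes.
#' @param functions list of 0/1 output vectors, one per node, of length
#'   \code{2^k} where \code{k} is the number of regulators (length 1 allowed
#'   for zero-regulator constants, interpreted as a frozen constant).
#' @return an object of class \code{boolean_network}.
#' @examples
#' net <- boolean_network(c("A", "B"),
#'                        list("B", c("A", "B")),
#'                        list(c(1, 0), c(0, 0, 0, 1)))
#' synchronous_step(net, c(1, 1))
#' @export
boolean_network <- function(nodes, regulators, functions) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  if (n < 1L) stop("a network needs at least one node", call. = FALSE)
  if (anyDuplicated(nodes)) stop("node names must be unique", call. = FALSE)
  if (length(regulators) != n || length(functions) != n)
    stop("`regulators` and `functions` must have one entry per node",
         call. = FALSE)
  regs <- vector("list", n)
  funs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- regulators[[i]]
    if (is.character(r)) {
      idx <- match(r, nodes)
      if (anyNA(idx))
        stop(sprintf("node '%s': unknown regulator '%s'", nodes[i],
                     r[which(is.na(idx))[1L]]), call. = FALSE)
      r <- idx
    }
    r <- as.integer(r)
    out <- as.integer(functions[[i]])
    if (length(r) == 0L) {
      # external input: frozen at its initial value via a self-input;
      # a declared constant keeps its constant table
      if (length(out) == 1L) {
        regs[[i]] <- i
        funs[[i]] <- rep(out, 2L)
      } else {
        regs[[i]] <- i
        funs[[i]] <- c(0L, 1L)
      }
      next
    }
    if (anyDuplicated(r))
      stop(sprintf("node '%s': duplicated regulator", nodes[i]), call. = FALSE)
    if (any(r < 1L | r > n))
      stop(sprintf("node '%s': regulator index out of range", nodes[i]),
           call. = FALSE)
    k <- length(r)
    if (length(out) != 2^k)
      stop(sprintf("node '%s': truth table length %d does not match arity %d",
                   nodes[i], length(out), k), call. = FALSE)
    if (!all(out %in% c(0L, 1L)))
      stop(sprintf("node '%s': truth table entries must be 0/1", nodes[i]),
           call. = FALSE)
    ord <- order(r)
    if (!identical(ord, seq_len(k)))
      out <- permute_truth_table(out, ord)
    regs[[i]] <- r[ord]
    funs[[i]] <- out
  }
  structure(list(nodes = nodes, regulators = regs, functions = funs),
            class = "boolean_network")
}

# reorder a truth table after permuting the regulator list: `perm` maps new
# regulator position -> old position
permute_truth_table <- function(outputs, perm) {
  k <- length(perm)
  rows <- 0:(2^k - 1L)
  new_out <- integer(length(outputs))
  for (r in rows) {
    bits_new <- row_to_bits(r, k)
    bits_old <- integer(k)
    bits_old[perm] <- bits_new       # old position perm[j] holds new bit j
    new_out[r + 1L] <- outputs[bits_to_row(bits_old) + 1L]
  }
  new_out
}

#' @export
print.boolean_network <- function(x, ...) {
  k <- lengths(x$regulators)
  cat(sprintf("Boolean network: %d nodes, in-degree %d-%d\n",
              length(x$nodes), min(k), max(k)))
  cat("nodes:", paste(utils::head(x$nodes, 10L), collapse = ", "),
      if (length(x$nodes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Number of nodes of a Boolean network
#' @param net a \code{boolean_network}.
#' @return integer.
#' @export
n_nodes <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  length(net$nodes)
}

#' Derived adjacency matrix
#'
#' \code{A[j, i] = 1} iff node \code{j} is a regulator of node \code{i}.
#'
#' @param net a \code{boolean_network}.
#' @return an N x N 0/1 integer matrix with node names as dimnames.
#' @export
adjacency_matrix <- function(net) {
  n <- n_nodes(net)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(n)) A[net$regulators[[i]], i] <- 1L
  A
}

#' Define a pinned seed set
#'
#' A seed set is a collection of (node, pinned state) tuples; pinned nodes
#' keep their imposed state at every step of the dynamics (pinning control).
#' A node may appear at most once.
#'
#' @param net a \code{boolean_network}.
#' @param states a named 0/1 vector (names are node names), or a 0/1 vector
#'   named by \code{nodes}; use \code{seed_set(net)} for the empty set.
#' @param nodes optional node names or indices when \code{states} is unnamed.
#' @return an object of class \code{seed_set} with integer fields
#'   \code{node} (ascending indices) and \code{state}.
#' @examples
#' net <- boolean_network(c("A", "B"), list("A", "A"), list(c(0, 1), c(1, 0)))
#' seed_set(net, c(A = 1))
#' @export
seed_set <- function(net, states = NULL, nodes = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.null(states) || length(states) == 0L) {
    return(structure(list(node = integer(0), state = integer(0),
                          nodes = character(0)), class = "seed_set"))
  }
  if (is.null(nodes)) {
    if (is.null(names(states)))
      stop("`states` must be named by node, or `nodes` must be given",
           call. = FALSE)
    nodes <- names(states)
  }
  idx <- if (is.character(nodes)) match(nodes, net$nodes) else as.integer(nodes)
  if (anyNA(idx) || any(idx < 1L | idx > n_nodes(net)))
    stop("unknown node in seed set", call. = FALSE)
  if (anyDuplicated(idx))
    stop("a node may appear at most once in a seed set", call. = FALSE)
  st <- as.integer(states)
  if (!all(st %in% c(0L, 1L)))
    stop("pinned states must be 0/1", call. = FALSE)
  ord <- order(idx)
  structure(list(node = idx[ord], state = st[ord],
                 nodes = net$nodes[idx[ord]]), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  if (length(x$node) == 0L) {
    cat("seed set: (empty)\n")
  } else {
    cat("seed set:", paste0(x$nodes, "=", x$state, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.seed_set <- function(x) length(x$node)

#' @export
format.seed_set <- function(x, ...) {
  if (length(x$node) == 0L) "{}" else
    paste0("{", paste0("(", x$nodes, ",", x$state, ")", collapse = ","), "}")
}

# internal: extend a seed set by one tuple (assumes node not present)
seed_set_add <- function(net, seeds, node, state) {
  seed_set(net, c(seeds$state, as.integer(state)),
           nodes = c(seeds$node, as.integer(node)))
}

# internal: drop the m-th tuple
seed_set_drop <- function(net, seeds, m) {
  seed_set(net, seeds$state[-m], nodes = seeds$node[-m])
}

# internal: -1/0/1 pin mask of length N
pin_mask <- function(net, seeds) {
  p <- rep(-1L, n_nodes(net))
  if (!is.null(seeds) && length(seeds$node)) p[seeds$node] <- seeds$state
  p
}

as_seed_set <- function(net, seeds) {
  if (is.null(seeds)) return(seed_set(net))
  if (inherits(seeds, "seed_set")) return(seeds)
  seed_set(net, seeds)
}
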