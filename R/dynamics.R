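#' One synchronous update of a Boolean network
#'
#' Every non-pinned node takes the value of its Boolean function applied to
#' the regulator states of the previous step; pinned nodes keep their imposed
#' state.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param config 0/1 state vector of length \code{n_nodes(net)}.
#' @param pins optional \code{\link{seed_set}}.
#' @return the successor configuration (integer 0/1 vector).
#' @export
synchronous_step <- function(net, config, pins = NULL) {
  config <- check_config(net, config)
  pins <- as_seed_set(net, pins)
  nxt <- integer(n_nodes(net))
  for (i in seq_len(n_nodes(net))) {
    r <- net$regulators[[i]]
    nxt[i] <- net$functions[[i]][bits_to_row(config[r]) + 1L]
  }
  if (length(pins$node)) nxt[pins$node] <- pins$state
  nxt
}

check_config <- function(net, config) {
  config <- as.integer(config)
  if (length(config) != n_nodes(net))
    stop(sprintf("configuration must have length %d", n_nodes(net)),
         call. = FALSE)
  if (!all(config %in% c(0L, 1L)))
    stop("configuration entries must be 0/1", call. = FALSE)
  config
}

#' Simulate a trajectory of the exact Boolean dynamics
#'
#' Supported update schemes:
#' \describe{
#'   \item{\code{synchronous}}{all nodes updated simultaneously (default).}
#'   \item{\code{deterministic-async}}{within one time unit, nodes are
#'     updated one at a time in ascending index order, each seeing the
#'     current (partially updated) state.}
#'   \item{\code{stochastic-async}}{one uniformly random node is updated per
#'     substep; \code{n_nodes(net)} substeps make one time unit. Requires
#'     \code{seed} for reproducibility.}
#'   \item{\code{block-deterministic}}{a user-supplied ordered partition of
#'     the nodes (\code{blocks}); blocks are processed sequentially, nodes
#'     within a block synchronously.}
#' }
#' Pinned nodes never change state under any scheme. Fixed points of the
#' synchronous dynamics are fixed points under every scheme.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param config initial 0/1 configuration.
#' @param t_max number of time units to simulate (\eqn{\ge 0}).
#' @param pins optional \code{\link{seed_set}}.
#' @param scheme update scheme tag, see Details.
#' @param blocks list of integer index vectors forming an ordered partition
#'   (only for \code{block-deterministic}).
#' @param seed RNG seed (only used, and then required, for
#'   \code{stochastic-async}).
#' @return integer matrix of dimension \code{(t_max + 1) x N}; row \code{t+1}
#'   is the configuration at time \code{t}.
#' @export
simulate_trajectory <- function(net, config, t_max, pins = NULL,
                                scheme = c("synchronous",
                                           "deterministic-async",
                                           "stochastic-async",
                                           "block-deterministic"),
                                blocks = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  config <- check_config(net, config)
  pins <- as_seed_set(net, pins)
  if (t_max < 0) stop("`t_max` must be >= 0", call. = FALSE)
  n <- n_nodes(net)
  if (length(pins$node)) config[pins$node] <- pins$state
  if (scheme == "stochastic-async") {
    if (is.null(seed)) stop("stochastic-async updating requires `seed`",
                            call. = FALSE)
    set.seed(seed)
  }
  if (scheme == "block-deterministic") {
    if (is.null(blocks)) stop("block-deterministic updating requires `blocks`",
                              call. = FALSE)
    if (!setequal(unlist(blocks), seq_len(n)) ||
        length(unlist(blocks)) != n)
      stop("`blocks` must be an ordered partition of the node indices",
           call. = FALSE)
  }
  pinned <- pin_mask(net, pins)
  traj <- matrix(NA_integer_, t_max + 1L, n,
                 dimnames = list(NULL, net$nodes))
  traj[1L, ] <- config
  cur <- config
  update_one <- function(state, i) {
    if (pinned[i] >= 0L) return(state)
    r <- net$regulators[[i]]
    state[i] <- net$functions[[i]][bits_to_row(state[r]) + 1L]
    state
  }
  for (t in seq_len(t_max)) {
    cur <- switch(scheme,
      "synchronous" = synchronous_step(net, cur, pins),
      "deterministic-async" = {
        st <- cur
        for (i in seq_len(n)) st <- update_one(st, i)
        st
      },
      "stochastic-async" = {
        st <- cur
        picks <- sample.int(n, n, replace = TRUE)
        for (i in picks) st <- update_one(st, i)
        st
      },
      "block-deterministic" = {
        st <- cur
        for (b in blocks) {
          blk <- synchronous_step(net, st, pins)
          st[b] <- blk[b]
        }
        st
      })
    traj[t + 1L, ] <- cur
  }
  traj
}

# configuration <-> integer code over the nodes `which` (first = MSB)
encode_config <- function(config, which = seq_along(config)) {
  bits_to_row(config[which])
}

decode_config <- function(code, which, n) {
  bits <- row_to_bits(code, length(which))
  out <- integer(n)
  out[which] <- bits
  out
}
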