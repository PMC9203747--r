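# small networks built in code, shared across test files

# single node negating itself: period-2 cycle under synchronous update
not_self_net <- function() {
  boolean_network("A", list("A"), list(c(1L, 0L)))
}

# every node copies itself (all 2^n configurations are fixed points)
identity_net <- function(n = 2L) {
  boolean_network(paste0("n", seq_len(n)),
                  as.list(seq_len(n)),
                  rep(list(c(0L, 1L)), n))
}

# every node's function is the constant `value`
constant_net <- function(n = 3L, value = 1L) {
  boolean_network(paste0("n", seq_len(n)),
                  as.list(seq_len(n)),
                  rep(list(rep(as.integer(value), 2L)), n))
}

# binary in-tree on 7 nodes: leaves 4..7 are frozen self-inputs, nodes 1..3
# combine two children whose ancestries never overlap (exactness case for
# the mean-field approximation)
tree_net <- function(ops = c(c(0L, 0L, 0L, 1L))) {
  regs <- list(c(2L, 3L), c(4L, 5L), c(6L, 7L), 4L, 5L, 6L, 7L)
  funs <- list(c(0L, 0L, 0L, 1L),   # AND
               c(0L, 1L, 1L, 1L),   # OR
               c(0L, 1L, 1L, 0L),   # XOR
               c(0L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 1L))
  boolean_network(paste0("t", 1:7), regs, funs)
}

# exact marginals at time t, by brute-force enumeration of all initial
# configurations weighted by independent marginals s0 (independent of the
# STG and IBMFA code paths: uses simulate_trajectory on each configuration)
enumeration_marginals <- function(net, s0, t, pins = NULL) {
  n <- n_nodes(net)
  s0 <- rep(s0, length.out = n)
  if (!is.null(pins)) s0[pins$node] <- pins$state
  marg <- numeric(n)
  total <- 0
  for (code in 0:(2^n - 1L)) {
    cfg <- as.integer(bitwAnd(bitwShiftR(code, (n - 1L):0L), 1L))
    w <- prod(ifelse(cfg == 1L, s0, 1 - s0))
    if (w == 0) next
    tr <- simulate_trajectory(net, cfg, t, pins = pins)
    marg <- marg + w * tr[t + 1L, ]
    total <- total + w
  }
  unname(marg / total)
}

# random k=2 networks reused by property tests
random_nets <- function(n_nets, n = 8L, k = 2L, seed = 99L) {
  lapply(seq_len(n_nets), function(i) make_rbn(n, k, seed = seed + i))
}

# first fixed-point attractor of a network, or NULL
first_fixed_point <- function(net) {
  atts <- find_attractors(net)
  for (a in atts) if (nrow(a$states) == 1L) return(a$states[1L, ])
  NULL
}
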