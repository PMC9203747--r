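test_that("binary entropy follows the closed form and its conventions", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(c(0, 1)), c(0, 0))
  expect_equal(binary_entropy(0.25),
               -0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_equal(binary_entropy(0.25), 0.811278124459, tolerance = 1e-10)
  expect_equal(binary_entropy(0.3), binary_entropy(0.7))
  expect_error(binary_entropy(-0.1), "\\[0, 1\\]")
  expect_error(binary_entropy(1.1), "\\[0, 1\\]")
})

test_that("network entropy averages per-node entropies over N", {
  expect_equal(network_entropy(rep(0.5, 6L)), 1)
  expect_equal(network_entropy(c(0, 1, 1, 0)), 0)
  expect_equal(network_entropy(c(1, 0.5, 0.5, 0)), 0.5)
})

test_that("residual entropy: frozen uncertainty, full pinning, t = 0 bound", {
  idn <- identity_net(4L)
  for (tt in c(1L, 5L, 20L))
    expect_equal(residual_entropy(idn, NULL, t_max = tt), 1)
  all_pinned <- seed_set(idn, rep(1L, 4L), nodes = 1:4)
  expect_equal(residual_entropy(idn, all_pinned), 0)
  # H at t = 0 equals (N - |X|) / N exactly
  net <- make_rbn(10L, 2L, seed = 44L)
  for (m in c(0L, 2L, 5L)) {
    ss <- if (m == 0L) seed_set(net) else
      seed_set(net, rep(1L, m), nodes = seq_len(m))
    h <- entropy_trajectory(net, ss, t_max = 2L)
    expect_equal(as.numeric(h)[1L], (10 - m) / 10)
  }
})

test_that("entropy trajectory of a constant network drops to 0 at t = 1", {
  h <- entropy_trajectory(constant_net(5L), NULL, t_max = 4L)
  expect_equal(as.numeric(h), c(1, 0, 0, 0, 0))
})

test_that("entropy stays within [0, 1] for arbitrary networks and pins", {
  set.seed(6)
  for (net in random_nets(6L, n = 9L, k = 3L, seed = 220L)) {
    m <- sample(0:4, 1L)
    ss <- if (m == 0L) NULL else
      seed_set(net, sample(0:1, m, replace = TRUE),
               nodes = sample(9L, m))
    h <- entropy_trajectory(net, ss, t_max = 15L)
    expect_true(all(h >= 0 & h <= 1))
  }
})

test_that("independent-marginal entropy upper-bounds the exact joint entropy", {
  # the independence bound holds for the TRUE marginals; the approximate
  # mean-field marginals guarantee no such bound in general
  for (net in random_nets(5L, n = 9L, k = 2L, seed = 260L)) {
    for (ss in list(seed_set(net), seed_set(net, c(n1 = 1)))) {
      h_marg <- exact_marginal_entropy(net, ss, t_max = 8L)
      h_joint <- exact_joint_entropy(net, ss, t_max = 8L)
      expect_gte(h_marg + 1e-9, h_joint / 9)
    }
  }
})

test_that("supersets consistent with a zero-entropy set stay at zero", {
  for (net in random_nets(6L, n = 8L, seed = 310L)) {
    fp <- first_fixed_point(net)
    if (is.null(fp)) next
    full <- seed_set(net, fp, nodes = seq_len(8L))
    base <- prune_driver_set(net, full)
    # add back any dropped tuple, one at a time, at its fixed-point state
    dropped <- setdiff(seq_len(8L), base$node)
    for (d in dropped) {
      sup <- seed_set(net, c(base$state, fp[d]), nodes = c(base$node, d))
      expect_lte(residual_entropy(net, sup), 1e-4)
    }
  }
})

test_that("exhaustive scan enumerates all sets and ranks by entropy", {
  id1 <- identity_net(1L)
  sc <- exhaustive_seed_scan(id1, max_size = 1L)
  expect_equal(nrow(sc), 3L)               # empty set + two pinned states
  z <- sc[sc$zero_entropy, ]
  expect_equal(nrow(z), 2L)
  expect_true(all(z$size == 1L))
  expect_false(is.unsorted(sc$entropy))
  net <- make_rbn(6L, 2L, seed = 71L)
  sc2 <- exhaustive_seed_scan(net, max_size = 2L)
  expect_equal(nrow(sc2), 1L + 2L * 6L + 4L * choose(6L, 2L))
  expect_error(exhaustive_seed_scan(net, max_size = 2L, max_sets = 10),
               "cap")
})

test_that("exact ground-truth entropies agree with direct enumeration", {
  net <- tree_net()
  ss <- seed_set(net, c(t4 = 1))
  marg <- enumeration_marginals(net, 0.5, 4L, pins = ss)
  expect_equal(exact_marginal_entropy(net, ss, t_max = 4L),
               network_entropy(marg), tolerance = 1e-12)
  # joint entropy of a frozen identity network stays maximal on free nodes
  idn <- identity_net(3L)
  expect_equal(exact_joint_entropy(idn, seed_set(idn, c(n1 = 0)),
                                   t_max = 5L), 2)
})
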