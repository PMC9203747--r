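test_that("boolean functions evaluate by the MSB-first row convention", {
  f_and <- boolean_function(c(0, 0, 0, 1))
  f_not <- boolean_function(c(1, 0))
  f_xor <- boolean_function(c(0, 1, 1, 0))
  expect_equal(evaluate_function(f_and, c(1, 1)), 1L)
  expect_equal(evaluate_function(f_and, c(1, 0)), 0L)
  expect_equal(evaluate_function(f_not, 1), 0L)
  expect_equal(evaluate_function(f_xor, c(1, 0)), 1L)
  expect_error(evaluate_function(f_and, c(1, 0, 1)), "input bits")
  expect_error(boolean_function(c(0, 1, 1)), "power of two")
})

test_that("network constructor normalizes regulator order and validates", {
  # same function declared with regulators in both orders must agree:
  # f(A, B) = A & !B
  net1 <- boolean_network(c("A", "B"),
                          list(c("A", "B"), "B"),
                          list(c(0L, 0L, 1L, 0L), c(0L, 1L)))
  net2 <- boolean_network(c("A", "B"),
                          list(c("B", "A"), "B"),
                          list(c(0L, 1L, 0L, 0L), c(0L, 1L)))
  expect_identical(net1$functions, net2$functions)
  expect_identical(net1$regulators, net2$regulators)
  expect_error(boolean_network("A", list(c(1, 1)), list(c(0, 1, 0, 1))),
               "duplicated")
  expect_error(boolean_network("A", list(2), list(c(0, 1))), "out of range")
  expect_error(boolean_network("A", list("B"), list(c(0, 1))), "unknown")
  # zero-regulator nodes become frozen identity self-inputs
  net3 <- boolean_network(c("A", "B"), list(NULL, "A"),
                          list(integer(0), c(0L, 1L)))
  expect_identical(net3$regulators[[1L]], 1L)
  expect_identical(net3$functions[[1L]], c(0L, 1L))
})

test_that("synchronous_step follows the rules and pins override", {
  expect_equal(synchronous_step(identity_net(2L), c(0, 1)), c(0L, 1L))
  nn <- not_self_net()
  expect_equal(synchronous_step(nn, 1L), 0L)
  expect_equal(synchronous_step(nn, 1L, pins = seed_set(nn, c(A = 1))), 1L)
  expect_error(synchronous_step(nn, c(1, 0)), "length")
})

test_that("simulate_trajectory handles all schemes and is reproducible", {
  cn <- constant_net(3L)
  tr <- simulate_trajectory(cn, c(0L, 0L, 0L), 2L)
  expect_equal(unname(tr[2L, ]), rep(1L, 3L))
  expect_equal(unname(tr[3L, ]), rep(1L, 3L))
  nn <- not_self_net()
  expect_equal(unname(simulate_trajectory(nn, 0L, 4L)[, 1L]),
               c(0L, 1L, 0L, 1L, 0L))
  expect_error(simulate_trajectory(nn, 0L, 2L, scheme = "nope"))
  expect_error(simulate_trajectory(nn, 0L, 2L, scheme = "stochastic-async"),
               "seed")
  net <- make_rbn(10L, 2L, seed = 5L)
  a <- simulate_trajectory(net, rep(0L, 10L), 6L,
                           scheme = "stochastic-async", seed = 11L)
  b <- simulate_trajectory(net, rep(0L, 10L), 6L,
                           scheme = "stochastic-async", seed = 11L)
  expect_identical(a, b)
  blocks <- list(1:5, 6:10)
  d <- simulate_trajectory(net, rep(0L, 10L), 6L,
                           scheme = "block-deterministic", blocks = blocks)
  expect_equal(dim(d), c(7L, 10L))
  expect_error(simulate_trajectory(net, rep(0L, 10L), 2L,
                                   scheme = "block-deterministic",
                                   blocks = list(1:4)), "partition")
})

test_that("pinned nodes never change state under any scheme", {
  net <- make_rbn(8L, 2L, seed = 21L)
  pins <- seed_set(net, c(n2 = 1, n5 = 0))
  for (sch in c("synchronous", "deterministic-async", "stochastic-async")) {
    tr <- simulate_trajectory(net, rep(0L, 8L), 10L, pins = pins,
                              scheme = sch, seed = 3L)
    expect_true(all(tr[, 2L] == 1L), info = sch)
    expect_true(all(tr[, 5L] == 0L), info = sch)
  }
})

test_that("synchronous fixed points are fixed under every scheme", {
  for (net in random_nets(8L, n = 10L, seed = 300L)) {
    fp <- first_fixed_point(net)
    if (is.null(fp)) next
    for (sch in c("deterministic-async", "stochastic-async")) {
      tr <- simulate_trajectory(net, fp, 3L, scheme = sch, seed = 1L)
      expect_equal(unname(tr[4L, ]), unname(fp), info = sch)
    }
    blk <- simulate_trajectory(net, fp, 3L, scheme = "block-deterministic",
                               blocks = list(1:3, 4:10))
    expect_equal(unname(blk[4L, ]), unname(fp))
  }
})

test_that("build_stg enumerates pin-compatible configurations", {
  idn <- identity_net(2L)
  stg <- build_stg(idn)
  expect_equal(stg$n_states, 4L)
  expect_identical(stg$successor, 0:3)      # every configuration is fixed
  stg2 <- build_stg(idn, pins = seed_set(idn, c(n1 = 1)))
  expect_equal(stg2$n_states, 2L)
  expect_error(build_stg(make_rbn(24L, 1L, seed = 1L), max_free = 22L),
               "cap")
})

test_that("stg successors agree with the R-level synchronous step", {
  net <- make_rbn(9L, 3L, seed = 77L)
  stg <- build_stg(net)
  set.seed(1)
  for (code in sample(0:(2^9 - 1L), 40L)) {
    cfg <- as.integer(bitwAnd(bitwShiftR(code, 8:0), 1L))
    nxt <- synchronous_step(net, cfg)
    expect_identical(stg$successor[code + 1L],
                     as.integer(sum(nxt * 2^(8:0))))
  }
})

test_that("find_attractors partitions the state space and basins add up", {
  cn <- constant_net(4L)
  atts <- find_attractors(cn)
  expect_length(atts, 1L)
  expect_equal(unname(atts[[1L]]$states[1L, ]), rep(1L, 4L))
  expect_equal(atts[[1L]]$basin_size, 16L)
  for (net in random_nets(5L, n = 9L, seed = 500L)) {
    atts <- find_attractors(net)
    expect_equal(sum(vapply(atts, function(a) a$basin_size, 0L)), 2^9)
    # every cycle really cycles
    for (a in atts) {
      L <- nrow(a$states)
      for (m in seq_len(L)) {
        expect_equal(synchronous_step(net, a$states[m, ]),
                     unname(a$states[(m %% L) + 1L, ]))
      }
    }
  }
})

test_that("trajectories are absorbed by a reported attractor", {
  net <- make_rbn(8L, 2L, seed = 1234L)
  atts <- find_attractors(net)
  keys <- vapply(atts, function(a)
    boolcontrol:::attractor_key(a$states), "")
  set.seed(8)
  for (i in 1:10) {
    cfg <- sample(0:1, 8L, replace = TRUE)
    tr <- simulate_trajectory(net, cfg, 2^8)
    # the last 2^8-step window must contain a full attractor period
    walk <- cpp <- NULL
    fin <- tr[nrow(tr), ]
    reached <- vapply(atts, function(a)
      any(apply(a$states, 1L, function(s) all(s == fin))), TRUE)
    expect_true(any(reached))
  }
})

test_that("basin_fraction matches direct counting", {
  idn <- identity_net(1L)
  expect_equal(basin_fraction(idn, NULL, target = 1L), 0.5)
  cn <- constant_net(3L)
  expect_equal(basin_fraction(cn, NULL, target = rep(1L, 3L)), 1)
  # non-attractor target gives 0
  expect_equal(basin_fraction(not_self_net(), NULL, target = 1L), 0)
})

test_that("fixed_points (FVS search) agrees with STG enumeration", {
  for (net in random_nets(6L, n = 10L, k = 2L, seed = 900L)) {
    fp <- fixed_points(net)
    atts <- find_attractors(net)
    stg_fp <- do.call(rbind, lapply(atts, function(a)
      if (nrow(a$states) == 1L) a$states else NULL))
    n_stg <- if (is.null(stg_fp)) 0L else nrow(stg_fp)
    expect_equal(nrow(fp), n_stg)
    if (n_stg > 0L) {
      key <- function(m) sort(apply(m, 1L, paste, collapse = ""))
      expect_equal(key(fp), key(stg_fp))
    }
  }
})

test_that("seed sets reject duplicates and invalid entries", {
  net <- identity_net(3L)
  expect_error(seed_set(net, c(n1 = 1, n1 = 0)), "at most once")
  expect_error(seed_set(net, c(nope = 1)), "unknown")
  expect_error(seed_set(net, c(n1 = 2)), "0/1")
  expect_length(seed_set(net), 0L)
})
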