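test_that("rule parsing handles operators, negation, and freezing", {
  net <- parse_network("A = NOT A")
  expect_equal(synchronous_step(net, 0L), 1L)
  expect_equal(synchronous_step(net, 1L), 0L)
  net2 <- parse_network(c("X = Y AND NOT Z", "Y := 1", "Z = X XOR Y"))
  # X reads the *current* Y (still 0); the frozen Y jumps to 1
  expect_equal(synchronous_step(net2, c(0L, 0L, 0L)), c(0L, 1L, 0L))
  expect_equal(synchronous_step(net2, c(0L, 1L, 0L)), c(1L, 1L, 1L))
  expect_error(parse_network("A = B OR C"), "unknown name")
  expect_error(parse_network("A = (B"), "line 1")
  expect_error(parse_network(c("A = A", "A = NOT A")), "duplicate")
})

test_that("the packaged cell-cycle network matches its published logic", {
  net <- cellcycle_network()
  expect_equal(net$n, 10L)
  expect_setequal(net$genes, c("CycD", "CycE", "Rb", "E2F", "CycA", "p27",
                               "Cdc20", "UbcH10", "Cdh1", "CycB"))
  rules <- stats::setNames(net$rules, net$genes)
  expect_match(rules[["CycB"]], "NOT Cdc20 AND NOT Cdh1")
  expect_match(rules[["CycE"]], "E2F AND NOT Rb")
})

test_that("synchronous updates respect the declared semantics", {
  idn <- parse_network(c("A = A", "B = B"))
  s <- c(1L, 0L)
  expect_equal(synchronous_step(idn, s), s)
  # simultaneous update: swap network exchanges bits in one step
  swap <- parse_network(c("A = B", "B = A"))
  expect_equal(synchronous_step(swap, c(1L, 0L)), c(0L, 1L))
})

test_that("attractor enumeration finds fixed points, cycles, and basins", {
  idn <- parse_network(c("A = A", "B = B"))
  at <- enumerate_attractors(idn)
  expect_length(at$attractors, 4L)
  expect_true(all(vapply(at$attractors, `[[`, 0L, "basin_size") == 1L))
  neg <- parse_network("A = NOT A")
  at2 <- enumerate_attractors(neg)
  expect_length(at2$attractors, 1L)
  expect_equal(at2$attractors[[1]]$length, 2L)
  expect_equal(at2$attractors[[1]]$basin_size, 2L)
  # basins partition the state space
  net <- two_gene_net()
  at3 <- enumerate_attractors(net)
  expect_equal(sum(vapply(at3$attractors, `[[`, 0L, "basin_size")), 4L)
  expect_true(all(at3$basin > 0L))
})

test_that("the cell-cycle fixture has one quiescent fixed point and a 7-cycle", {
  net <- cellcycle_network()
  at <- enumerate_attractors(net)
  lens <- sort(vapply(at$attractors, `[[`, 0L, "length"))
  expect_equal(lens, c(1L, 7L))
  fp <- at$attractors[[which(lens == 1L)[1]]]
  fp_state <- fp$states[1, ]
  expect_equal(unname(fp_state[c("Rb", "p27", "Cdh1")]), c(1L, 1L, 1L))
  expect_equal(unname(fp_state["CycD"]), 0L)
  # the cycle lives on the CycD-on half of state space
  cyc <- at$attractors[[which(vapply(at$attractors, `[[`, 0L,
                                     "length") == 7L)]]
  expect_true(all(cyc$states[, "CycD"] == 1L))
})

test_that("long perturbation-free simulations recur exactly on attractors", {
  net <- two_gene_net()
  at <- enumerate_attractors(net)
  recurrent <- sort(unique(unlist(lapply(at$attractors, `[[`, "indices"))))
  seen <- integer(0)
  for (start in seq_len(4L)) {
    s0 <- lpbn:::.index_to_state(start, 2L)
    traj <- simulate_trajectory(net, p = 0, steps = 20, init = s0)
    tail_states <- lpbn:::.state_to_index(traj[11:21, , drop = FALSE])
    seen <- union(seen, tail_states)
  }
  expect_setequal(seen, recurrent)
})

test_that("the perturbed kernel has the closed form p^H (1-p)^(n-H)", {
  neg <- parse_network("A = NOT A")
  P0 <- transition_matrix(neg, 0)
  expect_equal(P0, matrix(c(0, 1, 1, 0), 2))
  Phalf <- transition_matrix(neg, 0.4999999)
  expect_true(all(abs(Phalf - 0.5) < 1e-6))
  P <- transition_matrix(neg, 0.001)
  expect_equal(P[1, 2], 0.999)
  expect_equal(P[1, 1], 0.001)
  net <- cellcycle_network()
  Pc <- transition_matrix(net, 0.001)
  expect_true(all(abs(rowSums(Pc) - 1) < 1e-12))
  expect_error(transition_matrix(neg, 0.5), "p")
})

test_that("stationary distributions solve mu P = mu", {
  P2 <- matrix(c(0.5, 0.5, 0.5, 0.5), 2)
  expect_equal(stationary_distribution(P2), c(0.5, 0.5))
  expect_error(stationary_distribution(diag(2)), "ergodic|unique")
  # random ergodic chains vs eigen-decomposition oracle
  set.seed(31)
  for (rep in 1:5) {
    P <- matrix(rexp(16 * 16), 16)
    P <- P / rowSums(P)
    mu_pow <- stationary_distribution(P, method = "power")
    mu_dir <- stationary_distribution(P, method = "direct")
    ev <- eigen(t(P))
    k <- which.min(abs(ev$values - 1))
    mu_eig <- Re(ev$vectors[, k]); mu_eig <- mu_eig / sum(mu_eig)
    expect_equal(mu_pow, mu_eig, tolerance = 1e-8)
    expect_equal(mu_dir, mu_eig, tolerance = 1e-8)
    expect_lte(sum(abs(drop(mu_pow %*% P) - mu_pow)), 1e-10)
    expect_equal(sum(mu_pow), 1, tolerance = 1e-12)
  }
})

test_that("stationary mass concentrates on attractors as p shrinks", {
  net <- cellcycle_network()
  at <- enumerate_attractors(net)
  attr_idx <- unlist(lapply(at$attractors, `[[`, "indices"))
  off_mass <- vapply(c(1e-2, 1e-3, 1e-4), function(p) {
    mu <- stationary_distribution(transition_matrix(net, p),
                                  method = "direct")
    1 - sum(mu[attr_idx])
  }, numeric(1))
  expect_true(all(diff(off_mass) < 0))
})

test_that("KL divergence is a floored, nonnegative comparison", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3))
  set.seed(32)
  for (i in 1:10) {
    mu <- selector_probs(rnorm(6))
    nu <- selector_probs(rnorm(6))
    expect_gte(kl_divergence(mu, nu), 0)
  }
  # flooring keeps zero-mass reference states finite
  expect_true(is.finite(kl_divergence(c(0.5, 0.5), c(1, 0))))
})

test_that("perturbed simulation is reproducible and ergodic in the limit", {
  neg <- parse_network("A = NOT A")
  set.seed(33); t1 <- simulate_trajectory(neg, 0.2, 500)
  set.seed(33); t2 <- simulate_trajectory(neg, 0.2, 500)
  expect_identical(t1, t2)
  fp_net <- parse_network("A = A")
  traj <- simulate_trajectory(fp_net, 0, 50, init = 1L)
  expect_true(all(traj == 1L))
  # occupation frequencies approach the stationary law
  set.seed(34)
  long <- simulate_trajectory(neg, 0.2, 100000)
  mu <- stationary_distribution(transition_matrix(neg, 0.2),
                                method = "direct")
  freq <- tabulate(lpbn:::.state_to_index(long), 2) / (nrow(long))
  expect_equal(freq, mu, tolerance = 0.01)
})

test_that("transition fitting recovers simple realizable dynamics", {
  set.seed(35)
  # constant gene: always 1 next step
  const_net <- parse_network(c("A := 1", "B = A"))
  traj <- simulate_trajectory(const_net, 0.02, 3000)
  fit <- fit_transition_lpbn(traj, N = 6, epochs = 2)
  Z <- cbind(lpbn:::.all_states(2), 0L, 1L)
  pA <- head_forward(fit$models[[1]]$head,
                     lpbn_forward(map_structure(fit$models[[1]]$policy), Z))
  expect_true(all(pA > 0.9))
  # negation dynamics: learned MAP computes NOT x with perfect accuracy
  set.seed(36)
  neg <- parse_network("A = NOT A")
  traj2 <- simulate_trajectory(neg, 0.05, 3000)
  fit2 <- fit_transition_lpbn(traj2, N = 6, epochs = 2)
  learned2 <- lpbn_to_network(fit2)
  expect_equal(synchronous_step(learned2, 0L), 1L)
  expect_equal(synchronous_step(learned2, 1L), 0L)
  # two-gene AND network reproduces the full truth table and attractors
  set.seed(37)
  net <- two_gene_net()
  traj3 <- simulate_trajectory(net, 0.1, 8000)
  fit3 <- fit_transition_lpbn(traj3, N = 8, epochs = 4)
  learned3 <- lpbn_to_network(fit3)
  S <- lpbn:::.all_states(2)
  expect_equal(synchronous_step(learned3, S), synchronous_step(net, S))
  at_t <- enumerate_attractors(net)
  at_l <- enumerate_attractors(learned3)
  expect_equal(sort(vapply(at_l$attractors, `[[`, 0L, "length")),
               sort(vapply(at_t$attractors, `[[`, 0L, "length")))
  expect_error(fit_transition_lpbn(matrix(0L, 1, 3)), "short")
})
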