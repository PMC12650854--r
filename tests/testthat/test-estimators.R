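test_that("score-function gradient matches exhaustive enumeration", {
  # single unit, m = 1 so only the operator slot matters; uniform 4-way
  pol <- new_selector_policy(1, 1)
  F_fun <- function(s) as.numeric(s$O == 3L)          # rewards XOR
  ex <- exact_expectation(pol, F_fun)
  expect_equal(ex$grad$o[1, 3], 0.25 * 0.75)          # chosen slot
  expect_equal(ex$grad$o[1, 1], -0.0625)              # an unchosen slot
  # constant feedback has zero expected gradient (zero-mean score)
  ex_const <- exact_expectation(pol, function(s) 3.7)
  expect_true(all(abs(ex_const$grad$o) < 1e-12))
  expect_error(score_function_grad(pol, map_structure(pol), NaN), "finite")
})

test_that("Monte-Carlo score gradients are unbiased for any fixed baseline", {
  set.seed(21)
  pol <- new_selector_policy(1, 2, init_sd = 0.4)
  F_tab <- array(runif(2 * 2 * 4), dim = c(2, 2, 4))
  F_fun <- function(s) F_tab[s$A, s$B, s$O]
  ex <- exact_expectation(pol, F_fun)
  for (b in c(0, 0.5)) {
    n <- 20000
    acc <- matrix(0, 1, 4)
    acc2 <- matrix(0, 1, 4)
    for (i in seq_len(n)) {
      s <- sample_structure(pol)
      g <- score_function_grad(pol, s, F_fun(s), b)
      acc <- acc + g$o
      acc2 <- acc2 + g$o^2
    }
    mc_mean <- acc / n
    mc_se <- sqrt(pmax(acc2 / n - mc_mean^2, 0) / n)
    expect_true(all(abs(mc_mean - ex$grad$o) < 3 * mc_se + 1e-8),
                info = paste("baseline", b))
  }
})

test_that("EMA baseline updates as a convex combination", {
  st <- list(b = 0, decay = 0.95)
  expect_equal(ema_update(st, 1)$b, 0.05)
  st2 <- list(b = 2.5, decay = 0.95)
  expect_equal(ema_update(st2, 2.5)$b, 2.5)            # fixed point
  st3 <- new_baseline(0.9)
  expect_true(is.na(st3$b))
  st3 <- ema_update(st3, 4)                            # initializes to F
  expect_equal(st3$b, 4)
  for (i in 1:100) st3 <- ema_update(st3, 1)
  expect_equal(st3$b, 1, tolerance = 1e-3)             # geometric approach
  expect_error(new_baseline(0.5), "decay")
})

test_that("the optimal constant baseline minimizes the second moment", {
  expect_equal(optimal_constant_baseline(c(2, 2, 2), c(1, 5, 3)), 2)
  set.seed(22)
  F_s <- rnorm(5000, mean = 1.3)
  nrm <- rexp(5000)                                    # independent of F
  expect_equal(optimal_constant_baseline(F_s, nrm), mean(F_s),
               tolerance = 0.1)
  expect_error(optimal_constant_baseline(c(1, 2), c(0, 0)), "zero")
  # grid oracle on an enumerable policy: E||g_b||^2 convex in b, min at b*
  pol <- new_selector_policy(1, 2, init_sd = 0.3)
  F_tab <- array(runif(16), dim = c(2, 2, 4))
  F_fun <- function(s) F_tab[s$A, s$B, s$O]
  structs <- enumerate_structures(1, 2, 4)
  second_moment <- function(b) {
    sum(vapply(structs, function(s) {
      g <- score_function_grad(pol, s, F_fun(s), b)
      structure_prob(pol, s) * sum(c(g$a, g$b, g$o)^2)
    }, numeric(1)))
  }
  Fv <- vapply(structs, F_fun, numeric(1))
  nv <- vapply(structs, function(s) {
    g <- score_function_grad(pol, s, 1, 0)             # score itself (F=1,b=0)
    sum(c(g$a, g$b, g$o)^2)
  }, numeric(1))
  pv <- vapply(structs, function(s) structure_prob(pol, s), numeric(1))
  b_star <- optimal_constant_baseline(Fv, nv * pv)
  grid <- seq(min(Fv), max(Fv), length.out = 41)
  expect_equal(grid[which.min(vapply(grid, second_moment, numeric(1)))],
               b_star, tolerance = diff(range(Fv)) / 20)
})

test_that("entropy and its gradient are exact", {
  expect_equal(categorical_entropy(rep(0.25, 4)), log(4))
  expect_equal(categorical_entropy(c(1, 0, 0)), 0)
  set.seed(23)
  for (i in 1:10) {
    p <- selector_probs(rnorm(5))
    expect_lte(categorical_entropy(p), log(5) + 1e-12)
  }
  expect_equal(entropy_grad(rep(1.3, 6)), rep(0, 6))
  # central finite differences
  l <- rnorm(5)
  g <- entropy_grad(l)
  eps <- 1e-6
  for (i in 1:5) {
    lp <- l; lp[i] <- lp[i] + eps
    lm <- l; lm[i] <- lm[i] - eps
    fd <- (categorical_entropy(selector_probs(lp)) -
             categorical_entropy(selector_probs(lm))) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-6)
  }
  # concentrated logits are pushed back toward uniform
  l2 <- c(4, 0, 0)
  g2 <- entropy_grad(l2)
  expect_lt(g2[1], 0)
  expect_true(all(g2[2:3] > 0))
})

test_that("entropy weight anneals linearly to zero at half budget", {
  expect_equal(anneal_entropy(1e-3, 0, 100), 1e-3)
  expect_equal(anneal_entropy(1e-3, 50, 100), 0)
  expect_equal(anneal_entropy(1e-3, 100, 100), 0)
  expect_equal(anneal_entropy(5e-3, 25, 100), 2.5e-3)
})

test_that("with zero feedback and entropy bonus, logits flow to uniform", {
  l <- c(2, -1, 0.5, 0)
  for (i in 1:2000) l <- l + 0.5 * entropy_grad(l)
  p <- selector_probs(l)
  expect_equal(p, rep(0.25, 4), tolerance = 1e-4)
})

test_that("Gumbel-Softmax relaxation has the right limits and law", {
  logits <- c(1, 0, -1)
  noise <- c(0.3, 0.1, -0.5)
  out_small_tau <- gumbel_softmax_sample(logits, 1e-6, noise)
  hard <- which.max(logits + noise)
  expect_equal(out_small_tau$hard, hard)
  expect_equal(out_small_tau$relaxed[hard], 1, tolerance = 1e-9)
  expect_equal(gumbel_softmax_sample(rep(0, 4), 0.7, rep(0, 4))$relaxed,
               rep(0.25, 4))
  expect_error(gumbel_softmax_sample(logits, 0), "tau")
  # Gumbel-Max: hard argmax is Categorical(softmax(logits))
  set.seed(24)
  n <- 20000
  draws <- vapply(seq_len(n),
                  function(i) gumbel_softmax_sample(logits, 1)$hard,
                  integer(1))
  p <- selector_probs(logits)
  freq <- tabulate(draws, 3) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 3 * se + 1e-9))
})

test_that("Rao-Blackwellization preserves the mean and lowers variance", {
  logits <- c(0.5, -0.3, 0.1)
  p <- selector_probs(logits)
  # aux randomness: a second independent uniform 2-way choice
  F_joint <- matrix(c(1, 0, 2, 1, 0, 3), nrow = 3)     # [choice, aux]
  cond_F <- rowMeans(F_joint)
  expect_error(rao_blackwell_grad(logits, 1, cond_F[1:2]), "entry")
  # constant conditional table: zero expected gradient
  g0 <- Reduce(`+`, lapply(1:3, function(k)
    p[k] * rao_blackwell_grad(logits, k, rep(2, 3), 0)))
  expect_true(all(abs(g0) < 1e-12))
  # exact joint enumeration: means agree, Var(RB) <= Var(raw), per logit
  raw_mean <- matrix(0, 1, 3); raw_m2 <- matrix(0, 1, 3)
  rb_mean <- matrix(0, 1, 3); rb_m2 <- matrix(0, 1, 3)
  for (k in 1:3) for (aux in 1:2) {
    pr <- p[k] * 0.5
    sc <- -p; sc[k] <- sc[k] + 1
    raw <- F_joint[k, aux] * sc
    rb <- rao_blackwell_grad(logits, k, cond_F, 0)
    raw_mean <- raw_mean + pr * raw
    raw_m2 <- raw_m2 + pr * raw^2
    rb_mean <- rb_mean + pr * rb
    rb_m2 <- rb_m2 + pr * rb^2
  }
  expect_equal(c(raw_mean), c(rb_mean), tolerance = 1e-12)
  expect_true(all(rb_m2 - rb_mean^2 <= raw_m2 - raw_mean^2 + 1e-12))
})

test_that("straight-through gradients pass through with clipping", {
  expect_equal(straight_through_grad(1L, 0.7, 0), 0)
  expect_equal(straight_through_grad(1L, 0.7, 0.42), 0.42)
  expect_equal(straight_through_grad(0L, 0.3, -3.5), -1)
  expect_error(straight_through_grad(1L, 1, 0.1), "surrogate")
})

test_that("advantage and gradient clipping follow the stated bounds", {
  expect_equal(clip_advantage(7), 5)
  expect_equal(clip_advantage(c(-9, 0.3)), c(-5, 0.3))
  g3 <- c(3, 0, 0)
  expect_equal(clip_gradient_norm(g3), g3)
  g10 <- c(10, 0, 0)
  expect_equal(sqrt(sum(clip_gradient_norm(g10)^2)), 5)
  expect_equal(clip_gradient_norm(g10)[1], 5)
})

test_that("baseline choice leaves the exact expected gradient unchanged", {
  pol <- new_selector_policy(2, 2, init_sd = 0.2)
  F_fun <- function(s) s$A[1] + 0.5 * (s$O[2] == 2L)
  structs <- enumerate_structures(2, 2, 4)
  for (b in c(0, 0.8)) {
    g <- list(o = matrix(0, 2, 4))
    ga <- matrix(0, 2, 2)
    for (s in structs) {
      pr <- structure_prob(pol, s)
      gs <- score_function_grad(pol, s, F_fun(s), b)
      g$o <- g$o + pr * gs$o
      ga <- ga + pr * gs$a
    }
    if (b == 0) { ref_o <- g$o; ref_a <- ga }
    else {
      expect_equal(g$o, ref_o, tolerance = 1e-12)
      expect_equal(ga, ref_a, tolerance = 1e-12)
    }
  }
})
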