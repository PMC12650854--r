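test_that("operator truth tables are correct", {
  ref <- list(AND = c(0L, 0L, 0L, 1L), OR = c(0L, 1L, 1L, 1L),
              XOR = c(0L, 1L, 1L, 0L), NAND = c(1L, 1L, 1L, 0L))
  for (op in names(ref)) {
    tab <- op_truth_table(function(a, b) apply_operator(op, a, b))
    expect_equal(tab, ref[[op]], info = op)
  }
  expect_error(apply_operator("IMPLIES", 1, 0), "unknown")
})

test_that("softmax selector probabilities behave as a simplex map", {
  expect_equal(selector_probs(rep(0, 4)), rep(0.25, 4))
  l <- c(0.3, -1, 2)
  expect_equal(selector_probs(l), selector_probs(l + 17.5))
  expect_equal(selector_probs(c(log(2), 0)), c(2 / 3, 1 / 3))
  expect_error(selector_probs(c(0, Inf)), "finite")
})

test_that("structure sampling is reproducible and matches its distribution", {
  pol <- new_selector_policy(1, 4)
  pol$a_logits[1, 2] <- 1e6
  s <- sample_structure(pol)
  expect_equal(s$A, 2L)                       # concentrated logit wins
  set.seed(42); s1 <- sample_structure(pol)
  set.seed(42); s2 <- sample_structure(pol)
  expect_identical(s1, s2)
  # Monte-Carlo frequencies of the operator slot vs exact probabilities
  pol2 <- new_selector_policy(1, 2)
  pol2$o_logits[1, ] <- c(0.7, -0.2, 0.1, 0)
  p <- selector_probs(pol2$o_logits[1, ])
  set.seed(7)
  n <- 20000
  draws <- vapply(seq_len(n), function(i) sample_structure(pol2)$O, integer(1))
  freq <- tabulate(draws, 4) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 3 * se + 1e-9))
})

test_that("MAP decoding takes the argmax with lowest-index ties", {
  pol <- new_selector_policy(2, 3)
  pol$a_logits[1, ] <- c(0, 3, 1)
  pol$a_logits[2, ] <- c(2, 2, 0)             # tie -> first index
  s <- map_structure(pol)
  expect_equal(s$A, c(2L, 1L))
  pol$b_logits[1, 3] <- 50
  pol$o_logits[1, 4] <- 50
  s <- map_structure(pol)
  expect_equal(s$B[1], 3L)
  expect_equal(s$O[1], 4L)
})

test_that("structure log-probabilities normalize over the structure space", {
  pol <- new_selector_policy(1, 2)
  s <- structure(list(A = 1L, B = 2L, O = 3L), class = "lpbn_structure")
  expect_equal(structure_log_prob(pol, s), -log(16))
  # near-deterministic policy assigns ~0 to its own MAP
  pol$a_logits[1, 1] <- 100; pol$b_logits[1, 2] <- 100
  pol$o_logits[1, 3] <- 100
  expect_equal(structure_log_prob(pol, map_structure(pol)), 0,
               tolerance = 1e-10)
  # total probability over all structures is 1 (N = 2 units)
  pol2 <- new_selector_policy(2, 3, init_sd = 0.5)
  tot <- sum(vapply(enumerate_structures(2, 3, 4),
                    function(s) structure_prob(pol2, s), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("the Boolean forward pass composes units as declared", {
  z <- c(1L, 0L, 1L)
  s <- structure(list(A = 1L, B = 3L, O = 3L), class = "lpbn_structure")
  expect_equal(lpbn_forward(s, z), 0L)        # XOR(1, 1)
  # unary behaviors through a constant-one bit
  z2 <- c(1L, 0L, 0L, 1L)                     # last bit CONST1
  s_not <- structure(list(A = 1:2, B = c(4L, 4L), O = c(3L, 3L)),
                     class = "lpbn_structure")
  expect_equal(lpbn_forward(s_not, z2), c(0L, 1L))   # XOR with 1 = NOT
  s_id <- structure(list(A = 1:2, B = c(4L, 4L), O = c(1L, 1L)),
                    class = "lpbn_structure")
  expect_equal(lpbn_forward(s_id, z2), c(1L, 0L))    # AND with 1 = identity
  # matrix forward agrees with rowwise forward
  Z <- rbind(z2, c(0L, 1L, 1L, 1L))
  H <- lpbn_forward(s_not, Z)
  expect_equal(H[1, ], lpbn_forward(s_not, Z[1, ]))
  expect_equal(H[2, ], lpbn_forward(s_not, Z[2, ]))
})

test_that("output heads map features to the declared ranges", {
  h <- c(1L, 0L, 1L)
  expect_equal(head_forward(new_head("logistic", 3), h), 0.5)
  expect_equal(head_forward(new_head("policy", 3, K = 2), h), c(0.5, 0.5))
  lin <- new_head("linear", 2); lin$w <- c(1, 1)
  expect_equal(head_forward(lin, c(1L, 0L)), 1)
  sm <- new_head("softmax", 3, K = 4)
  expect_equal(sum(head_forward(sm, h)), 1)
})

test_that("parameter counting and MLP width matching obey the 10% rule", {
  expect_equal(param_count(20, 40, 4, new_head("logistic", 20)), 1701L)
  expect_equal(param_count(1, 2, 4, new_head("logistic", 1)), 10L)
  counts <- vapply(c(5L, 10L, 15L), function(N)
    param_count(N, 12, 4, new_head("logistic", N)), numeric(1))
  expect_equal(diff(diff(counts)), 0)                 # affine in N
  # brute-force oracle over H
  target <- 1701; d_in <- 8; d_out <- 1
  H <- match_mlp_width(target, d_in, d_out)
  all_counts <- vapply(1:500, function(h) mlp_param_count(h, d_in, d_out),
                       numeric(1))
  feasible <- which(abs(all_counts - target) / target <= 0.10)
  expect_true(H %in% feasible)
  expect_equal(abs(mlp_param_count(H, d_in, d_out) - target),
               min(abs(all_counts[feasible] - target)))
  expect_lte(abs(mlp_param_count(H, d_in, d_out) - target) / target, 0.10)
  # monotone in the target count
  Hs <- vapply(seq(200, 2000, by = 100),
               function(p) match_mlp_width(p, 8, 1), integer(1))
  expect_true(all(diff(Hs) >= 0))
})

test_that("compiled NAND indicators fire exactly on their pattern", {
  # NOT gate base case
  circ_not <- compile_indicator(c(0L))
  expect_equal(eval_circuit(circ_not, 0L), 1L)
  expect_equal(eval_circuit(circ_not, 1L), 0L)
  for (pattern in list(c(1L, 0L), c(1L, 1L, 1L), c(0L, 1L, 0L, 1L))) {
    d <- length(pattern)
    circ <- compile_indicator(pattern)
    grid <- as.matrix(expand.grid(rep(list(0:1), d)))
    for (i in seq_len(nrow(grid))) {
      expect_equal(eval_circuit(circ, grid[i, ]),
                   as.integer(all(grid[i, ] == pattern)))
    }
  }
})

test_that("every 2-input Boolean function is reachable with <= 3 units", {
  ops <- lpbn_operators()
  tab_of <- function(f) paste(op_truth_table(f), collapse = "")
  # signals reachable with k units, tracked as truth-table strings
  base <- list(function(a, b) a, function(a, b) b)
  found <- new.env()
  cost <- new.env()
  for (f in base) assign(tab_of(f), 0L, envir = cost)
  frontier <- base
  all_funs <- base
  for (round in 1:3) {
    new_funs <- list()
    for (g1 in all_funs) for (g2 in all_funs) {
      c1 <- get(tab_of(g1), envir = cost); c2 <- get(tab_of(g2), envir = cost)
      for (op in ops) {
        f <- local({
          g1l <- g1; g2l <- g2; opl <- op
          function(a, b) apply_operator(opl, g1l(a, b), g2l(a, b))
        })
        key <- tab_of(f)
        newc <- c1 + c2 + 1L
        if (newc <= 3L &&
            (!exists(key, envir = cost) || get(key, envir = cost) > newc)) {
          assign(key, newc, envir = cost)
          new_funs[[length(new_funs) + 1L]] <- f
        }
      }
    }
    all_funs <- c(all_funs, new_funs)
  }
  reachable <- ls(envir = cost)
  all_tables <- apply(as.matrix(expand.grid(rep(list(0:1), 4))), 1,
                      paste, collapse = "")
  expect_true(all(all_tables %in% reachable))
})

test_that("compiled indicators plus a linear head interpolate any map", {
  # exact interpolation of arbitrary targets on a finite bit-vector set
  set.seed(9)
  d <- 3
  X <- unique(matrix(rbinom(5 * d, 1, 0.5), ncol = d))
  f_star <- rnorm(nrow(X))
  circs <- lapply(seq_len(nrow(X)), function(i) compile_indicator(X[i, ]))
  predict_f <- function(z)
    sum(f_star * vapply(circs, eval_circuit, integer(1), z = z))
  for (i in seq_len(nrow(X))) {
    expect_equal(predict_f(X[i, ]), f_star[i], tolerance = 1e-12)
  }
  # off-support points map to 0 (no indicator fires)
  grid <- as.matrix(expand.grid(rep(list(0:1), d)))
  on_support <- apply(grid, 1, function(g)
    any(apply(X, 1, function(x) all(x == g))))
  for (i in which(!on_support)) expect_equal(predict_f(grid[i, ]), 0)
})

test_that("forward pass is pure", {
  set.seed(10)
  pol <- new_selector_policy(5, 6, init_sd = 1)
  s <- map_structure(pol)
  Z <- matrix(rbinom(60, 1, 0.5), 10, 6)
  expect_identical(lpbn_forward(s, Z), lpbn_forward(s, Z))
})
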