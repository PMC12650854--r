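# shared oracles and fixtures, built in code

# enumerate every structure of a small policy as a data frame of index
# triples per unit; used by exact-gradient and normalization oracles
enumerate_structures <- function(N, m, k_ops) {
  slots <- rep(list(seq_len(m), seq_len(m), seq_len(k_ops)), N)
  grid <- do.call(expand.grid, slots)
  lapply(seq_len(nrow(grid)), function(i) {
    v <- as.integer(grid[i, ])
    structure(list(A = v[seq(1, 3 * N, by = 3)],
                   B = v[seq(2, 3 * N, by = 3)],
                   O = v[seq(3, 3 * N, by = 3)]),
              class = "lpbn_structure")
  })
}

# exact probability of a structure under a policy
structure_prob <- function(policy, s) exp(structure_log_prob(policy, s))

# exact expected value and expected score-function gradient of a scalar
# feedback F(structure) by full enumeration
exact_expectation <- function(policy, F_fun) {
  k_ops <- length(policy$operators)
  structs <- enumerate_structures(policy$N, policy$m, k_ops)
  EF <- 0
  g <- list(a = matrix(0, policy$N, policy$m),
            b = matrix(0, policy$N, policy$m),
            o = matrix(0, policy$N, k_ops))
  for (s in structs) {
    pr <- structure_prob(policy, s)
    f <- F_fun(s)
    EF <- EF + pr * f
    gs <- score_function_grad(policy, s, f, 0)
    g$a <- g$a + pr * gs$a
    g$b <- g$b + pr * gs$b
    g$o <- g$o + pr * gs$o
  }
  list(EF = EF, grad = g)
}

# truth table (as a length-4 0/1 vector over inputs 00,01,10,11) of a
# two-input Boolean function
op_truth_table <- function(f) {
  vapply(list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)),
         function(ab) f(ab[1L], ab[2L]), integer(1L))
}

# tiny deterministic two-gene network: A' = A AND B, B' = B
two_gene_net <- function() parse_network(c("A = A AND B", "B = B"))
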