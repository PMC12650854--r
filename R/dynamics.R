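#' Parse a Boolean network rule file
#'
#' One gene per line, \code{NAME = expr} with operators \code{AND}, \code{OR},
#' \code{NOT}, \code{XOR}, \code{NAND} and parentheses; \code{NAME := 0} or
#' \code{NAME := 1} freezes a gene at a constant. Lines starting with
#' \code{#} and blank lines are ignored. Synchronous semantics: every
#' right-hand side reads the *current* state, all genes update together.
#'
#' @param text character vector of rule lines, or a single string with
#'   newlines, or a file path (when \code{file = TRUE}).
#' @param file logical; treat \code{text} as a path.
#' @return object of class \code{"boolean_network"}: \code{genes} (ordered
#'   names), \code{n}, \code{rules} (deparsed text per gene), and
#'   \code{update(states)}, a vectorized successor map taking an s x n 0/1
#'   matrix to the s x n matrix of synchronous successors.
#' @examples
#' net <- parse_network(c("A = NOT B", "B = A"))
#' synchronous_step(net, c(1, 1))
#' @export
parse_network <- function(text, file = FALSE) {
  if (file) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text <- trimws(text)
  text <- text[nzchar(text) & !startsWith(text, "#")]
  frozen <- grepl(":=", text, fixed = TRUE)
  split_at <- ifelse(frozen, ":=", "=")
  parts <- mapply(function(ln, sep) {
    i <- regexpr(sep, ln, fixed = TRUE)
    c(trimws(substr(ln, 1L, i - 1L)),
      trimws(substr(ln, i + attr(i, "match.length"), nchar(ln))))
  }, text, split_at, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  genes <- vapply(parts, `[`, "", 1L)
  exprs <- vapply(parts, `[`, "", 2L)
  if (anyDuplicated(genes)) stop("duplicate gene name(s)")
  asts <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    asts[[i]] <- if (frozen[i]) {
      v <- as.integer(exprs[i])
      if (!v %in% c(0L, 1L)) stop("line ", i, ": frozen value must be 0 or 1")
      list(kind = "const", value = v)
    } else {
      tryCatch(.parse_bool_expr(exprs[i], genes),
               error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                        call. = FALSE))
    }
  }
  update <- function(states) {
    states <- matrix(as.integer(states), ncol = length(genes))
    colnames(states) <- genes
    out <- vapply(asts, function(a) as.integer(.eval_bool_ast(a, states)),
                  integer(nrow(states)))
    matrix(out, nrow = nrow(states))
  }
  structure(list(genes = genes, n = length(genes), rules = exprs,
                 frozen = frozen, update = update),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("boolean_network: %d genes (%s), 2^%d = %d states\n",
              x$n, paste(utils::head(x$genes, 5L), collapse = ", "),
              x$n, 2^x$n))
  invisible(x)
}

# tokenizer + recursive-descent parser; precedence OR < XOR < AND/NAND < NOT
.parse_bool_expr <- function(src, genes) {
  toks <- regmatches(src, gregexpr("[A-Za-z_][A-Za-z0-9_]*|[01]|\\(|\\)",
                                   src))[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    l <- parse_xor()
    while (peek() == "OR") { take(); l <- list(kind = "OR", l = l, r = parse_xor()) }
    l
  }
  parse_xor <- function() {
    l <- parse_and()
    while (peek() == "XOR") { take(); l <- list(kind = "XOR", l = l, r = parse_and()) }
    l
  }
  parse_and <- function() {
    l <- parse_unary()
    repeat {
      if (peek() == "AND") { take(); l <- list(kind = "AND", l = l, r = parse_unary()) }
      else if (peek() == "NAND") { take(); l <- list(kind = "NAND", l = l, r = parse_unary()) }
      else break
    }
    l
  }
  parse_unary <- function() {
    t <- peek()
    if (t == "NOT") { take(); return(list(kind = "NOT", l = parse_unary())) }
    if (t == "(") {
      take(); e <- parse_or()
      if (take() != ")") stop("expected ')'")
      return(e)
    }
    if (t %in% c("0", "1")) { take(); return(list(kind = "const", value = as.integer(t))) }
    if (t %in% genes) { take(); return(list(kind = "var", name = t)) }
    stop("unknown name or token: '", t, "'")
  }
  e <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens after expression")
  e
}

.eval_bool_ast <- function(a, states) {
  switch(a$kind,
    const = rep(a$value == 1L, nrow(states)),
    var   = states[, a$name] == 1L,
    NOT   = !.eval_bool_ast(a$l, states),
    AND   = .eval_bool_ast(a$l, states) & .eval_bool_ast(a$r, states),
    OR    = .eval_bool_ast(a$l, states) | .eval_bool_ast(a$r, states),
    XOR   = xor(.eval_bool_ast(a$l, states), .eval_bool_ast(a$r, states)),
    NAND  = !(.eval_bool_ast(a$l, states) & .eval_bool_ast(a$r, states)),
    stop("bad AST node"))
}

#' One synchronous update of a Boolean network
#'
#' @param net a \code{"boolean_network"}.
#' @param state 0/1 vector of length n, or an s x n matrix of states.
#' @return successor state(s), same shape.
#' @export
synchronous_step <- function(net, state) {
  if (is.matrix(state)) return(net$update(state))
  drop(net$update(matrix(state, nrow = 1L)))
}

# 1-based state index <-> bit row (gene 1 = least-significant bit)
.state_to_index <- function(states) {
  states <- matrix(states, ncol = ncol(as.matrix(states)))
  as.integer(states %*% 2^(seq_len(ncol(states)) - 1L)) + 1L
}

.index_to_state <- function(idx, n) {
  v <- idx - 1L
  vapply(seq_len(n), function(j) as.integer((v %/% 2^(j - 1L)) %% 2L),
         integer(length(idx)))
}

.all_states <- function(n) {
  m <- .index_to_state(seq_len(2^n), n)
  matrix(m, ncol = n)
}

# successor index for every state, by one vectorized sweep
.successor_table <- function(net) {
  S <- .all_states(net$n)
  .state_to_index(net$update(S))
}

#' Exhaustively enumerate attractors of the synchronous dynamics
#'
#' Iterates every one of the 2^n states to its terminal cycle. Each
#' attractor is an ordered cycle of states (length 1 = fixed point),
#' canonicalized to start at its smallest state index; basin sizes count
#' the states draining into each attractor (basins partition state space).
#'
#' @param net a \code{"boolean_network"} with n <= 20.
#' @return object of class \code{"attractor_set"}: list with
#'   \code{attractors} (each a list with \code{states} matrix, \code{length},
#'   \code{basin_size}) and \code{basin} (attractor id per state index).
#' @export
enumerate_attractors <- function(net) {
  if (net$n > 20L) stop("exhaustive enumeration supported for n <= 20 genes")
  S <- 2^net$n
  succ <- .successor_table(net)
  attr_id <- integer(S)           # 0 = unknown
  cycles <- list()
  for (s0 in seq_len(S)) {
    if (attr_id[s0] != 0L) next
    path <- integer(0)
    onpath <- integer(S)          # position within current path, 0 if absent
    s <- s0
    while (attr_id[s] == 0L && onpath[s] == 0L) {
      path <- c(path, s)
      onpath[s] <- length(path)
      s <- succ[s]
    }
    if (attr_id[s] != 0L) {
      aid <- attr_id[s]
    } else {
      cyc <- path[onpath[s]:length(path)]
      k <- which.min(cyc)
      cyc <- c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)])
      cycles[[length(cycles) + 1L]] <- cyc
      aid <- length(cycles)
    }
    attr_id[path] <- aid
  }
  attractors <- lapply(cycles, function(cyc) {
    list(states = matrix(.index_to_state(cyc, net$n), ncol = net$n,
                         dimnames = list(NULL, net$genes)),
         indices = cyc, length = length(cyc), basin_size = 0L)
  })
  tab <- tabulate(attr_id, nbins = length(cycles))
  for (i in seq_along(attractors)) attractors[[i]]$basin_size <- tab[i]
  structure(list(attractors = attractors, basin = attr_id, n = net$n,
                 genes = net$genes),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("attractor_set: %d attractor(s) over %d states\n",
              length(x$attractors), 2^x$n))
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    cat(sprintf("  [%d] %s, basin %d\n", i,
                if (a$length == 1L) "fixed point"
                else sprintf("%d-state cycle", a$length), a$basin_size))
  }
  invisible(x)
}

#' Transition matrix of the perturbed (PBN) chain
#'
#' The chain performs the synchronous update and then flips every bit
#' independently with probability p, giving the closed-form kernel
#' \code{P(x -> y) = p^H (1-p)^(n-H)} where H is the Hamming distance
#' between the deterministic successor f(x) and y. Any p > 0 makes the
#' chain irreducible and aperiodic.
#'
#' @param net a \code{"boolean_network"} with n <= 12 (dense matrix).
#' @param p per-bit flip probability in [0, 0.5).
#' @return dense 2^n x 2^n row-stochastic matrix.
#' @export
transition_matrix <- function(net, p) {
  stopifnot(p >= 0, p < 0.5)
  if (net$n > 12L) stop("dense transition matrix supported for n <= 12")
  S <- 2^net$n
  succ <- .successor_table(net)
  pc <- integer(S)                        # popcount of 0..S-1
  for (v in seq_len(S - 1L)) pc[v + 1L] <- pc[bitwShiftR(v, 1L) + 1L] + (v %% 2L)
  H <- matrix(pc[bitwXor(rep(succ - 1L, times = S),
                         rep(0:(S - 1L), each = S)) + 1L], S, S)
  if (p == 0) return(matrix(as.numeric(H == 0L), S, S))
  p^H * (1 - p)^(net$n - H)
}

#' Stationary distribution of a finite Markov chain
#'
#' Left fixed point mu with mu P = mu. \code{method = "power"} iterates
#' mu <- mu P from uniform until the L1 change falls below \code{tol};
#' \code{"direct"} solves the linear system (one row replaced by the
#' normalization constraint), which is preferable for slowly mixing chains
#' such as small-p perturbations.
#'
#' @param P row-stochastic matrix.
#' @param method "power" or "direct".
#' @param tol L1 convergence tolerance for power iteration.
#' @param max_iter iteration cap for power iteration.
#' @return probability vector mu with \code{sum(mu) = 1}.
#' @export
stationary_distribution <- function(P, method = c("power", "direct"),
                                    tol = 1e-12, max_iter = 100000L) {
  method <- match.arg(method)
  S <- nrow(P)
  if (any(abs(rowSums(P) - 1) > 1e-8)) stop("P rows must sum to 1")
  if (method == "direct") {
    A <- t(P) - diag(S)
    A[S, ] <- 1
    e <- c(rep(0, S - 1L), 1)
    mu <- solve(A, e)
    mu <- pmax(mu, 0)
    return(mu / sum(mu))
  }
  iterate <- function(mu) {
    for (it in seq_len(max_iter)) {
      mu2 <- drop(mu %*% P)
      if (sum(abs(mu2 - mu)) < tol) return(mu2 / sum(mu2))
      mu <- mu2
    }
    # oscillation without convergence indicates a periodic chain
    stop("power iteration did not converge; chain may not be ergodic")
  }
  mu1 <- iterate(rep(1 / S, S))
  # a second start detects non-uniqueness (e.g. reducible chains), which a
  # single converged run cannot
  alt <- seq_len(S); alt <- alt / sum(alt)
  mu2 <- iterate(alt)
  if (sum(abs(mu1 - mu2)) > 1e-8)
    stop("stationary distribution is not unique; chain is not ergodic")
  mu1
}

#' Kullback-Leibler divergence between two distributions
#'
#' \code{sum(mu * log(mu / nu))} in nats. The reference distribution nu is
#' floored at \code{floor} and renormalized so states with zero estimated
#' mass do not produce infinities.
#'
#' @param mu,nu probability vectors of equal length.
#' @param floor lower bound applied to nu before renormalization.
#' @return scalar >= 0 (0 iff mu equals the floored nu).
#' @export
kl_divergence <- function(mu, nu, floor = 1e-12) {
  stopifnot(length(mu) == length(nu))
  nu <- pmax(nu, floor)
  nu <- nu / sum(nu)
  keep <- mu > 0
  sum(mu[keep] * log(mu[keep] / nu[keep]))
}

#' Simulate the perturbed chain
#'
#' Each step applies the synchronous update and then independent per-bit
#' flips with probability p. Uses R's global RNG.
#'
#' @param net a \code{"boolean_network"}.
#' @param p per-bit flip probability.
#' @param steps number of transitions T.
#' @param init optional initial 0/1 state (default: uniform random).
#' @return (T+1) x n 0/1 matrix of visited states.
#' @export
simulate_trajectory <- function(net, p, steps, init = NULL) {
  n <- net$n
  s <- if (is.null(init)) stats::rbinom(n, 1L, 0.5) else as.integer(init)
  if (n <= 16L) {
    # index walk over a precomputed successor table
    succ <- .successor_table(net)
    pow <- as.integer(2^(seq_len(n) - 1L))
    idx <- integer(steps + 1L)
    idx[1L] <- .state_to_index(matrix(s, 1L))
    flips <- matrix(stats::runif(steps * n) < p, steps, n)
    cur <- idx[1L]
    for (t in seq_len(steps)) {
      cur <- succ[cur]
      if (any(flips[t, ])) {
        v <- cur - 1L
        for (j in which(flips[t, ])) v <- bitwXor(v, pow[j])
        cur <- v + 1L
      }
      idx[t + 1L] <- cur
    }
    out <- matrix(.index_to_state(idx, n), ncol = n)
  } else {
    out <- matrix(0L, steps + 1L, n)
    out[1L, ] <- s
    flips <- matrix(stats::runif(steps * n) < p, steps, n)
    for (t in seq_len(steps)) {
      s <- synchronous_step(net, s)
      s <- as.integer(xor(s == 1L, flips[t, ]))
      out[t + 1L, ] <- s
    }
  }
  colnames(out) <- net$genes
  out
}

#' Fit per-gene LPBNs to observed one-step transitions
#'
#' Learns the transition law of a Boolean system from a trajectory: for
#' each gene, a logistic-head LPBN over the substrate (current state bits
#' plus CONST0/CONST1) is trained to minimize cross-entropy between its
#' predicted next-bit probability and the empirical transitions, with
#' selector logits trained by REINFORCE with an EMA baseline and annealed
#' entropy. Transitions are aggregated by unique current state (with
#' counts as weights), so heavily revisited attractor states dominate the
#' objective exactly as they dominate the data.
#'
#' @param trajectory (T+1) x n 0/1 state matrix (from
#'   [simulate_trajectory()]) or a list with elements \code{x}, \code{y} of
#'   paired current/next state matrices.
#' @param N Boolean units per gene model.
#' @param epochs training epochs per gene; one epoch is one pass over the
#'   raw transitions (minibatches of 64 resampled from the empirical
#'   state-visitation distribution).
#' @param lr_logits,lr_head learning rates for selector logits and head.
#' @param lambda0 initial entropy weight (annealed to 0 at half budget).
#' @param ema_decay EMA baseline decay.
#' @param genes optional gene names.
#' @return object of class \code{"lpbn_dynamics_fit"}: per-gene models
#'   (policy, head, operators), gene names, substrate description.
#' @export
fit_transition_lpbn <- function(trajectory, N = 24L, epochs = 3L,
                                lr_logits = 7e-2, lr_head = 3e-1,
                                lambda0 = 1e-3, ema_decay = 0.95,
                                genes = NULL) {
  if (is.list(trajectory) && !is.matrix(trajectory)) {
    x <- trajectory$x; y <- trajectory$y
  } else {
    Tn <- nrow(trajectory)
    if (Tn < 2L) stop("trajectory too short to contain a transition")
    x <- trajectory[-Tn, , drop = FALSE]
    y <- trajectory[-1L, , drop = FALSE]
  }
  n <- ncol(x)
  if (is.null(genes)) genes <- colnames(x)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  # aggregate transitions by unique current state
  idx <- .state_to_index(x)
  ustates <- sort(unique(idx))
  w <- as.numeric(table(factor(idx, levels = ustates)))
  Xu <- matrix(.index_to_state(ustates, n), ncol = n)
  Yu <- matrix(0, length(ustates), n)   # empirical next-bit frequency
  for (g in seq_len(n)) {
    s <- rowsum(y[, g], idx)
    Yu[, g] <- s[match(ustates, as.integer(rownames(s)))] / w
  }
  Z <- cbind(Xu, 0L, 1L)                # substrate: state bits + CONST0/CONST1
  config <- lpbn_train_config(epochs = epochs, batch_size = 64L,
                              N = N, lr_logits = lr_logits,
                              lr_head = lr_head, lambda0 = lambda0,
                              ema_decay = ema_decay)
  models <- vector("list", n)
  for (g in seq_len(n)) {
    models[[g]] <- .train_lpbn_core(Z, Yu[, g], "logistic", config,
                                    weights = w, sample_by_weight = TRUE)
  }
  structure(list(models = models, genes = genes, n = n,
                 substrate = c(genes, "CONST0", "CONST1")),
            class = "lpbn_dynamics_fit")
}

#' Convert fitted per-gene LPBNs back into a Boolean network
#'
#' Decodes each gene model's MAP structure and thresholds its logistic
#' head at 0.5, yielding a deterministic synchronous network whose
#' attractors and stationary behavior can be compared against the source
#' system.
#'
#' @param fit an \code{"lpbn_dynamics_fit"}.
#' @return a \code{"boolean_network"}.
#' @export
lpbn_to_network <- function(fit) {
  maps <- lapply(fit$models, function(mod) list(
    s = map_structure(mod$policy), head = mod$head, ops = mod$operators))
  genes <- fit$genes
  n <- fit$n
  update <- function(states) {
    states <- matrix(as.integer(states), ncol = n)
    Z <- cbind(states, 0L, 1L)
    out <- vapply(maps, function(mm) {
      H <- lpbn_forward(mm$s, Z, mm$ops)
      as.integer(head_forward(mm$head, H) >= 0.5)
    }, integer(nrow(states)))
    matrix(out, nrow = nrow(states))
  }
  structure(list(genes = genes, n = n,
                 rules = rep("<learned MAP structure>", n),
                 frozen = rep(FALSE, n), update = update),
            class = "boolean_network")
}

#' The packaged mammalian cell-cycle network
#'
#' Loads the ten-gene mammalian cell-cycle Boolean model (CycD, CycE, Rb,
#' E2F, CycA, p27, Cdc20, UbcH10, Cdh1, CycB) shipped with the package;
#' see the rule file header for provenance. Its synchronous dynamics have
#' exactly one quiescent fixed point (Rb, p27, Cdh1 active) and one
#' 7-state oscillatory cycle.
#'
#' @return a \code{"boolean_network"} with 10 genes.
#' @export
cellcycle_network <- function() {
  path <- system.file("extdata", "cellcycle_mammalian.bn", package = "lpbn")
  if (!nzchar(path)) stop("cell-cycle rule file not found")
  parse_network(path, file = TRUE)
}
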