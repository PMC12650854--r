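#' The default two-input Boolean operator library
#'
#' @return character vector of operator labels, in canonical order.
#' @export
lpbn_operators <- function() c("AND", "OR", "XOR", "NAND")

#' Evaluate a named two-input Boolean operator
#'
#' @param op operator label; one of AND, OR, XOR, NAND, plus NOR and NOT
#'   (NOT ignores \code{b}) which are accepted by the rule parser.
#' @param a,b 0/1 values (vectorized).
#' @return 0/1 integer vector.
#' @export
apply_operator <- function(op, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  switch(op,
    AND  = a & b,
    OR   = a | b,
    XOR  = xor(a, b),
    NAND = !(a & b),
    NOR  = !(a | b),
    NOT  = !a,
    stop("unknown operator: ", op)) |> as.integer()
}

#' Softmax selector probabilities
#'
#' Numerically safe softmax (max-subtraction) turning a logit vector into a
#' categorical distribution.
#'
#' @param logits finite numeric vector.
#' @return probability vector summing to 1.
#' @export
selector_probs <- function(logits) {
  if (!all(is.finite(logits))) stop("logits must be finite")
  e <- exp(logits - max(logits))
  e / sum(e)
}

# row-wise softmax for a logit matrix
.softmax_rows <- function(L) {
  e <- exp(L - apply(L, 1L, max))
  e / rowSums(e)
}

#' Create a selector policy over structures
#'
#' A selector policy holds, for each of N Boolean units, three logit vectors
#' parameterizing independent categorical distributions: input-A position
#' (over the m substrate bits), input-B position, and the operator choice.
#' The softmax of each logit vector is the sampling distribution for that
#' slot. All logits start at zero (uniform) unless \code{init_sd > 0}.
#'
#' @param N number of Boolean units.
#' @param m substrate width the units read from.
#' @param operators operator label vector (default [lpbn_operators()]).
#' @param init_sd standard deviation of Gaussian logit initialization.
#' @return object of class \code{"lpbn_policy"} with matrices
#'   \code{a_logits}, \code{b_logits} (N x m) and \code{o_logits} (N x |O|).
#' @export
new_selector_policy <- function(N, m, operators = lpbn_operators(),
                                init_sd = 0) {
  stopifnot(N >= 1L, m >= 1L, length(operators) >= 1L,
            !anyDuplicated(operators))
  rmat <- function(r, c) matrix(if (init_sd > 0) stats::rnorm(r * c, 0, init_sd)
                                else 0, r, c)
  structure(list(N = as.integer(N), m = as.integer(m), operators = operators,
                 a_logits = rmat(N, m), b_logits = rmat(N, m),
                 o_logits = rmat(N, length(operators))),
            class = "lpbn_policy")
}

#' @export
print.lpbn_policy <- function(x, ...) {
  cat(sprintf("lpbn_policy: N=%d units over m=%d bits, operators {%s}\n",
              x$N, x$m, paste(x$operators, collapse = ", ")))
  invisible(x)
}

#' Sample a structure from a selector policy
#'
#' Draws, independently for every unit, an input-A index, an input-B index
#' and an operator index from the unit's categorical distributions. Uses
#' R's global RNG stream; set the seed for reproducibility.
#'
#' @param policy an \code{"lpbn_policy"}.
#' @return object of class \code{"lpbn_structure"}: integer vectors
#'   \code{A}, \code{B}, \code{O} of length N.
#' @export
sample_structure <- function(policy) {
  pa <- .softmax_rows(policy$a_logits)
  pb <- .softmax_rows(policy$b_logits)
  po <- .softmax_rows(policy$o_logits)
  A <- B <- O <- integer(policy$N)
  for (n in seq_len(policy$N)) {
    A[n] <- sample.int(policy$m, 1L, prob = pa[n, ])
    B[n] <- sample.int(policy$m, 1L, prob = pb[n, ])
    O[n] <- sample.int(length(policy$operators), 1L, prob = po[n, ])
  }
  structure(list(A = A, B = B, O = O), class = "lpbn_structure")
}

#' Maximum a posteriori structure of a policy
#'
#' Per-slot argmax of the selector logits; ties break toward the lowest
#' index, making the decoded structure deterministic.
#'
#' @param policy an \code{"lpbn_policy"}.
#' @return an \code{"lpbn_structure"}.
#' @export
map_structure <- function(policy) {
  structure(list(A = apply(policy$a_logits, 1L, which.max),
                 B = apply(policy$b_logits, 1L, which.max),
                 O = apply(policy$o_logits, 1L, which.max)),
            class = "lpbn_structure")
}

#' Log-probability of a structure under a policy
#'
#' Sum over units of the three slot log-probabilities; the selector factors
#' are independent across units and slots.
#'
#' @param policy an \code{"lpbn_policy"}.
#' @param s an \code{"lpbn_structure"} with indices in range.
#' @return scalar log-probability.
#' @export
structure_log_prob <- function(policy, s) {
  lp <- 0
  for (n in seq_len(policy$N)) {
    lp <- lp + log(selector_probs(policy$a_logits[n, ])[s$A[n]]) +
               log(selector_probs(policy$b_logits[n, ])[s$B[n]]) +
               log(selector_probs(policy$o_logits[n, ])[s$O[n]])
  }
  lp
}

#' Boolean forward pass of a sampled structure
#'
#' Given a fixed structure, each unit n computes
#' \code{op[O_n](z[A_n], z[B_n])}. Deterministic given (structure, z).
#'
#' @param s an \code{"lpbn_structure"}.
#' @param z 0/1 substrate vector, or an n x m matrix of substrate rows.
#' @param operators operator labels indexed by \code{s$O}.
#' @return 0/1 vector of length N (or n x N matrix for matrix input).
#' @export
lpbn_forward <- function(s, z, operators = lpbn_operators()) {
  if (is.matrix(z)) {
    Za <- z[, s$A, drop = FALSE]
    Zb <- z[, s$B, drop = FALSE]
    H <- matrix(0L, nrow(z), length(s$A))
    for (k in seq_along(operators)) {
      cols <- which(s$O == k)
      if (length(cols))
        H[, cols] <- apply_operator(operators[k], Za[, cols], Zb[, cols])
    }
    return(H)
  }
  mapply(function(a, b, o) apply_operator(operators[o], z[a], z[b]),
         s$A, s$B, s$O)
}

#' Construct an output head
#'
#' @param kind one of \code{"logistic"} (binary probability),
#'   \code{"linear"} (real output), \code{"softmax"} / \code{"policy"}
#'   (probability vector over classes or actions).
#' @param N number of Boolean features feeding the head.
#' @param K output arity for softmax/policy heads.
#' @return object of class \code{"lpbn_head"} with zero-initialized weights.
#' @export
new_head <- function(kind = c("logistic", "linear", "softmax", "policy"),
                     N, K = 2L) {
  kind <- match.arg(kind)
  if (kind %in% c("logistic", "linear")) {
    structure(list(kind = kind, w = numeric(N), b = 0), class = "lpbn_head")
  } else {
    structure(list(kind = kind, W = matrix(0, K, N), b = numeric(K)),
              class = "lpbn_head")
  }
}

#' Evaluate an output head on Boolean features
#'
#' @param head an \code{"lpbn_head"}.
#' @param h 0/1 feature vector of length N, or an n x N matrix.
#' @return logistic: probability in (0,1); linear: real; softmax/policy:
#'   probability vector (rows for matrix input).
#' @export
head_forward <- function(head, h) {
  if (is.matrix(h)) {
    if (head$kind %in% c("logistic", "linear")) {
      s <- drop(h %*% head$w) + head$b
      return(if (head$kind == "logistic") stats::plogis(s) else s)
    }
    S <- h %*% t(head$W) + rep(head$b, each = nrow(h))
    return(.softmax_rows(S))
  }
  if (head$kind %in% c("logistic", "linear")) {
    s <- sum(head$w * h) + head$b
    if (head$kind == "logistic") stats::plogis(s) else s
  } else {
    selector_probs(drop(head$W %*% h) + head$b)
  }
}

#' Count trainable parameters of an LPBN
#'
#' Selector logits contribute \code{N * (2m + |O|)}; the head contributes
#' \code{N + 1} (scalar heads) or \code{K * (N + 1)} (vector heads).
#'
#' @param N units; @param m substrate width; @param n_ops operator count.
#' @param head an \code{"lpbn_head"}, or NULL for selector logits only.
#' @return integer parameter count.
#' @export
param_count <- function(N, m, n_ops = 4L, head = NULL) {
  p <- N * (2L * m + n_ops)
  if (!is.null(head)) {
    p <- p + if (!is.null(head$w)) length(head$w) + 1L
             else length(head$W) + length(head$b)
  }
  p
}

#' Match a one-hidden-layer MLP width to an LPBN parameter count
#'
#' Finds the hidden width H whose tanh-MLP parameter count
#' \code{(d_in + 1) * H + (H + 1) * d_out} is closest to the LPBN count,
#' requiring agreement within 10 percent (the capacity-matching rule used
#' for every paired comparison).
#'
#' @param lpbn_params target parameter count.
#' @param d_in,d_out MLP input/output dimensions.
#' @return integer width H.
#' @export
match_mlp_width <- function(lpbn_params, d_in, d_out) {
  per_h <- d_in + 1 + d_out
  H_star <- (lpbn_params - d_out) / per_h
  cand <- unique(pmax(1L, c(floor(H_star), ceiling(H_star))))
  counts <- (d_in + 1) * cand + (cand + 1) * d_out
  rel <- abs(counts - lpbn_params) / lpbn_params
  ok <- rel <= 0.10
  if (!any(ok)) stop("no hidden width matches the parameter count within 10%")
  as.integer(cand[ok][which.min(rel[ok])])
}

#' MLP parameter count for a given width
#' @param H hidden width; @param d_in,d_out input/output dimensions.
#' @return integer count.
#' @export
mlp_param_count <- function(H, d_in, d_out) (d_in + 1) * H + (H + 1) * d_out

#' Compile an exact pattern indicator into a NAND circuit
#'
#' Builds a multi-layer circuit of two-input NAND gates whose output is 1
#' exactly when the input equals \code{pattern}: literals are taken directly
#' (bit = 1) or negated via \code{NAND(x, x)} (bit = 0), then folded into a
#' conjunction with the two-gate identity \code{AND(u, v) =
#' NAND(NAND(u, v), NAND(u, v))}. This is the constructive step behind the
#' functional-completeness and exact-interpolation guarantees; trained
#' models remain single-layer.
#'
#' @param pattern 0/1 vector of length d.
#' @return object of class \code{"lpbn_circuit"}: \code{d}, a gate matrix
#'   (columns a, b; references 1..d are inputs, d+1.. are gate outputs) and
#'   \code{out}, the reference of the output signal.
#' @export
compile_indicator <- function(pattern) {
  d <- length(pattern)
  stopifnot(d >= 1L, all(pattern %in% c(0L, 1L)))
  gates <- matrix(integer(0), ncol = 2L)
  add_gate <- function(a, b) {
    gates <<- rbind(gates, c(a, b))
    d + nrow(gates)
  }
  lits <- integer(d)
  for (j in seq_len(d)) {
    lits[j] <- if (pattern[j] == 1L) j else add_gate(j, j)  # NAND(x,x) = NOT x
  }
  conj <- function(refs) {
    if (length(refs) == 1L) return(refs)
    t <- add_gate(refs[1L], refs[2L])
    refs <- c(add_gate(t, t), refs[-(1:2)])
    conj(refs)
  }
  out <- conj(lits)
  structure(list(d = d, gates = gates, out = out), class = "lpbn_circuit")
}

#' Evaluate a NAND circuit
#'
#' @param circuit an \code{"lpbn_circuit"}.
#' @param z 0/1 input vector of length \code{circuit$d}.
#' @return 0/1 output bit.
#' @export
eval_circuit <- function(circuit, z) {
  vals <- c(as.integer(z), integer(nrow(circuit$gates)))
  for (g in seq_len(nrow(circuit$gates))) {
    a <- vals[circuit$gates[g, 1L]]
    b <- vals[circuit$gates[g, 2L]]
    vals[circuit$d + g] <- 1L - (a & b)
  }
  vals[circuit$out]
}
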