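#' Score-function (REINFORCE) gradient for selector logits
#'
#' For feedback F (a quantity to be *increased*: negative loss for
#' supervised tasks, return for RL) and baseline b, the per-logit ascent
#' gradient of E[F] is \code{(F - b) * (1{chosen = i} - pi(i))} for each of
#' the three categorical slots of every unit. Subtracting any baseline
#' independent of the sample leaves the estimator unbiased (the score has
#' zero mean) while reducing variance.
#'
#' @param policy an \code{"lpbn_policy"}.
#' @param s the \code{"lpbn_structure"} that was sampled from \code{policy}.
#' @param F scalar feedback for that sample.
#' @param baseline scalar baseline b.
#' @return object of class \code{"lpbn_grad"}: matrices \code{a}, \code{b}
#'   (N x m) and \code{o} (N x |O|) aligned with the policy logits, plus
#'   the advantage used.
#' @export
score_function_grad <- function(policy, s, F, baseline = 0) {
  if (!is.finite(F)) stop("non-finite feedback F")
  adv <- F - baseline
  pa <- .softmax_rows(policy$a_logits)
  pb <- .softmax_rows(policy$b_logits)
  po <- .softmax_rows(policy$o_logits)
  N <- policy$N
  ia <- cbind(seq_len(N), s$A); ib <- cbind(seq_len(N), s$B)
  io <- cbind(seq_len(N), s$O)
  ga <- -pa; ga[ia] <- ga[ia] + 1
  gb <- -pb; gb[ib] <- gb[ib] + 1
  go <- -po; go[io] <- go[io] + 1
  structure(list(a = adv * ga, b = adv * gb, o = adv * go, advantage = adv),
            class = "lpbn_grad")
}

#' Exponential-moving-average baseline
#'
#' Online approximation of the variance-minimizing constant baseline:
#' \code{b <- decay * b + (1 - decay) * F}. The first observation
#' initializes b to F, avoiding a transient from an arbitrary zero start.
#'
#' @param state list with \code{b} (may be NA before the first update) and
#'   \code{decay} in [0.9, 0.99]; create with [new_baseline()].
#' @param F observed scalar feedback.
#' @return updated state.
#' @export
ema_update <- function(state, F) {
  if (!is.finite(F)) stop("non-finite feedback F")
  state$b <- if (is.na(state$b)) F else state$decay * state$b +
    (1 - state$decay) * F
  state
}

#' @rdname ema_update
#' @param decay EMA decay in [0.9, 0.99] (default 0.95).
#' @export
new_baseline <- function(decay = 0.95) {
  stopifnot(decay >= 0.9, decay <= 0.99)
  list(b = NA_real_, decay = decay)
}

#' Variance-minimizing constant baseline
#'
#' The constant b* minimizing the second moment of the score-function
#' estimator weights feedback by the squared score norm:
#' \code{b* = sum(F * normsq) / sum(normsq)}.
#'
#' @param F_samples scalar feedback samples.
#' @param score_norms_sq matching squared L2 norms of the score vectors.
#' @return scalar b*.
#' @export
optimal_constant_baseline <- function(F_samples, score_norms_sq) {
  stopifnot(length(F_samples) == length(score_norms_sq),
            length(F_samples) > 0L)
  tot <- sum(score_norms_sq)
  if (tot <= 0) stop("all score norms are zero; baseline undefined")
  sum(F_samples * score_norms_sq) / tot
}

#' Shannon entropy of a categorical distribution
#'
#' Natural-log entropy with the convention 0 * log 0 = 0.
#'
#' @param probs probability vector.
#' @return scalar >= 0.
#' @export
categorical_entropy <- function(probs) {
  p <- probs[probs > 0]
  -sum(p * log(p))
}

#' Gradient of softmax entropy with respect to the logits
#'
#' Exact derivative of \code{H(softmax(logits))}:
#' \code{dH/dl_i = -p_i * (log p_i + H)}. Zero at the uniform distribution;
#' elsewhere it points back toward uniform, which is what the annealed
#' entropy bonus uses to delay selector collapse.
#'
#' @param logits finite numeric vector.
#' @return gradient vector of the same length.
#' @export
entropy_grad <- function(logits) {
  p <- selector_probs(logits)
  lp <- ifelse(p > 0, log(p), 0)
  H <- -sum(p * lp)
  -p * (lp + H)
}

# row-wise entropy gradient of a logit matrix, shape-preserving even for
# single-column matrices (where apply() would drop dimensions)
.entropy_grad_rows <- function(L) {
  out <- t(apply(L, 1L, entropy_grad))
  if (ncol(L) == 1L) out <- matrix(out, ncol = 1L)
  out
}

#' Linear entropy-weight annealing
#'
#' \code{lambda(t) = lambda0 * max(0, 1 - 2 t / total_steps)}: linear decay
#' to zero over the first half of the budget, zero afterwards.
#'
#' @param lambda0 initial entropy weight.
#' @param t current step (0-based).
#' @param total_steps training budget.
#' @return scalar weight at step t.
#' @export
anneal_entropy <- function(lambda0, t, total_steps) {
  lambda0 * max(0, 1 - 2 * t / total_steps)
}

#' Draw standard Gumbel noise
#' @param n number of variates.
#' @return numeric vector.
#' @export
rgumbel <- function(n) -log(-log(stats::runif(n)))

#' Gumbel-Softmax (Concrete) relaxed categorical sample
#'
#' \code{softmax((logits + noise) / tau)} with standard Gumbel noise. As
#' \code{tau -> 0} the relaxation approaches the one-hot sample at
#' \code{argmax(logits + noise)}, which is distributed Categorical(softmax
#' (logits)) by the Gumbel-Max property. Supplying the same noise to the
#' hard and relaxed paths gives the common-random-numbers coupling used by
#' relaxed surrogate training.
#'
#' @param logits numeric logit vector.
#' @param tau temperature > 0.
#' @param noise standard-Gumbel vector (defaults to a fresh draw).
#' @return list with \code{relaxed} (probability vector) and \code{hard}
#'   (index of argmax(logits + noise)).
#' @export
gumbel_softmax_sample <- function(logits, tau, noise = rgumbel(length(logits))) {
  if (tau <= 0) stop("tau must be positive")
  pert <- logits + noise
  list(relaxed = selector_probs(pert / tau), hard = which.max(pert))
}

#' Rao-Blackwellized score-function gradient for one selector slot
#'
#' Replaces the raw feedback with its conditional expectation given this
#' slot's choice, \code{F_tilde[k] = E[F | choice = k]}, which preserves
#' the expected gradient while provably lowering variance (law of total
#' variance). The conditional table is computed by exact enumeration on
#' small problems.
#'
#' @param logits logit vector of the slot.
#' @param chosen sampled index for the slot.
#' @param conditional_F numeric vector, \code{E[F | choice = k]} for every k.
#' @param baseline scalar baseline.
#' @return per-logit gradient vector.
#' @export
rao_blackwell_grad <- function(logits, chosen, conditional_F, baseline = 0) {
  if (length(conditional_F) != length(logits))
    stop("conditional table must have one entry per choice")
  p <- selector_probs(logits)
  g <- -p
  g[chosen] <- g[chosen] + 1
  (conditional_F[chosen] - baseline) * g
}

#' Straight-through gradient rule
#'
#' Forward passes use hard thresholding; the backward pass substitutes the
#' identity on the pre-threshold value, with the passed-through gradient
#' clipped to [-1, 1] to limit the bias when the surrogate saturates.
#'
#' @param hard_output the 0/1 forward value (unused by the rule; kept for
#'   the calling convention).
#' @param soft_surrogate the pre-threshold value in (0, 1).
#' @param upstream_grad gradient arriving from above.
#' @return clipped pass-through gradient.
#' @export
straight_through_grad <- function(hard_output, soft_surrogate, upstream_grad) {
  if (soft_surrogate <= 0 || soft_surrogate >= 1)
    stop("soft surrogate must lie strictly in (0, 1)")
  pmin(1, pmax(-1, upstream_grad))
}

#' Clip advantages elementwise
#' @param a numeric vector; @param range clipping interval (default [-5, 5]).
#' @return clipped vector.
#' @export
clip_advantage <- function(a, range = c(-5, 5)) pmin(range[2], pmax(range[1], a))

#' Rescale a gradient vector to an L2-norm cap
#' @param g numeric vector; @param cap positive norm bound (default 5).
#' @return g unchanged if within the cap, otherwise rescaled to norm cap.
#' @export
clip_gradient_norm <- function(g, cap = 5) {
  stopifnot(cap > 0)
  nrm <- sqrt(sum(g^2))
  if (nrm > cap) g * (cap / nrm) else g
}
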