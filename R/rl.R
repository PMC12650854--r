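#' LineWorld environment
#'
#' A 1-D chain of length 9 with terminal states at both ends: reward +1 on
#' entering the right terminal, -1 on the left, 0 otherwise; episodes start
#' at the center and are capped at a horizon of 40 steps. States are
#' one-hot positions.
#'
#' @return list with \code{L}, \code{horizon}, \code{n_actions},
#'   \code{reset()} and \code{encode(position)} (one-hot substrate).
#' @export
lineworld_env <- function() {
  L <- 9L
  list(L = L, horizon = 40L, n_actions = 2L,
       reset = function() (L + 1L) %/% 2L,
       encode = function(pos) { z <- integer(L); z[pos] <- 1L; z },
       m = L)
}

#' One LineWorld transition
#'
#' @param position current position in 1..9 (non-terminal).
#' @param action 1 = left, 2 = right.
#' @return list with \code{position}, \code{reward}, \code{done}.
#' @export
lineworld_step <- function(position, action) {
  L <- 9L
  if (position <= 1L || position >= L) stop("episode already terminated")
  pos2 <- position + if (action == 2L) 1L else -1L
  reward <- if (pos2 == L) 1 else if (pos2 == 1L) -1 else 0
  list(position = pos2, reward = reward, done = pos2 == 1L || pos2 == L)
}

#' Cart-pole environment (canonical constants)
#'
#' The classical inverted pendulum with state (x, xdot, theta, thetadot),
#' binary force actions, explicit-Euler integration with a 0.02 s step,
#' gravity 9.8, cart mass 1.0, pole mass 0.1, pole half-length 0.5, force
#' 10 N, and termination thresholds of 2.4 m on position and 12 degrees on
#' angle; reward +1 per surviving step, horizon 280. Discretization ranges
#' for the substrate: x in [-2.4, 2.4], xdot in [-3, 3], theta in
#' [-12 deg, 12 deg], thetadot in [-3.5, 3.5], 8 bins each.
#'
#' @return list with physics constants, \code{horizon}, \code{n_actions},
#'   \code{ranges}, \code{B}, \code{reset()} (uniform in [-0.05, 0.05]^4)
#'   and \code{encode(state)}.
#' @export
cartpole_env <- function() {
  th_lim <- 12 * pi / 180
  ranges <- rbind(c(-2.4, 2.4), c(-3, 3), c(-th_lim, th_lim), c(-3.5, 3.5))
  B <- 8L
  list(horizon = 280L, n_actions = 2L, ranges = ranges, B = B,
       reset = function() stats::runif(4L, -0.05, 0.05),
       encode = function(state) discretize_rl_state(state, ranges, B),
       m = 4L * B)
}

#' One cart-pole transition
#'
#' @param state numeric (x, xdot, theta, thetadot).
#' @param action 1 = push left, 2 = push right.
#' @return list with \code{state}, \code{reward} (+1), \code{done}
#'   (threshold violation; the horizon cap is handled by the episode loop).
#' @export
cartpole_step <- function(state, action) {
  g <- 9.8; mc <- 1.0; mp <- 0.1; mt <- mc + mp
  l <- 0.5; pml <- mp * l; force_mag <- 10; tau <- 0.02
  x <- state[1L]; xd <- state[2L]; th <- state[3L]; thd <- state[4L]
  force <- if (action == 2L) force_mag else -force_mag
  costh <- cos(th); sinth <- sin(th)
  temp <- (force + pml * thd^2 * sinth) / mt
  thacc <- (g * sinth - costh * temp) / (l * (4 / 3 - mp * costh^2 / mt))
  xacc <- temp - pml * thacc * costh / mt
  s2 <- c(x + tau * xd, xd + tau * xacc, th + tau * thd, thd + tau * thacc)
  done <- abs(s2[1L]) > 2.4 || abs(s2[3L]) > 12 * pi / 180
  list(state = s2, reward = 1, done = done)
}

#' Discounted returns and clipped advantages for a trajectory
#'
#' Computes returns by the backward recursion \code{G_t = r_t + gamma
#' G_(t+1)} and advantages \code{A_t = G_t - b_t} clipped to [-5, 5].
#'
#' @param rewards per-step reward vector.
#' @param discount gamma in (0, 1].
#' @param baseline scalar or per-step baseline values b_t.
#' @return list with \code{returns} and \code{advantages}.
#' @export
returns_and_advantages <- function(rewards, discount = 1, baseline = 0) {
  T_ <- length(rewards)
  G <- numeric(T_)
  acc <- 0
  for (t in rev(seq_len(T_))) {
    acc <- rewards[t] + discount * acc
    G[t] <- acc
  }
  list(returns = G, advantages = clip_advantage(G - baseline))
}

#' Trailing moving average
#'
#' Mean over the last \code{window} values, with truncated windows at the
#' head of the series (the first element is its own average).
#'
#' @param values numeric series.
#' @param window window length (default 100).
#' @return series of the same length.
#' @export
moving_average <- function(values, window = 100L) {
  stopifnot(length(values) >= 1L)
  cs <- cumsum(values)
  n <- length(values)
  idx <- seq_len(n)
  lo <- pmax(idx - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (idx - lo)
}

# run one episode with a per-step action-probability function;
# returns substrate rows, actions, rewards
.play_episode <- function(env, kind, act_probs) {
  if (kind == "lineworld") {
    pos <- env$reset()
    Zs <- list(); acts <- integer(0); rews <- numeric(0)
    for (t in seq_len(env$horizon)) {
      z <- env$encode(pos)
      pr <- act_probs(z)
      a <- sample.int(2L, 1L, prob = pr)
      st <- lineworld_step(pos, a)
      Zs[[t]] <- z; acts[t] <- a; rews[t] <- st$reward
      pos <- st$position
      if (st$done) break
    }
  } else {
    s <- env$reset()
    Zs <- list(); acts <- integer(0); rews <- numeric(0)
    for (t in seq_len(env$horizon)) {
      z <- env$encode(s)
      pr <- act_probs(z)
      a <- sample.int(2L, 1L, prob = pr)
      st <- cartpole_step(s, a)
      Zs[[t]] <- z; acts[t] <- a; rews[t] <- st$reward
      s <- st$state
      if (st$done) break
    }
  }
  list(Z = do.call(rbind, Zs), actions = acts, rewards = rews)
}

#' Run one episode with a trained policy
#'
#' @param model result of [train_policy()].
#' @param env_name "lineworld" or "cartpole".
#' @param structure "map" (deterministic structure) or "sample".
#' @return list with \code{Z} (visited substrate rows), \code{actions},
#'   \code{rewards} and the episode \code{return}.
#' @export
run_episode <- function(model, env_name = c("lineworld", "cartpole"),
                        structure = c("map", "sample")) {
  env_name <- match.arg(env_name)
  structure <- match.arg(structure)
  env <- if (env_name == "lineworld") lineworld_env() else cartpole_env()
  if (model$kind == "lpbn") {
    s <- if (structure == "map") map_structure(model$policy)
         else sample_structure(model$policy)
    act_probs <- function(z) {
      h <- lpbn_forward(s, z, model$operators)
      selector_probs(drop(model$V %*% h) + model$b_head)
    }
  } else {
    act_probs <- function(z) {
      a1 <- tanh(drop(model$W1 %*% z) + model$b1)
      selector_probs(drop(model$W2 %*% a1) + model$b2)
    }
  }
  tr <- .play_episode(env, env_name, act_probs)
  tr$return <- sum(tr$rewards)
  tr
}

#' Episodic policy-gradient training of LPBN and MLP policies
#'
#' LPBN policies sample a structure once per episode; the softmax policy
#' head over the Boolean features is updated by REINFORCE with per-step
#' clipped advantages, and selector logits by the score-function estimator
#' with the episode return against an EMA baseline, plus annealed entropy.
#' A linear critic on the features supplies the per-step baseline when
#' \code{critic = TRUE} (default for cart-pole). MLP policies (one hidden
#' tanh layer) are updated by the same per-step REINFORCE rule. All
#' gradients are L2-clipped to norm 5 and advantages to [-5, 5].
#'
#' Defaults follow the study protocol: LineWorld 500 episodes, selector
#' lr 7e-2, head lr 1.8e-1, undiscounted, entropy weight 5e-3 annealed to
#' zero at half budget, MLP lr 2e-2; cart-pole 300 episodes, selector lr
#' 1e-2, head lr 2e-2, gamma 0.99.
#'
#' @param env_name "lineworld" or "cartpole".
#' @param policy "lpbn" or "mlp".
#' @param episodes episode budget (default: 500 LineWorld, 300 cart-pole).
#' @param N LPBN unit count (default: parameter-matched choices, 8 for
#'   LineWorld and 64 for cart-pole).
#' @param H MLP hidden width (default 16 for LineWorld, 40-40 two-layer
#'   for cart-pole is out of scope here; single hidden layer is used).
#' @param lr_logits,lr_head,lr_mlp,lambda0,gamma,ema_decay overrides.
#' @param critic use a linear critic baseline on features (default TRUE
#'   for cart-pole, FALSE for LineWorld).
#' @param resample "episode" (default) or "step" structure resampling.
#' @param init "identity" starts every unit as a pass-through reader of one
#'   substrate bit (unit n reads bit n mod m through the unary AND(z, z)
#'   trick, selector logits concentrated with offset \code{init_offset}),
#'   the Boolean analogue of identity-initialized residual blocks: the
#'   policy head sees a stable tabular view of the state from episode one
#'   while structure learning recomposes units. "uniform" starts all
#'   selector logits at zero. Defaults: identity for cart-pole, uniform
#'   for LineWorld.
#' @param init_offset logit concentration of the identity initialization.
#' @return list with the trained policy (\code{kind} "lpbn" or "mlp"),
#'   per-episode \code{returns}, and \code{moving_avg} (window 100).
#' @export
train_policy <- function(env_name = c("lineworld", "cartpole"),
                         policy = c("lpbn", "mlp"),
                         episodes = NULL, N = NULL, H = NULL,
                         lr_logits = NULL, lr_head = NULL, lr_mlp = NULL,
                         lambda0 = 5e-3, gamma = NULL, ema_decay = 0.95,
                         critic = NULL,
                         resample = c("episode", "step"),
                         init = NULL, init_offset = 8) {
  env_name <- match.arg(env_name)
  policy <- match.arg(policy)
  resample <- match.arg(resample)
  lw <- env_name == "lineworld"
  env <- if (lw) lineworld_env() else cartpole_env()
  if (is.null(episodes)) episodes <- if (lw) 500L else 300L
  if (is.null(N)) N <- if (lw) 8L else 64L
  if (is.null(H)) H <- if (lw) 16L else 26L
  if (is.null(lr_logits)) lr_logits <- if (lw) 7e-2 else 1e-2
  if (is.null(lr_head)) lr_head <- if (lw) 1.8e-1 else 2e-2
  if (is.null(lr_mlp)) lr_mlp <- if (lw) 2e-2 else 5e-3
  if (is.null(gamma)) gamma <- if (lw) 1 else 0.99
  if (is.null(critic)) critic <- !lw
  if (is.null(init)) init <- if (lw) "uniform" else "identity"
  m <- env$m
  returns <- numeric(episodes)
  if (policy == "lpbn") {
    pol <- new_selector_policy(N, m)
    if (init == "identity") {
      bit <- ((seq_len(N) - 1L) %% m) + 1L
      pol$a_logits[cbind(seq_len(N), bit)] <- init_offset
      pol$b_logits[cbind(seq_len(N), bit)] <- init_offset
      pol$o_logits[, match("AND", lpbn_operators())] <- init_offset
    }
    V <- matrix(0, 2L, N); b_head <- numeric(2L)
    cw <- numeric(N); cb <- 0            # linear critic on features
    base <- new_baseline(ema_decay)
    for (ep in seq_len(episodes)) {
      s <- sample_structure(pol)
      act_probs <- if (resample == "episode") {
        function(z) {
          h <- lpbn_forward(s, z)
          selector_probs(drop(V %*% h) + b_head)
        }
      } else {
        function(z) {
          s <<- sample_structure(pol)
          h <- lpbn_forward(s, z)
          selector_probs(drop(V %*% h) + b_head)
        }
      }
      tr <- .play_episode(env, env_name, act_probs)
      T_ <- length(tr$rewards)
      Hm <- lpbn_forward(s, tr$Z)
      G <- returns_and_advantages(tr$rewards, gamma)$returns
      bvals <- if (critic) drop(Hm %*% cw) + cb else
        if (is.na(base$b)) 0 else base$b
      adv <- clip_advantage(G - bvals)
      # policy head: per-step REINFORCE on action log-probs
      Pact <- .softmax_rows(Hm %*% t(V) + rep(b_head, each = T_))
      Ind <- matrix(0, T_, 2L); Ind[cbind(seq_len(T_), tr$actions)] <- 1
      dlog <- Ind - Pact
      gV <- t(dlog * adv) %*% Hm
      gb <- colSums(dlog * adv)
      gh <- clip_gradient_norm(c(gV, gb))
      gV <- matrix(gh[seq_along(gV)], 2L, N)
      gb <- gh[length(gV) + 1:2]
      V <- V + lr_head * gV
      b_head <- b_head + lr_head * gb
      if (critic) {
        # normalized LMS (a few passes per episode): step scaled by the
        # mean squared feature norm so the value fit stays stable however
        # dense the Boolean features are
        scale <- mean(rowSums(Hm * Hm)) + 1
        for (pass in 1:3) {
          ce <- G - (drop(Hm %*% cw) + cb)
          cw <- cw + 0.3 * drop(ce %*% Hm) / (T_ * scale)
          cb <- cb + 0.3 * mean(ce) / scale
        }
      }
      # selector update: episode return vs EMA baseline
      F_ <- sum(tr$rewards)
      sel_base <- if (is.na(base$b)) F_ else base$b
      sadv <- clip_advantage(F_ - sel_base)
      g <- score_function_grad(pol, s, F_, F_ - sadv)
      lam <- anneal_entropy(lambda0, ep - 1L, episodes)
      flat <- c(g$a, g$b, g$o)
      flat <- clip_gradient_norm(flat)
      na_ <- length(g$a)
      ga <- matrix(flat[seq_len(na_)], N, m)
      gb2 <- matrix(flat[na_ + seq_len(na_)], N, m)
      go <- matrix(flat[2L * na_ + seq_len(length(g$o))], N,
                   length(lpbn_operators()))
      if (lam > 0) {
        ga <- ga + lam * .entropy_grad_rows(pol$a_logits)
        gb2 <- gb2 + lam * .entropy_grad_rows(pol$b_logits)
        go <- go + lam * .entropy_grad_rows(pol$o_logits)
      }
      pol$a_logits <- pol$a_logits + lr_logits * ga
      pol$b_logits <- pol$b_logits + lr_logits * gb2
      pol$o_logits <- pol$o_logits + lr_logits * go
      base <- ema_update(base, F_)
      returns[ep] <- F_
    }
    model <- list(kind = "lpbn", policy = pol, V = V, b_head = b_head,
                  operators = lpbn_operators(), env = env_name)
  } else {
    W1 <- matrix(stats::rnorm(H * m, 0, 1 / sqrt(m)), H, m)
    b1 <- numeric(H)
    W2 <- matrix(0, 2L, H); b2 <- numeric(2L)
    base <- new_baseline(ema_decay)
    cw <- numeric(H); cb <- 0
    for (ep in seq_len(episodes)) {
      act_probs <- function(z) {
        a1 <- tanh(drop(W1 %*% z) + b1)
        selector_probs(drop(W2 %*% a1) + b2)
      }
      tr <- .play_episode(env, env_name, act_probs)
      T_ <- length(tr$rewards)
      A1 <- tanh(tr$Z %*% t(W1) + rep(b1, each = T_))
      G <- returns_and_advantages(tr$rewards, gamma)$returns
      bvals <- if (critic) drop(A1 %*% cw) + cb else
        if (is.na(base$b)) 0 else base$b
      adv <- clip_advantage(G - bvals)
      Pact <- .softmax_rows(A1 %*% t(W2) + rep(b2, each = T_))
      Ind <- matrix(0, T_, 2L); Ind[cbind(seq_len(T_), tr$actions)] <- 1
      dS2 <- (Ind - Pact) * adv
      dA1 <- dS2 %*% W2 * (1 - A1^2)
      gall <- c(t(dS2) %*% A1, colSums(dS2), t(dA1) %*% tr$Z, colSums(dA1))
      gall <- clip_gradient_norm(gall)
      i <- 0L
      take <- function(k) { v <- gall[i + seq_len(k)]; i <<- i + k; v }
      W2 <- W2 + lr_mlp * matrix(take(2L * H), 2L, H)
      b2 <- b2 + lr_mlp * take(2L)
      W1 <- W1 + lr_mlp * matrix(take(H * m), H, m)
      b1 <- b1 + lr_mlp * take(H)
      if (critic) {
        scale <- mean(rowSums(A1 * A1)) + 1
        for (pass in 1:3) {
          ce <- G - (drop(A1 %*% cw) + cb)
          cw <- cw + 0.3 * drop(ce %*% A1) / (T_ * scale)
          cb <- cb + 0.3 * mean(ce) / scale
        }
      }
      base <- ema_update(base, sum(tr$rewards))
      returns[ep] <- sum(tr$rewards)
    }
    model <- list(kind = "mlp", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                  env = env_name)
  }
  list(model = model, returns = returns,
       moving_avg = moving_average(returns, 100L))
}
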