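#' Training configuration for supervised LPBNs
#'
#' Defaults follow the study protocol: 50 epochs, batch 64, selector
#' learning rate 7e-2, head learning rate 3e-1 (midpoint of the printed
#' interval), entropy weight 1e-3 annealed to zero over the first half of
#' training, EMA decay 0.95, B = 5 bins, REINFORCE estimator.
#'
#' @param epochs,batch_size training budget (early stopping is never used).
#' @param N Boolean unit count.
#' @param B bins per feature.
#' @param lr_logits,lr_head learning rates.
#' @param lambda0 initial entropy weight.
#' @param ema_decay EMA baseline decay in [0.9, 0.99].
#' @param operators operator label vector.
#' @param const_bits append CONST0/CONST1 to the substrate.
#' @param use_baseline disable to run raw REINFORCE (ablation); the
#'   estimator stays unbiased but noisier.
#' @param init selector initialization: \code{"identity"} (default)
#'   concentrates unit n's input selectors on substrate bit n mod m with
#'   the AND operator, so every unit starts as a stable pass-through
#'   reader of one bit while structure learning recomposes pairs;
#'   \code{"uniform"} starts all logits at zero, under which per-example
#'   structure resampling scrambles the head's feature identities and
#'   learning must bootstrap from symmetry breaking.
#' @param init_offset logit concentration of the identity initialization.
#' @return named list of settings.
#' @export
lpbn_train_config <- function(epochs = 50L, batch_size = 64L, N = 16L,
                              B = 5L, lr_logits = 7e-2, lr_head = 3e-1,
                              lambda0 = 1e-3, ema_decay = 0.95,
                              operators = lpbn_operators(),
                              const_bits = FALSE, use_baseline = TRUE,
                              init = c("identity", "uniform"),
                              init_offset = 8) {
  stopifnot(epochs >= 1L, batch_size >= 1L, N >= 0L, B >= 2L)
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       N = as.integer(N), B = as.integer(B), lr_logits = lr_logits,
       lr_head = lr_head, lambda0 = lambda0, ema_decay = ema_decay,
       operators = operators, const_bits = const_bits,
       use_baseline = isTRUE(use_baseline), init = match.arg(init),
       init_offset = init_offset)
}

# Shared LPBN trainer on a fixed 0/1 substrate matrix Z.
# head_kind: "logistic" (y in [0,1], cross-entropy), "linear" (real y,
# squared error), "decoder" (y a matrix, mean squared reconstruction).
# Per-example structure samples; per-example advantages (F - EMA baseline);
# selector gradients averaged over the batch with an annealed entropy bonus.
# With sample_by_weight the rows are drawn per batch from the weight
# distribution (with replacement) and treated uniformly, so an "epoch"
# is one pass over sum(weights) implied raw observations; used when the
# data are aggregated unique rows with visitation counts.
.train_lpbn_core <- function(Z, y, head_kind, config, weights = NULL,
                             sample_by_weight = FALSE) {
  m <- ncol(Z)
  n_obs <- nrow(Z)
  N <- config$N
  operators <- config$operators
  k_ops <- length(operators)
  if (is.null(weights)) weights <- rep(1, n_obs)
  policy <- if (N > 0L) new_selector_policy(N, m, operators) else NULL
  if (N > 0L && identical(config$init, "identity")) {
    bit <- ((seq_len(N) - 1L) %% m) + 1L
    policy$a_logits[cbind(seq_len(N), bit)] <- config$init_offset
    policy$b_logits[cbind(seq_len(N), bit)] <- config$init_offset
    and_k <- match("AND", operators)
    if (!is.na(and_k)) policy$o_logits[, and_k] <- config$init_offset
  }
  head <- if (head_kind == "decoder") {
    d_out <- ncol(y)
    list(kind = "decoder", W = matrix(0, d_out, max(N, 1L)),
         b = colMeans(y))
  } else new_head(head_kind, max(N, 1L))
  if (head_kind == "linear" || head_kind == "logistic") {
    # bias starts at the target base rate / mean for a sane zero-unit model
    head$b <- if (head_kind == "logistic")
      stats::qlogis(min(max(stats::weighted.mean(y, weights), 1e-3), 1 - 1e-3))
    else stats::weighted.mean(y, weights)
  }
  base <- new_baseline(config$ema_decay)
  n_batches <- if (sample_by_weight)
    max(1L, ceiling(sum(weights) / config$batch_size))
  else max(1L, ceiling(n_obs / config$batch_size))
  total_steps <- config$epochs * n_batches
  hist <- list(loss = numeric(config$epochs),
               entropy = numeric(config$epochs),
               baseline = numeric(config$epochs))
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_obs)
    ep_loss <- 0; ep_w <- 0
    if (N > 0L) {
      pa <- .softmax_rows(policy$a_logits)
      pb <- .softmax_rows(policy$b_logits)
      po <- .softmax_rows(policy$o_logits)
    }
    for (bt in seq_len(n_batches)) {
      if (sample_by_weight) {
        rows <- sample.int(n_obs, config$batch_size, replace = TRUE,
                           prob = weights)
        nb <- length(rows)
        wb <- rep(1 / nb, nb)
      } else {
        rows <- ord[seq.int((bt - 1L) * config$batch_size + 1L,
                            min(bt * config$batch_size, n_obs))]
        nb <- length(rows)
        wb <- weights[rows]; wb <- wb / sum(wb)
      }
      if (N > 0L) {
        A <- B_ <- O <- matrix(0L, nb, N)
        for (nn in seq_len(N)) {
          A[, nn] <- sample.int(m, nb, replace = TRUE, prob = pa[nn, ])
          B_[, nn] <- sample.int(m, nb, replace = TRUE, prob = pb[nn, ])
          O[, nn] <- sample.int(k_ops, nb, replace = TRUE, prob = po[nn, ])
        }
        ridx <- rep(rows, N)
        Za <- matrix(Z[cbind(ridx, as.vector(A))], nb, N)
        Zb <- matrix(Z[cbind(ridx, as.vector(B_))], nb, N)
        H <- matrix(0L, nb, N)
        for (k in seq_len(k_ops)) {
          sel <- O == k
          if (any(sel)) H[sel] <- apply_operator(operators[k], Za[sel], Zb[sel])
        }
      } else H <- matrix(0L, nb, 1L)
      if (head_kind == "logistic") {
        p <- stats::plogis(drop(H %*% head$w) + head$b)
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        yb <- y[rows]
        loss <- -(yb * log(p) + (1 - yb) * log(1 - p))
        resid <- p - yb                      # d loss / d score
      } else if (head_kind == "linear") {
        p <- drop(H %*% head$w) + head$b
        yb <- y[rows]
        loss <- (p - yb)^2
        resid <- 2 * (p - yb)
      } else {                               # decoder reconstruction
        P <- H %*% t(head$W) + rep(head$b, each = nb)
        E <- P - y[rows, , drop = FALSE]
        loss <- rowMeans(E^2)
        resid <- 2 * E / ncol(E)
      }
      F_ <- -loss
      base <- ema_update(base, sum(wb * F_))
      if (N > 0L) {
        b_use <- if (isTRUE(config$use_baseline) ||
                     is.null(config$use_baseline)) base$b else 0
        adv <- (F_ - b_use) * wb
        lam <- anneal_entropy(config$lambda0, step, total_steps)
        for (slot in 1:3) {
          Smat <- list(A, B_, O)[[slot]]
          probs <- list(pa, pb, po)[[slot]]
          width <- if (slot == 3L) k_ops else m
          acc <- matrix(0, N, width)
          for (nn in seq_len(N)) {
            sums <- rowsum(adv, Smat[, nn])
            acc[nn, as.integer(rownames(sums))] <- sums
          }
          grad <- acc - sum(adv) * probs
          logit_name <- c("a_logits", "b_logits", "o_logits")[slot]
          if (lam > 0)
            grad <- grad + lam * .entropy_grad_rows(policy[[logit_name]])
          policy[[logit_name]] <- policy[[logit_name]] +
            config$lr_logits * grad
        }
      }
      if (head_kind == "decoder") {
        gw <- t(resid * wb) %*% H
        head$W <- head$W - config$lr_head * gw
        head$b <- head$b - config$lr_head * colSums(resid * wb)
      } else {
        rw <- resid * wb
        head$w <- head$w - config$lr_head * drop(rw %*% H)
        head$b <- head$b - config$lr_head * sum(rw)
      }
      ep_loss <- ep_loss + sum(wb * loss) * nb
      ep_w <- ep_w + nb
      step <- step + 1L
      if (N > 0L && bt == n_batches) {
        pa <- .softmax_rows(policy$a_logits)
        pb <- .softmax_rows(policy$b_logits)
        po <- .softmax_rows(policy$o_logits)
      }
    }
    hist$loss[ep] <- ep_loss / ep_w
    hist$entropy[ep] <- if (N > 0L)
      mean(c(apply(pa, 1L, categorical_entropy),
             apply(pb, 1L, categorical_entropy),
             apply(po, 1L, categorical_entropy))) else 0
    hist$baseline[ep] <- base$b
  }
  list(policy = policy, head = head, operators = operators, history = hist)
}

.new_lpbn_model <- function(scheme, fit, task) {
  structure(list(scheme = scheme, policy = fit$policy, head = fit$head,
                 operators = fit$operators, task = task,
                 history = fit$history),
            class = "lpbn_model")
}

#' @export
print.lpbn_model <- function(x, ...) {
  N <- if (is.null(x$policy)) 0L else x$policy$N
  cat(sprintf("lpbn_model (%s): N=%d units on m=%d bits, head '%s'\n",
              x$task, N, if (is.null(x$scheme)) x$policy$m else x$scheme$m,
              x$head$kind))
  invisible(x)
}

#' Train an LPBN binary classifier
#'
#' Binarizes the features with a scheme fitted on the training rows only,
#' then trains a logistic-head LPBN: head weights by gradient descent on
#' cross-entropy, selector logits by REINFORCE with the negative loss as
#' feedback, an EMA baseline, and annealed entropy.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels.
#' @param config see [lpbn_train_config()].
#' @param train_idx rows used for fitting (default: all rows).
#' @return an \code{"lpbn_model"} with the training history attached.
#' @export
train_classifier <- function(x, y, config = lpbn_train_config(),
                             train_idx = seq_len(nrow(x))) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y[train_idx])) < 2L)
    stop("training split contains a single class")
  scheme <- fit_binarizer(x[train_idx, , drop = FALSE], B = config$B,
                          const_bits = config$const_bits)
  Z <- binarize(scheme, x[train_idx, , drop = FALSE])
  fit <- .train_lpbn_core(Z, y[train_idx], "logistic", config)
  .new_lpbn_model(scheme, fit, "classifier")
}

#' Train an LPBN on an already-Boolean substrate
#'
#' Variant of [train_classifier()] for inputs that are already bit
#' vectors (text bag-of-words, one-hot states): no binarizer is fitted.
#'
#' @param Z 0/1 substrate matrix.
#' @param y 0/1 labels (or [0,1] target probabilities).
#' @param config see [lpbn_train_config()].
#' @return an \code{"lpbn_model"} (with \code{scheme = NULL}).
#' @export
train_classifier_bits <- function(Z, y, config = lpbn_train_config()) {
  fit <- .train_lpbn_core(as.matrix(Z), y, "logistic", config)
  .new_lpbn_model(NULL, fit, "classifier")
}

#' Train an LPBN regressor
#'
#' Linear head trained on squared error; selector feedback is the negative
#' per-example squared error. Report RMSE (or -RMSE as a score).
#'
#' @inheritParams train_classifier
#' @param y real targets.
#' @return an \code{"lpbn_model"}.
#' @export
train_regressor <- function(x, y, config = lpbn_train_config(),
                            train_idx = seq_len(nrow(x))) {
  x <- as.matrix(x)
  scheme <- fit_binarizer(x[train_idx, , drop = FALSE], B = config$B,
                          const_bits = config$const_bits)
  Z <- binarize(scheme, x[train_idx, , drop = FALSE])
  fit <- .train_lpbn_core(Z, y[train_idx], "linear", config)
  .new_lpbn_model(scheme, fit, "regressor")
}

#' Train an LPBN feature extractor by reconstruction
#'
#' The Boolean features feed a shallow linear decoder trained to
#' reconstruct the standardized inputs (the identical decoder is used for
#' the MLP baseline to avoid bias). Embeddings are the MAP-structure unit
#' outputs at the end of the fixed budget; no model selection.
#'
#' @inheritParams train_classifier
#' @return an \code{"lpbn_model"} whose head is the linear decoder; use
#'   [embed_features()] for embeddings.
#' @export
train_embedding <- function(x, config = lpbn_train_config(),
                            train_idx = seq_len(nrow(x))) {
  x <- as.matrix(x)
  scheme <- fit_binarizer(x[train_idx, , drop = FALSE], B = config$B,
                          const_bits = config$const_bits)
  Z <- binarize(scheme, x[train_idx, , drop = FALSE])
  xs <- sweep(sweep(x[train_idx, , drop = FALSE], 2L, scheme$means, "-"),
              2L, scheme$sds, "/")
  fit <- .train_lpbn_core(Z, xs, "decoder", config)
  .new_lpbn_model(scheme, fit, "embedding")
}

#' Boolean embeddings from a trained model
#'
#' @param model an \code{"lpbn_model"}.
#' @param x feature matrix (binarized through the model's scheme), or a
#'   substrate matrix when the model has no scheme.
#' @return n x N 0/1 matrix of MAP-structure unit outputs.
#' @export
embed_features <- function(model, x) {
  Z <- if (is.null(model$scheme)) as.matrix(x) else binarize(model$scheme, x)
  lpbn_forward(map_structure(model$policy), Z, model$operators)
}

#' Predict from a trained LPBN
#'
#' Evaluation uses the deterministic MAP structure by default; set
#' \code{structure = "sample"} to draw a fresh structure instead.
#'
#' @param object an \code{"lpbn_model"}.
#' @param newdata feature matrix (or substrate matrix when the model was
#'   trained directly on bits).
#' @param type "response" (probability / real value) or "class".
#' @param structure "map" or "sample".
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.lpbn_model <- function(object, newdata,
                               type = c("response", "class"),
                               structure = c("map", "sample"), ...) {
  type <- match.arg(type)
  structure <- match.arg(structure)
  Z <- if (is.null(object$scheme)) as.matrix(newdata)
       else binarize(object$scheme, as.matrix(newdata))
  if (is.null(object$policy)) {
    H <- matrix(0L, nrow(Z), 1L)
  } else {
    s <- if (structure == "map") map_structure(object$policy)
         else sample_structure(object$policy)
    H <- lpbn_forward(s, Z, object$operators)
  }
  if (object$head$kind == "decoder") {
    return(H %*% t(object$head$W) + rep(object$head$b, each = nrow(H)))
  }
  out <- head_forward(object$head, H)
  if (type == "class") as.integer(out >= 0.5) else out
}

#' Train the parameter-matched tanh MLP baseline
#'
#' A one-hidden-layer tanh network trained by minibatch SGD on the task
#' loss, with the hidden width chosen by [match_mlp_width()] so its
#' parameter count matches the paired LPBN within 10 percent.
#'
#' @param x feature matrix; @param y labels/targets (ignored for
#'   \code{task = "embedding"}, which reconstructs standardized x).
#' @param task "classifier", "regressor" or "embedding".
#' @param H hidden width.
#' @param epochs,batch_size training budget (same as the paired LPBN).
#' @param lr SGD learning rate (default 0.05).
#' @param train_idx rows used for fitting.
#' @return object of class \code{"lpbn_mlp"}.
#' @export
train_mlp <- function(x, y = NULL,
                      task = c("classifier", "regressor", "embedding"),
                      H, epochs = 50L, batch_size = 64L, lr = 0.05,
                      train_idx = seq_len(nrow(x))) {
  task <- match.arg(task)
  stopifnot(H >= 1L)
  x <- as.matrix(x)
  mu <- colMeans(x[train_idx, , drop = FALSE])
  sd_ <- apply(x[train_idx, , drop = FALSE], 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sd_, "/")
  d_in <- ncol(x)
  d_out <- switch(task, classifier = 1L, regressor = 1L, embedding = d_in)
  tgt <- switch(task, classifier = as.numeric(y), regressor = as.numeric(y),
                embedding = xs)
  W1 <- matrix(stats::rnorm(H * d_in, 0, 1 / sqrt(d_in)), H, d_in)
  b1 <- numeric(H)
  W2 <- matrix(stats::rnorm(d_out * H, 0, 1 / sqrt(H)), d_out, H)
  b2 <- numeric(d_out)
  n_tr <- length(train_idx)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0
    for (start in seq(1L, n_tr, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, n_tr)]
      nb <- length(rows)
      Xb <- xs[rows, , drop = FALSE]
      A1 <- tanh(Xb %*% t(W1) + rep(b1, each = nb))
      S2 <- A1 %*% t(W2) + rep(b2, each = nb)
      if (task == "classifier") {
        p <- stats::plogis(drop(S2))
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        yb <- tgt[rows]
        ep_loss <- ep_loss - sum(yb * log(p) + (1 - yb) * log(1 - p))
        dS2 <- matrix((p - yb) / nb, ncol = 1L)
      } else if (task == "regressor") {
        yb <- tgt[rows]
        e <- drop(S2) - yb
        ep_loss <- ep_loss + sum(e^2)
        dS2 <- matrix(2 * e / nb, ncol = 1L)
      } else {
        E <- S2 - tgt[rows, , drop = FALSE]
        ep_loss <- ep_loss + sum(rowMeans(E^2))
        dS2 <- 2 * E / (ncol(E) * nb)
      }
      dA1 <- dS2 %*% W2 * (1 - A1^2)
      W2 <- W2 - lr * (t(dS2) %*% A1)
      b2 <- b2 - lr * colSums(dS2)
      W1 <- W1 - lr * (t(dA1) %*% Xb)
      b1 <- b1 - lr * colSums(dA1)
    }
    hist[ep] <- ep_loss / n_tr
  }
  structure(list(task = task, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 center = mu, scale = sd_, history = hist),
            class = "lpbn_mlp")
}

#' @export
predict.lpbn_mlp <- function(object, newdata,
                             type = c("response", "class", "hidden"), ...) {
  type <- match.arg(type)
  xs <- sweep(sweep(as.matrix(newdata), 2L, object$center, "-"), 2L,
              object$scale, "/")
  A1 <- tanh(xs %*% t(object$W1) + rep(object$b1, each = nrow(xs)))
  if (type == "hidden") return(A1)
  S2 <- A1 %*% t(object$W2) + rep(object$b2, each = nrow(xs))
  out <- if (object$task == "classifier") stats::plogis(drop(S2))
         else if (object$task == "regressor") drop(S2) else S2
  if (type == "class") as.integer(out >= 0.5) else out
}

#' Serialize a trained LPBN to JSON
#'
#' Writes the selector logits, head weights, operator labels, and the
#' binarization scheme (when present) so a run manifest can reproduce the
#' model exactly.
#'
#' @param model an \code{"lpbn_model"}.
#' @param path optional file; if missing the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "lpbn_model"))
  obj <- list(task = model$task, operators = model$operators,
              policy = if (!is.null(model$policy))
                list(N = model$policy$N, m = model$policy$m,
                     a_logits = model$policy$a_logits,
                     b_logits = model$policy$b_logits,
                     o_logits = model$policy$o_logits),
              head = model$head[setdiff(names(model$head), "kind")],
              head_kind = model$head$kind,
              scheme = if (!is.null(model$scheme)) unclass(model$scheme))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Bag-of-words featurization for the sentiment task
#'
#' Binary token-presence features over the closed vocabulary, with
#' CONST0/CONST1 bits appended so units can express unary functions.
#'
#' @param sentences list of token vectors.
#' @param vocabulary character vector (default [text_vocabulary()]).
#' @return n x (|V| + 2) 0/1 matrix.
#' @export
text_featurize <- function(sentences, vocabulary = text_vocabulary()) {
  bad <- setdiff(unique(unlist(sentences)), vocabulary)
  if (length(bad)) stop("out-of-vocabulary token(s): ",
                        paste(bad, collapse = ", "))
  Z <- t(vapply(sentences, function(s)
    as.integer(vocabulary %in% s), integer(length(vocabulary))))
  cbind(Z, 0L, 1L)
}
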