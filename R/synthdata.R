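# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators are pure functions of their seeds
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Deterministic 70/10/20 train/validation/test split
#'
#' Sizes are floor(0.7 n), floor(0.1 n) and the remainder; indices are
#' shuffled under the given seed, and the three sets are disjoint and
#' exhaustive.
#'
#' @param n number of rows.
#' @param seed shuffle seed.
#' @return list with integer vectors \code{train}, \code{val}, \code{test}.
#' @export
split_indices <- function(n, seed = 1L) {
  perm <- .with_seed(seed, sample.int(n))
  n_tr <- floor(0.7 * n)
  n_va <- floor(0.1 * n)
  list(train = perm[seq_len(n_tr)],
       val = perm[n_tr + seq_len(n_va)],
       test = perm[(n_tr + n_va + 1L):n])
}

# the shared weight vector of the linear-score generators; fixed by its own
# seed so "the same synthetic task" is reproducible across studies
.task_weights <- function(d, w_seed) .with_seed(w_seed, stats::rnorm(d))

#' Linear-score binary classification generator
#'
#' Covariates are i.i.d. standard normal in R^d; labels are
#' \code{y = ind(w.x + eps >= 0)} with \code{eps ~ N(0, sigma^2)} and a
#' weight vector drawn once from its own seed. Labels are balanced in
#' expectation by symmetry.
#'
#' @param n sample count.
#' @param d feature dimension (default 8).
#' @param sigma label-noise standard deviation (default 0.1).
#' @param data_seed seed for covariates and noise.
#' @param w_seed seed for the task weight vector.
#' @return list with \code{x} (n x d), \code{y} (0/1), \code{w},
#'   \code{split} (70/10/20 indices).
#' @export
gen_classification <- function(n, d = 8L, sigma = 0.1, data_seed = 1L,
                               w_seed = 20061L) {
  w <- .task_weights(d, w_seed)
  dat <- .with_seed(data_seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    s <- drop(x %*% w) + stats::rnorm(n, 0, sigma)
    list(x = x, y = as.integer(s >= 0))
  })
  c(dat, list(w = w, split = split_indices(n, data_seed)))
}

#' Linear-Gaussian regression generator
#'
#' Same covariates as the classification task with real targets
#' \code{t = w.x + eps}, \code{eps ~ N(0, sigma^2)}; the oracle linear
#' regressor has RMSE approximately sigma.
#'
#' @inheritParams gen_classification
#' @return list with \code{x}, \code{y} (numeric targets), \code{w},
#'   \code{split}.
#' @export
gen_regression <- function(n, d = 8L, sigma = 0.1, data_seed = 1L,
                           w_seed = 20061L) {
  w <- .task_weights(d, w_seed)
  dat <- .with_seed(data_seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    list(x = x, y = drop(x %*% w) + stats::rnorm(n, 0, sigma))
  })
  c(dat, list(w = w, split = split_indices(n, data_seed)))
}

#' Three isotropic Gaussian blobs with 120-degree-separated means
#'
#' K = 3 clusters in R^4 whose means lie in a coordinate plane at pairwise
#' angles of 120 degrees (pairwise cosine exactly -1/2), scaled to norm
#' \code{sep}, with isotropic unit-variance noise. True labels are
#' returned for external evaluation (ARI) but are meant to be hidden from
#' training.
#'
#' @param n sample count (split as evenly as possible across clusters).
#' @param sep norm of each cluster mean (default 3).
#' @param data_seed seed.
#' @return list with \code{x} (n x 4), \code{labels} (1..3), \code{means},
#'   \code{split}.
#' @export
gen_blobs <- function(n, sep = 3, data_seed = 1L) {
  means <- sep * rbind(c(1, 0, 0, 0),
                       c(-0.5, sqrt(3) / 2, 0, 0),
                       c(-0.5, -sqrt(3) / 2, 0, 0))
  dat <- .with_seed(data_seed, {
    labels <- sample(rep_len(1:3, n))
    x <- means[labels, ] + matrix(stats::rnorm(n * 4), n, 4)
    list(x = x, labels = labels)
  })
  c(dat, list(means = means, split = split_indices(n, data_seed)))
}

#' The closed vocabulary of the synthetic sentiment task
#'
#' @return character vector: template words, "not", intensifiers, then 8
#'   positive and 8 negative polarity words.
#' @export
text_vocabulary <- function() {
  c("the", "product", "is", "not",
    "very", "really", "quite", "extremely",
    "good", "great", "excellent", "fine", "superb", "solid", "nice",
    "wonderful",
    "bad", "poor", "terrible", "awful", "weak", "flawed", "horrible",
    "disappointing")
}

#' Templated negation-sentiment sentence generator
#'
#' Sentences follow the template "the product is [not] [intensifier]
#' word": the optional "not" (probability 1/2) and an optional
#' label-neutral intensifier (probability 1/2) precede a polarity word
#' drawn uniformly from 8 positive and 8 negative words. The sentiment
#' label is the polarity XOR the presence of "not", so any model blind to
#' the interaction between "not" and the polarity word cannot beat chance.
#'
#' @param n sentence count.
#' @param data_seed seed.
#' @return list with \code{sentences} (list of token vectors), \code{y}
#'   (1 = positive), \code{vocabulary}, \code{split}.
#' @export
gen_text <- function(n, data_seed = 1L) {
  vocab <- text_vocabulary()
  pos <- vocab[9:16]; neg <- vocab[17:24]; intens <- vocab[5:8]
  dat <- .with_seed(data_seed, {
    has_not <- stats::runif(n) < 0.5
    has_int <- stats::runif(n) < 0.5
    is_pos <- stats::runif(n) < 0.5
    word <- ifelse(is_pos, sample(pos, n, replace = TRUE),
                   sample(neg, n, replace = TRUE))
    chosen_int <- sample(intens, n, replace = TRUE)
    sentences <- lapply(seq_len(n), function(i) {
      c("the", "product", "is",
        if (has_not[i]) "not",
        if (has_int[i]) chosen_int[i],
        word[i])
    })
    # sentiment = polarity XOR negation
    list(sentences = sentences, y = as.integer(xor(is_pos, has_not)))
  })
  list(sentences = dat$sentences, y = dat$y, vocabulary = vocab,
       split = split_indices(n, data_seed))
}
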