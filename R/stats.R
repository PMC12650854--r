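#' Evaluation metrics
#'
#' Standard task metrics under one dispatcher. \code{accuracy} compares
#' hard labels; \code{auroc} is the rank (Mann-Whitney) statistic of
#' scores for the positive class; \code{rmse} is root-mean-squared error;
#' \code{ari} is the chance-corrected Rand index between two partitions;
#' \code{silhouette} and \code{calinski_harabasz} are internal cluster
#' quality indices of a labelled embedding.
#'
#' @param name one of "accuracy", "auroc", "rmse", "ari", "silhouette",
#'   "calinski_harabasz".
#' @param predictions predicted labels, scores, values, or cluster
#'   assignments (metric-dependent); for silhouette/calinski_harabasz,
#'   the embedding matrix.
#' @param truth true labels/values; for silhouette/calinski_harabasz, the
#'   cluster assignment.
#' @return scalar metric value.
#' @export
evaluate_metric <- function(name, predictions, truth) {
  switch(name,
    accuracy = mean(as.integer(predictions) == as.integer(truth)),
    auroc = {
      y <- as.integer(truth)
      if (length(unique(y)) < 2L) stop("AUROC undefined for single-class truth")
      r <- rank(predictions)
      n1 <- sum(y == 1L); n0 <- sum(y == 0L)
      (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    },
    rmse = sqrt(mean((predictions - truth)^2)),
    ari = adjusted_rand_index(predictions, truth),
    silhouette = silhouette_score(predictions, truth),
    calinski_harabasz = calinski_harabasz_score(predictions, truth),
    stop("unknown metric: ", name))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster label vectors of equal length.
#' @return scalar; 1 for identical partitions, about 0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(0)
  (sum_ij - expected) / (mx - expected)
}

#' Mean silhouette width of a clustering
#'
#' @param x embedding matrix (rows = points).
#' @param labels cluster assignment.
#' @return mean over points of (b - a) / max(a, b).
#' @export
silhouette_score <- function(x, labels) {
  D <- as.matrix(stats::dist(x))
  n <- nrow(D)
  labs <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) sum(D[i, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(labs[labs != labels[i]],
                    function(l) mean(D[i, labels == l]), numeric(1L)))
    s[i] <- if (sum(own) > 1L) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Calinski-Harabasz index of a clustering
#'
#' @param x embedding matrix; @param labels cluster assignment.
#' @return between-to-within dispersion ratio scaled by degrees of freedom.
#' @export
calinski_harabasz_score <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); k <- length(unique(labels))
  gm <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (l in unique(labels)) {
    xi <- x[labels == l, , drop = FALSE]
    cm <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((cm - gm)^2)
    ssw <- ssw + sum(sweep(xi, 2L, cm)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Percentile (or bias-corrected) bootstrap CI for a mean
#'
#' Resamples the paired differences with replacement and returns the
#' percentile interval of the resampled mean; \code{method = "bc"} applies
#' the bias-corrected adjustment to the percentiles.
#'
#' @param deltas numeric vector.
#' @param resamples bootstrap resample count (default 10000).
#' @param conf confidence level (default 0.95).
#' @param method "percentile" or "bc".
#' @return length-2 vector (lo, hi).
#' @export
bootstrap_ci <- function(deltas, resamples = 10000L, conf = 0.95,
                         method = c("percentile", "bc")) {
  method <- match.arg(method)
  n <- length(deltas)
  stopifnot(n >= 1L)
  means <- vapply(seq_len(resamples),
                  function(i) mean(deltas[sample.int(n, n, replace = TRUE)]),
                  numeric(1L))
  alpha <- (1 - conf) / 2
  if (method == "percentile") {
    q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 6)
  } else {
    prop <- mean(means < mean(deltas))
    prop <- min(max(prop, 1 / resamples), 1 - 1 / resamples)
    z0 <- stats::qnorm(prop)
    lo_p <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
    hi_p <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
    q <- stats::quantile(means, c(lo_p, hi_p), names = FALSE, type = 6)
  }
  q
}

#' Exact two-sided sign test on paired differences
#'
#' Zero differences are dropped as ties; with n+ positive and n- negative
#' signs the p-value is \code{min(1, 2 P(X >= max(n+, n-)))} with
#' X ~ Binomial(n+ + n-, 1/2). All ties gives p = 1.
#'
#' @param deltas numeric vector of paired differences.
#' @return list with \code{p}, \code{n_plus}, \code{n_minus}.
#' @export
sign_test <- function(deltas) {
  stopifnot(length(deltas) >= 1L)
  n_plus <- sum(deltas > 0)
  n_minus <- sum(deltas < 0)
  n <- n_plus + n_minus
  p <- if (n == 0L) 1 else
    min(1, 2 * stats::pbinom(max(n_plus, n_minus) - 1L, n, 0.5,
                             lower.tail = FALSE))
  list(p = p, n_plus = n_plus, n_minus = n_minus)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvalues numeric vector in (0, 1].
#' @return adjusted p-values (monotone, capped at 1).
#' @export
holm_adjust <- function(pvalues) stats::p.adjust(pvalues, method = "holm")

#' Two one-sided tests (TOST) for equivalence
#'
#' Tests whether the mean paired difference is statistically confined
#' within (-epsilon, +epsilon): one-sided t-tests of the mean against each
#' margin, declaring equivalence only when both reject at \code{alpha}.
#' With zero variance the verdict reduces to exact containment of the
#' common value. When a bootstrap CI is supplied (recommended for very
#' small n, where the t tests degenerate) the verdict additionally
#' requires the CI to lie inside the margin.
#'
#' @param deltas paired differences (n >= 2).
#' @param epsilon positive equivalence margin.
#' @param alpha test level (default 0.05).
#' @param ci optional length-2 bootstrap CI of the mean.
#' @return list with \code{equivalent} ("Yes"/"No"), \code{p_lower},
#'   \code{p_upper}.
#' @export
tost_equivalence <- function(deltas, epsilon, alpha = 0.05, ci = NULL) {
  stopifnot(length(deltas) >= 2L, epsilon > 0)
  m <- mean(deltas)
  s <- stats::sd(deltas)
  n <- length(deltas)
  if (s == 0) {
    inside <- abs(m) < epsilon
    p_lower <- p_upper <- if (inside) 0 else 1
  } else {
    se <- s / sqrt(n)
    p_lower <- stats::pt((m + epsilon) / se, n - 1L, lower.tail = FALSE)
    p_upper <- stats::pt((m - epsilon) / se, n - 1L)
    inside <- p_lower < alpha && p_upper < alpha
  }
  if (!is.null(ci)) inside <- inside && ci[1L] > -epsilon && ci[2L] < epsilon
  list(equivalent = if (inside) "Yes" else "No",
       p_lower = p_lower, p_upper = p_upper)
}

#' Cliff's delta effect size
#'
#' \code{(#\{a_i > b_j\} - #\{a_i < b_j\}) / (|a| |b|)}, in [-1, 1].
#'
#' @param a,b numeric samples.
#' @return scalar dominance statistic.
#' @export
cliffs_delta <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  d <- outer(a, b, "-")
  (sum(d > 0) - sum(d < 0)) / (length(a) * length(b))
}

#' Paired model comparison across tasks
#'
#' Builds the headline comparison table: per task, the mean seed-paired
#' difference \code{ann - lpbn} on a higher-is-better scale (score
#' regression as -RMSE upstream), a bootstrap 95 percent CI, the exact
#' sign-test p with Holm adjustment across tasks, Cliff's delta, and an
#' optional TOST equivalence verdict. A winner is declared when the
#' bootstrap CI of the mean difference excludes zero (the model favored
#' by its sign); otherwise the row reads "No clear winner".
#'
#' @param results data frame with columns \code{task}, \code{seed},
#'   \code{lpbn}, \code{ann} (one row per task x seed; seed sets must be
#'   identical within a task).
#' @param margins optional named numeric vector of TOST margins per task.
#' @param resamples bootstrap resamples (default 10000).
#' @param alpha significance level for the winner verdict.
#' @return data frame of class \code{"paired_result"}, one row per task.
#' @export
compare_models <- function(results, margins = NULL, resamples = 10000L,
                           alpha = 0.05) {
  stopifnot(all(c("task", "seed", "lpbn", "ann") %in% names(results)))
  tasks <- unique(results$task)
  rows <- lapply(tasks, function(tk) {
    sub <- results[results$task == tk, ]
    if (anyDuplicated(sub$seed)) stop("duplicated seeds within task ", tk)
    deltas <- sub$ann - sub$lpbn
    st <- sign_test(deltas)
    ci <- bootstrap_ci(deltas, resamples = resamples)
    eq <- NA_character_
    if (!is.null(margins) && tk %in% names(margins)) {
      eq <- tost_equivalence(deltas, margins[[tk]], ci = ci)$equivalent
    }
    data.frame(task = tk, n_seeds = nrow(sub), mean_delta = mean(deltas),
               ci_lo = ci[1L], ci_hi = ci[2L], sign_p = st$p,
               n_plus = st$n_plus, n_minus = st$n_minus,
               cliffs_delta = cliffs_delta(sub$ann, sub$lpbn),
               equivalent = eq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sign_p_holm <- holm_adjust(out$sign_p)
  excl0 <- out$ci_lo > 0 | out$ci_hi < 0
  out$winner <- ifelse(!excl0, "No clear winner",
                       ifelse(out$mean_delta > 0, "ANN", "LPBN"))
  class(out) <- c("paired_result", class(out))
  out
}

#' @export
print.paired_result <- function(x, ...) {
  cat("Paired comparison (delta = ANN - LPBN, higher-is-better scores)\n")
  df <- as.data.frame(x)
  df$mean_delta <- sprintf("%.3f", df$mean_delta)
  df$ci <- sprintf("[%.3f, %.3f]", x$ci_lo, x$ci_hi)
  df$sign_p <- sprintf("%.3f", x$sign_p)
  df$`n+/n-` <- sprintf("%d/%d", x$n_plus, x$n_minus)
  print(df[, c("task", "mean_delta", "ci", "sign_p", "n+/n-", "winner")],
        row.names = FALSE)
  invisible(x)
}
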