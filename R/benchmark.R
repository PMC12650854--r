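#' Run the paired LPBN-versus-MLP benchmark
#'
#' For every requested task and every seed, trains an LPBN and a
#' parameter-matched one-hidden-layer tanh MLP on identical data splits
#' with identical budgets, evaluates the task metric once at the end of
#' training, and assembles the paired comparison table (mean difference,
#' bootstrap CI, exact sign test with Holm correction, Cliff's delta,
#' winner verdict). Regression is scored as -RMSE so higher is better for
#' every task. The parameter-count gap is asserted to be at most 10
#' percent before any training runs.
#'
#' @param tasks subset of "classification", "regression", "clustering",
#'   "lineworld", "text".
#' @param seeds integer seed vector shared by both models (paired).
#' @param n sample count for the tabular generators.
#' @param config LPBN settings from [lpbn_train_config()].
#' @param episodes LineWorld episode budget.
#' @param resamples bootstrap resamples for the comparison table.
#' @return list with \code{table} (a \code{"paired_result"}),
#'   \code{scores} (long per-seed data frame), and \code{manifest}.
#' @export
run_benchmark <- function(tasks = c("classification", "regression",
                                    "clustering", "lineworld", "text"),
                          seeds = 1:3, n = 2000L,
                          config = lpbn_train_config(),
                          episodes = 500L, resamples = 10000L) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  rows <- list()
  for (task in tasks) {
    for (seed in seeds) {
      sc <- .bench_one(task, seed, n, config, episodes)
      rows[[length(rows) + 1L]] <- data.frame(task = task, seed = seed,
                                              lpbn = sc["lpbn"],
                                              ann = sc["ann"])
    }
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  tab <- compare_models(scores, resamples = resamples)
  manifest <- list(tasks = tasks, seeds = seeds, n = n, episodes = episodes,
                   config = config[setdiff(names(config), "operators")],
                   operators = config$operators,
                   software = as.character(utils::packageVersion("lpbn")))
  list(table = tab, scores = scores, manifest = manifest)
}

# one paired (LPBN, ANN) score for a task and seed; higher is better
.bench_one <- function(task, seed, n, config, episodes) {
  if (task == "lineworld") {
    set.seed(seed)
    lp <- train_policy("lineworld", "lpbn", episodes = episodes)
    set.seed(seed)
    mp <- train_policy("lineworld", "mlp", episodes = episodes)
    k <- min(100L, episodes)
    return(c(lpbn = mean(utils::tail(lp$returns, k)),
             ann = mean(utils::tail(mp$returns, k))))
  }
  if (task == "classification") {
    dat <- gen_classification(n, data_seed = seed)
    d_in <- ncol(dat$x)
    lpbn_p <- param_count(config$N, d_in * config$B, length(config$operators),
                          new_head("logistic", config$N))
    H <- match_mlp_width(lpbn_p, d_in, 1L)
    .assert_matched(lpbn_p, mlp_param_count(H, d_in, 1L))
    set.seed(seed)
    ml <- train_classifier(dat$x, dat$y, config, train_idx = dat$split$train)
    set.seed(seed)
    ma <- train_mlp(dat$x, dat$y, "classifier", H, epochs = config$epochs,
                    batch_size = config$batch_size,
                    train_idx = dat$split$train)
    te <- dat$split$test
    return(c(lpbn = evaluate_metric("accuracy",
                                    predict(ml, dat$x[te, ], type = "class"),
                                    dat$y[te]),
             ann = evaluate_metric("accuracy",
                                   predict(ma, dat$x[te, ], type = "class"),
                                   dat$y[te])))
  }
  if (task == "regression") {
    dat <- gen_regression(n, data_seed = seed)
    d_in <- ncol(dat$x)
    lpbn_p <- param_count(config$N, d_in * config$B, length(config$operators),
                          new_head("linear", config$N))
    H <- match_mlp_width(lpbn_p, d_in, 1L)
    .assert_matched(lpbn_p, mlp_param_count(H, d_in, 1L))
    set.seed(seed)
    ml <- train_regressor(dat$x, dat$y, config, train_idx = dat$split$train)
    set.seed(seed)
    ma <- train_mlp(dat$x, dat$y, "regressor", H, epochs = config$epochs,
                    batch_size = config$batch_size,
                    train_idx = dat$split$train)
    te <- dat$split$test
    return(c(lpbn = -evaluate_metric("rmse", predict(ml, dat$x[te, ]),
                                     dat$y[te]),
             ann = -evaluate_metric("rmse", predict(ma, dat$x[te, ]),
                                    dat$y[te])))
  }
  if (task == "clustering") {
    dat <- gen_blobs(n, data_seed = seed)
    d_in <- ncol(dat$x)
    lpbn_p <- config$N * (2L * d_in * config$B + length(config$operators)) +
      d_in * (config$N + 1L)
    H <- match_mlp_width(lpbn_p, d_in, d_in)
    .assert_matched(lpbn_p, mlp_param_count(H, d_in, d_in))
    set.seed(seed)
    ml <- train_embedding(dat$x, config, train_idx = dat$split$train)
    set.seed(seed)
    ma <- train_mlp(dat$x, task = "embedding", H = H, epochs = config$epochs,
                    batch_size = config$batch_size,
                    train_idx = dat$split$train)
    te <- dat$split$test
    emb_l <- embed_features(ml, dat$x[te, ])
    emb_a <- predict(ma, dat$x[te, ], type = "hidden")
    km_l <- stats::kmeans(emb_l, centers = 3L, nstart = 10L)
    km_a <- stats::kmeans(emb_a, centers = 3L, nstart = 10L)
    return(c(lpbn = adjusted_rand_index(km_l$cluster, dat$labels[te]),
             ann = adjusted_rand_index(km_a$cluster, dat$labels[te])))
  }
  # text
  dat <- gen_text(n, data_seed = seed)
  Z <- text_featurize(dat$sentences, dat$vocabulary)
  d_in <- ncol(Z)
  lpbn_p <- param_count(config$N, d_in, length(config$operators),
                        new_head("logistic", config$N))
  H <- match_mlp_width(lpbn_p, d_in, 1L)
  .assert_matched(lpbn_p, mlp_param_count(H, d_in, 1L))
  tr <- dat$split$train; te <- dat$split$test
  set.seed(seed)
  ml <- train_classifier_bits(Z[tr, ], dat$y[tr], config)
  set.seed(seed)
  ma <- train_mlp(Z, dat$y, "classifier", H, epochs = config$epochs,
                  batch_size = config$batch_size, train_idx = tr)
  c(lpbn = evaluate_metric("accuracy", predict(ml, Z[te, ], type = "class"),
                           dat$y[te]),
    ann = evaluate_metric("accuracy", predict(ma, Z[te, ], type = "class"),
                          dat$y[te]))
}

.assert_matched <- function(p_lpbn, p_mlp) {
  gap <- abs(p_mlp - p_lpbn) / p_lpbn
  if (gap > 0.10)
    stop(sprintf("parameter gap %.1f%% exceeds the 10%% matching rule",
                 100 * gap))
  invisible(gap)
}

#' One-axis ablation grid
#'
#' Re-runs a task while varying exactly one axis — bins per feature,
#' operator set, unit count, or variance reduction (EMA baseline and
#' entropy on/off) — holding everything else fixed, and reports the
#' per-value scores across seeds.
#'
#' @param axis one of "bins", "operators", "nodes", "variance_reduction".
#' @param values list/vector of axis values: bin counts; operator label
#'   vectors (e.g. \code{list(c("AND","OR","NAND"), "NAND")}); node
#'   counts; or flags "full" / "no_baseline" / "no_entropy".
#' @param task one of "classification", "text".
#' @param seeds seed vector; @param n sample count.
#' @param config base configuration.
#' @return data frame with columns \code{axis}, \code{value}, \code{seed},
#'   \code{score}.
#' @export
run_ablation <- function(axis = c("bins", "operators", "nodes",
                                  "variance_reduction"),
                         values, task = c("classification", "text"),
                         seeds = 1:3, n = 1000L,
                         config = lpbn_train_config()) {
  axis <- match.arg(axis)
  task <- match.arg(task)
  rows <- list()
  for (vi in seq_along(values)) {
    v <- if (is.list(values)) values[[vi]] else values[vi]
    cfg <- config
    if (axis == "bins") cfg$B <- as.integer(v)
    else if (axis == "operators") cfg$operators <- as.character(v)
    else if (axis == "nodes") cfg$N <- as.integer(v)
    else {
      if (identical(v, "no_baseline")) cfg$use_baseline <- FALSE
      if (identical(v, "no_entropy")) cfg$lambda0 <- 0
    }
    for (seed in seeds) {
      set.seed(seed)
      if (task == "classification") {
        dat <- gen_classification(n, data_seed = seed)
        ml <- train_classifier(dat$x, dat$y, cfg,
                               train_idx = dat$split$train)
        te <- dat$split$test
        sc <- evaluate_metric("accuracy",
                              predict(ml, dat$x[te, ], type = "class"),
                              dat$y[te])
      } else {
        dat <- gen_text(n, data_seed = seed)
        Z <- text_featurize(dat$sentences, dat$vocabulary)
        ml <- train_classifier_bits(Z[dat$split$train, ],
                                    dat$y[dat$split$train], cfg)
        sc <- evaluate_metric("accuracy",
                              predict(ml, Z[dat$split$test, ],
                                      type = "class"),
                              dat$y[dat$split$test])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, value = paste(v, collapse = "+"), seed = seed,
        score = sc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a run manifest as JSON
#'
#' @param manifest named list of run settings and outputs.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
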