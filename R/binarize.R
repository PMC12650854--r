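#' One-hot binarization of real-valued features
#'
#' Fits a per-feature standardize-then-bin map turning real vectors
#' \eqn{x \in R^d} into a Boolean substrate \eqn{z \in \{0,1\}^m} with
#' \eqn{m = dB} (plus two constant bits when \code{const_bits = TRUE}).
#' Each feature is standardized to zero mean and unit variance using
#' statistics of the training split only, then cut into \code{B} equal-width
#' bins spanning the standardized training min--max; the active bin is
#' one-hot coded. Values outside the training range clamp to the boundary
#' bin, so exactly one bit per feature block is always set.
#'
#' @param x numeric matrix (n rows, d features) of training data.
#' @param B integer, number of bins per feature (must be >= 2).
#' @param const_bits logical; append a constant-zero and a constant-one bit
#'   (CONST0/CONST1), which let a two-input unit express unary functions
#'   such as identity (AND with CONST1) and NOT (XOR with CONST1).
#' @return An object of class \code{"lpbn_binarizer"} with fields
#'   \code{d}, \code{B}, \code{means}, \code{sds}, \code{edges} (list of
#'   per-feature ascending boundary vectors of length B+1),
#'   \code{const_bits}, and the substrate width \code{m}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), ncol = 2)
#' bz <- fit_binarizer(x, B = 5)
#' z <- binarize(bz, x[1, ])
#' sum(z)  # one hot bit per feature
#' @export
fit_binarizer <- function(x, B = 5L, const_bits = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  B <- as.integer(B)
  if (B < 2L) stop("B must be at least 2 (single bin is degenerate)")
  d <- ncol(x)
  means <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("zero-variance feature(s): ", paste(which(sds == 0), collapse = ", "))
  }
  xs <- sweep(sweep(x, 2L, means, "-"), 2L, sds, "/")
  edges <- lapply(seq_len(d), function(j) {
    lo <- min(xs[, j]); hi <- max(xs[, j])
    if (hi <= lo) hi <- lo + 1e-8
    seq(lo, hi, length.out = B + 1L)
  })
  m <- d * B + if (const_bits) 2L else 0L
  structure(list(d = d, B = B, means = means, sds = sds, edges = edges,
                 const_bits = const_bits, m = m),
            class = "lpbn_binarizer")
}

#' @export
print.lpbn_binarizer <- function(x, ...) {
  cat(sprintf("lpbn_binarizer: d=%d features x B=%d bins -> m=%d bits%s\n",
              x$d, x$B, x$m,
              if (x$const_bits) " (incl. CONST0/CONST1)" else ""))
  invisible(x)
}

# bin index of a standardized value within edge vector e (length B+1),
# half-open [e_k, e_{k+1}) with the last bin closed; clamps outside values
.bin_index <- function(v, e) {
  B <- length(e) - 1L
  idx <- findInterval(v, e, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), B)
}

#' Map real vectors onto the Boolean substrate
#'
#' Applies a fitted binarizer to one vector or a matrix of rows. The fitted
#' scheme is never re-estimated: output bits depend only on the scheme and
#' the input, so validation/test data use the training-split statistics.
#'
#' @param scheme a fitted \code{"lpbn_binarizer"}.
#' @param x numeric vector of length d, or an n x d matrix.
#' @return integer 0/1 vector of length \code{scheme$m}, or an n x m matrix.
#' @export
binarize <- function(scheme, x) {
  stopifnot(inherits(scheme, "lpbn_binarizer"))
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, function(r) binarize(scheme, r)))
    dimnames(out) <- NULL
    return(out)
  }
  if (length(x) != scheme$d) stop("expected length-", scheme$d, " input")
  xs <- (x - scheme$means) / scheme$sds
  z <- integer(scheme$m)
  for (j in seq_len(scheme$d)) {
    k <- .bin_index(xs[j], scheme$edges[[j]])
    z[(j - 1L) * scheme$B + k] <- 1L
  }
  if (scheme$const_bits) z[scheme$d * scheme$B + 2L] <- 1L  # CONST0 then CONST1
  z
}

#' Discretize a bounded RL state into one-hot bins
#'
#' Equal-width one-hot coding of each state variable over a fixed physical
#' interval, clamping values outside the range to the boundary bins. Used
#' for control tasks where the state has known physical ranges rather than
#' a training split to standardize on.
#'
#' @param state numeric vector of state variables.
#' @param ranges 2-column matrix (lo, hi) with one row per state variable.
#' @param B integer, bins per variable.
#' @return integer 0/1 vector of length \code{length(state) * B}.
#' @export
discretize_rl_state <- function(state, ranges, B = 8L) {
  ranges <- matrix(ranges, ncol = 2L)
  k <- length(state)
  if (nrow(ranges) != k) stop("ranges must have one row per state variable")
  if (!all(is.finite(ranges))) stop("ranges must be finite")
  B <- as.integer(B)
  z <- integer(k * B)
  for (j in seq_len(k)) {
    frac <- (state[j] - ranges[j, 1L]) / (ranges[j, 2L] - ranges[j, 1L])
    idx <- 1L + floor(frac * B)
    idx <- min(max(idx, 1L), B)
    z[(j - 1L) * B + idx] <- 1L
  }
  z
}

#' Serialize a binarizer to JSON
#'
#' @param scheme a fitted \code{"lpbn_binarizer"}.
#' @param path optional file to write to; if missing, returns the JSON string.
#' @return JSON string (invisibly when written to file).
#' @export
binarizer_to_json <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "lpbn_binarizer"))
  js <- jsonlite::toJSON(unclass(scheme), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
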