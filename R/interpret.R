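#' Extract MAP rules from a trained LPBN
#'
#' Decodes each unit's MAP structure (two antecedent bits and an
#' operator), pairs it with the unit's readout weight, and renders a
#' human-readable rule of the form
#' \code{"(x1 in bin 2) XOR (x3 in bin 4) => dlogit = 1.2"}. Substrate
#' positions are decoded through the model's binarization scheme into
#' (feature, bin) pairs, or as CONST0/CONST1 for constant bits. Rules are
#' sorted by decreasing absolute weight. For softmax heads the weight is
#' taken from the class row with the largest absolute loading on the unit.
#'
#' @param model an \code{"lpbn_model"}.
#' @return data frame with columns \code{unit}, \code{a_pos}, \code{b_pos},
#'   \code{a_label}, \code{b_label}, \code{op}, \code{weight},
#'   \code{text}; one row per unit.
#' @export
extract_rules <- function(model) {
  stopifnot(!is.null(model$policy))
  s <- map_structure(model$policy)
  N <- model$policy$N
  w <- if (!is.null(model$head$w)) model$head$w else {
    vapply(seq_len(N), function(n) {
      cls <- which.max(abs(model$head$W[, n]))
      model$head$W[cls, n]
    }, numeric(1L))
  }
  lab <- vapply(c(s$A, s$B), function(i) .bit_label(model$scheme, i), "")
  a_label <- lab[seq_len(N)]
  b_label <- lab[N + seq_len(N)]
  op <- model$operators[s$O]
  txt <- sprintf("(%s) %s (%s) => dlogit = %.4g", a_label, op, b_label, w)
  out <- data.frame(unit = seq_len(N), a_pos = s$A, b_pos = s$B,
                    a_label = a_label, b_label = b_label, op = op,
                    weight = w, text = txt, stringsAsFactors = FALSE)
  out[order(-abs(out$weight)), , drop = FALSE]
}

.bit_label <- function(scheme, i) {
  if (is.null(scheme)) return(sprintf("z%d", i))
  dB <- scheme$d * scheme$B
  if (i > dB) return(if (i == dB + 1L) "CONST0" else "CONST1")
  f <- (i - 1L) %/% scheme$B + 1L
  b <- (i - 1L) %% scheme$B + 1L
  sprintf("x%d in bin %d", f, b)
}

#' Parse a rendered rule string back into its components
#'
#' Inverse of the rendering in [extract_rules()]; useful to verify that
#' rule text round-trips.
#'
#' @param text one rule string.
#' @return list with \code{a_label}, \code{b_label}, \code{op},
#'   \code{weight}.
#' @export
parse_rule <- function(text) {
  mt <- regmatches(text,
    regexec("^\\((.+)\\) (AND|OR|XOR|NAND) \\((.+)\\) => dlogit = (.+)$",
            text))[[1L]]
  if (length(mt) != 5L) stop("unparseable rule text")
  list(a_label = mt[2L], b_label = mt[4L], op = mt[3L],
       weight = as.numeric(mt[5L]))
}

# unit output bits for one rule row over a substrate matrix
.rule_fires <- function(rule, Z, operators = lpbn_operators()) {
  apply_operator(rule$op, Z[, rule$a_pos], Z[, rule$b_pos])
}

#' Coverage of a rule on (test) data
#'
#' Fraction of rows on which the unit's antecedent fires (output bit 1).
#'
#' @param rule one row of [extract_rules()] output (data frame or list).
#' @param substrate_data 0/1 matrix transformed by the model's scheme.
#' @return fraction in [0, 1].
#' @export
rule_coverage <- function(rule, substrate_data) {
  if (nrow(as.matrix(substrate_data)) == 0L) stop("empty data")
  mean(.rule_fires(rule, as.matrix(substrate_data)))
}

#' Precision of a rule on labelled (test) data
#'
#' Among rows where the rule fires, the fraction whose binary label
#' matches the sign of the rule's weight (positive weight predicts class
#' 1).
#'
#' @param rule one row of [extract_rules()] output.
#' @param substrate_data 0/1 substrate matrix.
#' @param labels 0/1 labels.
#' @return fraction in [0, 1].
#' @export
rule_precision <- function(rule, substrate_data, labels) {
  fires <- .rule_fires(rule, as.matrix(substrate_data)) == 1L
  if (!any(fires)) stop("rule never fires; precision undefined")
  pred <- as.integer(rule$weight > 0)
  mean(as.integer(labels[fires]) == pred)
}

#' Tabulate rules with coverage and precision on test data
#'
#' @param model an \code{"lpbn_model"} with logistic head.
#' @param x_test test features (or substrate when the model has no scheme).
#' @param y_test binary test labels.
#' @return the [extract_rules()] frame plus \code{coverage} and
#'   \code{precision} columns (precision NA where a rule never fires).
#' @export
rule_table <- function(model, x_test, y_test) {
  Z <- if (is.null(model$scheme)) as.matrix(x_test)
       else binarize(model$scheme, as.matrix(x_test))
  rules <- extract_rules(model)
  rules$coverage <- vapply(seq_len(nrow(rules)), function(i)
    rule_coverage(rules[i, ], Z), numeric(1L))
  rules$precision <- vapply(seq_len(nrow(rules)), function(i) {
    if (rules$coverage[i] == 0) return(NA_real_)
    rule_precision(rules[i, ], Z, y_test)
  }, numeric(1L))
  rules
}
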