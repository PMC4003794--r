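# Fuzzy partitions, rule representation, compatibility and winner-rule
# inference. Attributes live in [0,1]; each antecedent position holds one of
# 15 symbols: "don't care" plus the 14 triangular fuzzy sets of the uniform
# partitions with granularity 2, 3, 4 and 5.

.SYMBOL_CODES <- c("0", as.character(1:9), letters[1:5])

.SYMBOL_TABLE <- data.frame(
  code        = .SYMBOL_CODES,
  int         = 0:14,
  granularity = c(NA, 2, 2, 3, 3, 3, 4, 4, 4, 4, 5, 5, 5, 5, 5),
  index       = c(NA, 1, 2, 1, 2, 3, 1, 2, 3, 4, 1, 2, 3, 4, 5),
  label       = c("DC", "S2", "L2", "S3", "M3", "L3", "S4", "MS4", "ML4",
                  "L4", "S5", "MS5", "M5", "ML5", "L5"),
  stringsAsFactors = FALSE
)

#' Fuzzy symbol alphabet
#'
#' The 15-symbol alphabet used to encode rule antecedents: code `"0"` is
#' "don't care" (DC); the remaining 14 codes name the triangular fuzzy sets
#' of the uniform partitions of \eqn{[0,1]} with granularity 2 to 5
#' (e.g. `"1"` = S2, `"4"` = M3, `"b"` = MS5).
#'
#' @return A data frame with columns `code`, `int` (0--14), `granularity`,
#'   `index` (1-based position within its partition) and `label`.
#' @export
fuzzy_symbols <- function() .SYMBOL_TABLE

# map character codes to integer symbols 0..14, with validation
symbol_int <- function(code) {
  i <- match(code, .SYMBOL_CODES)
  if (anyNA(i)) {
    stop("invalid fuzzy symbol code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "))
  }
  i - 1L
}

symbol_code <- function(int) {
  if (any(int < 0L | int > 14L)) stop("fuzzy symbol integer out of range 0..14")
  .SYMBOL_CODES[int + 1L]
}

#' Triangular membership of a fuzzy symbol
#'
#' Membership of value(s) `x` in the fuzzy set named by `symbol`. Each
#' partition of granularity K consists of K symmetric triangles with apexes
#' at (i-1)/(K-1) and support half-width 1/(K-1), so memberships within a
#' partition sum to one everywhere on \eqn{[0,1]}. The don't-care symbol has
#' membership 1 everywhere, as do missing (`NA`) values.
#'
#' @param symbol A single symbol: one-character code (see [fuzzy_symbols()])
#'   or its integer form 0--14.
#' @param x Numeric vector of values in \eqn{[0,1]}; `NA` allowed.
#' @return Numeric vector of memberships in \eqn{[0,1]}.
#' @export
membership <- function(symbol, x) {
  s <- if (is.character(symbol)) symbol_int(symbol) else as.integer(symbol)
  if (length(s) != 1L) stop("membership() takes a single symbol")
  if (is.na(s) || s < 0L || s > 14L) stop("invalid fuzzy symbol: ", symbol)
  if (s == 0L) return(rep(1, length(x)))
  K <- .SYMBOL_TABLE$granularity[s + 1L]
  i <- .SYMBOL_TABLE$index[s + 1L]
  apex <- (i - 1) / (K - 1)
  mu <- pmax(0, 1 - abs(x - apex) * (K - 1))
  mu[is.na(x)] <- 1
  mu
}

#' Construct a fuzzy if-then rule
#'
#' A rule "if x_1 is A_1 and ... and x_n is A_n then class C with certainty
#' CF". Antecedents are symbols of the 15-symbol alphabet; the certainty
#' factor weights the rule in winner-rule inference.
#'
#' @param antecedents Either a string over the symbol alphabet (one character
#'   per attribute) or an integer vector with values 0--14.
#' @param consequent Class label (length-1 character).
#' @param cf Certainty factor in \eqn{[-1, 1]}.
#' @return An object of class `fuzzy_rule`.
#' @examples
#' fuzzy_rule("0150b0", "healthy", cf = 0.8)
#' @export
fuzzy_rule <- function(antecedents, consequent, cf = NA_real_) {
  ant <- if (is.character(antecedents) && length(antecedents) == 1L) {
    symbol_int(strsplit(antecedents, "", fixed = TRUE)[[1]])
  } else {
    a <- as.integer(antecedents)
    if (any(is.na(a) | a < 0L | a > 14L)) stop("antecedent symbols must be in 0..14")
    a
  }
  structure(
    list(antecedents = ant, consequent = as.character(consequent), cf = as.numeric(cf)),
    class = "fuzzy_rule"
  )
}

#' @export
print.fuzzy_rule <- function(x, ...) {
  active <- which(x$antecedents != 0L)
  lhs <- if (length(active) == 0L) {
    "(always)"
  } else {
    paste(sprintf("x%d is %s", active,
                  .SYMBOL_TABLE$label[x$antecedents[active] + 1L]),
          collapse = " and ")
  }
  cat(sprintf("if %s then class %s  [CF = %s]  (%s)\n",
              lhs, x$consequent, format(x$cf, digits = 4), encode_rule(x)))
  invisible(x)
}

#' Encode / decode fuzzy rules as symbol strings
#'
#' `encode_rule()` renders the antecedents of a rule as a string over the
#' 15-symbol alphabet; `decode_rule()` parses such a string back into a rule
#' (round-trip identity). For example `"0150b0"` with class 0 reads "if x2 is
#' S2 and x3 is L3 and x5 is MS5 then class 0".
#'
#' @param rule A [fuzzy_rule()].
#' @param s A string over the symbol alphabet.
#' @param consequent,cf Consequent class and certainty factor for the decoded
#'   rule.
#' @return `encode_rule()`: a string; `decode_rule()`: a `fuzzy_rule`.
#' @export
encode_rule <- function(rule) {
  paste(symbol_code(rule$antecedents), collapse = "")
}

#' @rdname encode_rule
#' @export
decode_rule <- function(s, consequent = NA_character_, cf = NA_real_) {
  fuzzy_rule(s, consequent, cf)
}

# internal: membership matrix of one rule against a value matrix.
# X: m x n numeric matrix in [0,1] (NA = missing). Returns length-m vector of
# compatibilities (product over attributes, Eq-1 style).
compat_matrix <- function(antecedents, X) {
  if (length(antecedents) != ncol(X)) {
    stop("rule has ", length(antecedents), " antecedents but data has ",
         ncol(X), " attributes")
  }
  mu <- rep(1, nrow(X))
  for (j in which(antecedents != 0L)) {
    mu <- mu * membership(antecedents[j], X[, j])
  }
  mu
}

#' Compatibility of a rule with instances
#'
#' The compatibility of a fuzzy rule with an instance is the product of the
#' per-attribute memberships of the instance's values in the rule's
#' antecedent fuzzy sets. Don't-care antecedents and missing values
#' contribute a factor of 1.
#'
#' @param rule A [fuzzy_rule()].
#' @param values A numeric vector (one instance) or an m x n matrix of
#'   instances with values in \eqn{[0,1]}; `NA` marks missing.
#' @return Numeric vector of compatibilities in \eqn{[0,1]}.
#' @export
rule_compatibility <- function(rule, values) {
  X <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  compat_matrix(rule$antecedents, X)
}

#' Per-class compatibility sums
#'
#' For each class, the sum of the rule's compatibility grades over the
#' training instances of that class, normalized by the class size.
#'
#' @param rule A [fuzzy_rule()].
#' @param data A [weighted_dataset()].
#' @return A list with `beta` (named numeric, one normalized sum per class)
#'   and `counts` (named integer class sizes).
#' @export
class_compatibility <- function(rule, data) {
  stopifnot(inherits(data, "weighted_dataset"))
  if (nrow(data$X) == 0L) stop("empty dataset")
  mu <- compat_matrix(rule$antecedents, data$X)
  classes <- sort(unique(data$labels))
  counts <- vapply(classes, function(cl) sum(data$labels == cl), integer(1))
  if (any(counts == 0L)) stop("degenerate class with no instances")
  beta <- vapply(classes, function(cl) sum(mu[data$labels == cl]), numeric(1)) / counts
  names(beta) <- classes
  names(counts) <- classes
  list(beta = beta, counts = counts)
}

#' Certainty factor and consequent class from class compatibilities
#'
#' The consequent is the class with the largest normalized compatibility sum;
#' its certainty factor is the winner's share minus the average share of the
#' other classes, normalized by the total. A rule with all-zero
#' compatibilities carries no information and is rejected with an error. A
#' tie for the largest sum leaves the consequent undetermined (`NA`): in the
#' two-class case the certainty factor is then exactly 0, and such rules are
#' never admitted to a rule set (only CF > 0 rules are kept).
#'
#' @param beta Named numeric vector of per-class compatibility sums (the
#'   `beta` element of [class_compatibility()]), length >= 2.
#' @return A list with `consequent` (class name, `NA` on a tie), `cf`, and
#'   `tied` (logical).
#' @export
certainty_factor <- function(beta) {
  if (length(beta) < 2L) stop("need at least two classes")
  total <- sum(beta)
  if (total <= 0) stop("vacuous rule: zero compatibility with every class")
  w <- which.max(beta)
  tied <- sum(beta == beta[w]) > 1L
  cc <- length(beta)
  cf <- (beta[w] - (total - beta[w]) / (cc - 1)) / total
  list(consequent = if (tied) NA_character_ else names(beta)[w],
       cf = unname(cf), tied = tied)
}

#' Winner-rule classification
#'
#' Classifies instances by the single winner rule: the rule maximizing
#' compatibility times certainty factor. An instance for which no rule has a
#' positive product, or for which rules of different classes tie at the
#' maximum, is left unclassified (`NA`).
#'
#' @param rules A list of [fuzzy_rule()] objects (or a `fuzzy_ruleset`).
#' @param values Numeric vector (one instance) or m x n matrix.
#' @return Character vector of predicted classes, `NA` where unclassified.
#' @export
classify <- function(rules, values) {
  if (inherits(rules, "fuzzy_ruleset")) rules <- rules$rules
  X <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  m <- nrow(X)
  if (length(rules) == 0L) return(rep(NA_character_, m))
  cons <- vapply(rules, function(r) r$consequent, character(1))
  cf <- vapply(rules, function(r) r$cf, numeric(1))
  score <- vapply(rules, function(r) compat_matrix(r$antecedents, X), numeric(m))
  score <- matrix(score, nrow = m) * rep(cf, each = m)
  winner_class(score, cons)
}

# internal: given an m x R score matrix and per-rule classes, return the
# winner class per row; NA when the max score is <= 0 or tied across classes.
winner_class <- function(score, cons) {
  m <- nrow(score)
  classes <- unique(cons)
  cmax <- matrix(-Inf, m, length(classes))
  for (k in seq_along(classes)) {
    cols <- which(cons == classes[k])
    mx <- score[, cols[1]]
    for (j in cols[-1]) mx <- pmax(mx, score[, j])
    cmax[, k] <- mx
  }
  best <- cmax[, 1]
  if (length(classes) > 1L) {
    for (k in 2:length(classes)) best <- pmax(best, cmax[, k])
  }
  nties <- rowSums(cmax == best)
  out <- classes[max.col(cmax, ties.method = "first")]
  out[best <= 0 | nties > 1L] <- NA_character_
  out
}

#' Weighted training dataset
#'
#' Bundles a matrix of scaled attribute values, class labels and per-instance
#' boosting weights. Weights start at 1 and are only ever reduced by
#' [update_weights()].
#'
#' @param X Numeric m x n matrix with values in \eqn{[0,1]}; `NA` = missing.
#' @param labels Character (or coercible) class labels, length m.
#' @param weights Nonnegative weights, length m (default all 1).
#' @return An object of class `weighted_dataset` with elements `X`, `labels`,
#'   `weights`.
#' @export
weighted_dataset <- function(X, labels, weights = rep(1, nrow(X))) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("labels length must match rows of X")
  if (length(weights) != nrow(X)) stop("weights length must match rows of X")
  if (any(weights < 0)) stop("weights must be nonnegative")
  rng <- range(X, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
    stop("attribute values must lie in [0,1]; scale the data first")
  }
  structure(list(X = X, labels = labels, weights = as.numeric(weights)),
            class = "weighted_dataset")
}

#' @export
print.weighted_dataset <- function(x, ...) {
  cat(sprintf("weighted_dataset: %d instances, %d attributes, classes: %s, total weight %.4g\n",
              nrow(x$X), ncol(x$X),
              paste(sort(unique(x$labels)), collapse = "/"), sum(x$weights)))
  invisible(x)
}

#' Read and write rule sets as plain text
#'
#' `write_rules()` writes one rule per line as
#' `<encoded antecedents><TAB><class><TAB><cf>`; `read_rules()` parses that
#' format back. `write_rules_json()` writes a structured document with fields
#' `version`, `n_attributes`, `attribute_names` and `rules`.
#'
#' @param rules A list of [fuzzy_rule()] or a `fuzzy_ruleset`.
#' @param path File path.
#' @param attribute_names Optional attribute names for the JSON document.
#' @return `read_rules()` returns a list of `fuzzy_rule`; the writers return
#'   `path` invisibly.
#' @export
write_rules <- function(rules, path) {
  if (inherits(rules, "fuzzy_ruleset")) rules <- rules$rules
  lines <- vapply(rules, function(r) {
    sprintf("%s\t%s\t%s", encode_rule(r), r$consequent,
            formatC(r$cf, digits = 17, format = "g"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L) stop("malformed rule line: ", ln)
    fuzzy_rule(f[1], f[2], as.numeric(f[3]))
  })
}

#' @rdname write_rules
#' @export
write_rules_json <- function(rules, path, attribute_names = NULL) {
  n <- NA_integer_
  if (inherits(rules, "fuzzy_ruleset")) {
    if (is.null(attribute_names)) attribute_names <- rules$attribute_names
    n <- rules$n_attributes
    rules <- rules$rules
  }
  if (is.na(n)) {
    n <- if (length(rules)) length(rules[[1]]$antecedents) else
      if (!is.null(attribute_names)) length(attribute_names) else NA_integer_
  }
  doc <- list(
    version = 1L,
    n_attributes = n,
    attribute_names = attribute_names,
    rules = lapply(rules, function(r) {
      list(antecedents = encode_rule(r), class = r$consequent, cf = r$cf)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
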