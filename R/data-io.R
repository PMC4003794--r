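# Data input: the 14-field comma-separated heart-disease record layout
# (13 predictors + angiographic outcome "num", "?" for missing values),
# min-max scaling into the unit hypercube, and a planted-rule synthetic
# generator used throughout the test suite.

.UCI_FIELDS <- c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
                 "thalach", "exang", "oldpeak", "slope", "ca", "thal", "num")

#' Min-max scaling schema
#'
#' `attribute_schema()` records per-attribute observed minima and maxima;
#' `scale_attributes()` maps values into \eqn{[0,1]} (clipping values outside
#' the observed training range); `unscale_attributes()` inverts the map for
#' in-range values.
#'
#' @param X Numeric matrix (rows = instances).
#' @param names Optional attribute names.
#' @param schema An `attribute_schema`.
#' @return `attribute_schema()`: a data frame with columns `name`, `min`,
#'   `max`; the scalers return a matrix.
#' @export
attribute_schema <- function(X, names = colnames(X)) {
  mins <- apply(X, 2, min, na.rm = TRUE)
  maxs <- apply(X, 2, max, na.rm = TRUE)
  if (any(!is.finite(mins) | !is.finite(maxs))) {
    stop("attribute with no observed values; cannot build scaling schema")
  }
  if (any(mins >= maxs)) {
    stop("constant attribute(s): ",
         paste(which(mins >= maxs), collapse = ", "),
         "; min-max scaling undefined")
  }
  if (is.null(names)) names <- paste0("x", seq_along(mins))
  data.frame(name = names, min = as.numeric(mins), max = as.numeric(maxs),
             stringsAsFactors = FALSE)
}

#' @rdname attribute_schema
#' @export
scale_attributes <- function(X, schema) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(schema)) stop("schema does not match attribute count")
  for (j in seq_len(ncol(X))) {
    X[, j] <- (X[, j] - schema$min[j]) / (schema$max[j] - schema$min[j])
  }
  X[X < 0] <- 0
  X[X > 1] <- 1
  colnames(X) <- schema$name
  X
}

#' @rdname attribute_schema
#' @export
unscale_attributes <- function(X, schema) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(schema)) stop("schema does not match attribute count")
  for (j in seq_len(ncol(X))) {
    X[, j] <- X[, j] * (schema$max[j] - schema$min[j]) + schema$min[j]
  }
  colnames(X) <- schema$name
  X
}

#' Read heart-disease records in the UCI processed layout
#'
#' Parses comma-separated records with 14 fields (age, sex, cp, trestbps,
#' chol, fbs, restecg, thalach, exang, oldpeak, slope, ca, thal, num) where
#' `"?"` marks a missing value. The angiographic outcome `num` is binarized:
#' 0 (less than 50% diameter narrowing) becomes `"healthy"`, 1--4 (number of
#' narrowed vessels) become `"patient"`. Predictors are min-max scaled to
#' \eqn{[0,1]} using the observed range (or a supplied `schema`, e.g. one
#' fitted on training folds only); missing values stay `NA` and behave as
#' don't-care in rule matching.
#'
#' @param path Path to a comma-separated file, one record per line.
#' @param schema Optional [attribute_schema()] to scale with; by default one
#'   is fitted to the file's own ranges.
#' @param scale Scale predictors into \eqn{[0,1]} (default `TRUE`).
#' @return List with `data` (a [weighted_dataset()], or `NULL` when
#'   `scale = FALSE`), `labels`, `schema`, and `raw` (the unscaled predictor
#'   matrix).
#' @export
read_uci <- function(path, schema = NULL, scale = TRUE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 14L)) {
    bad <- which(nf != 14L)[1]
    stop(sprintf("line %d has %d fields; expected 14", bad, nf[bad]))
  }
  tok <- matrix(trimws(unlist(parts)), ncol = 14L, byrow = TRUE)
  num <- suppressWarnings(
    matrix(as.numeric(ifelse(tok == "?", NA, tok)), ncol = 14L))
  bad <- which(is.na(num) & tok != "?", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("line %d, field %d: cannot parse %s as a number",
                 bad[1, 1], bad[1, 2], shQuote(tok[bad[1, 1], bad[1, 2]])))
  }
  colnames(num) <- .UCI_FIELDS
  outcome <- num[, "num"]
  if (any(is.na(outcome))) stop("missing outcome field (num) is not allowed")
  if (!all(outcome %in% 0:4)) stop("outcome field num must be an integer 0..4")
  labels <- ifelse(outcome == 0, "healthy", "patient")
  raw <- num[, 1:13, drop = FALSE]
  if (is.null(schema)) schema <- attribute_schema(raw)
  dat <- if (scale) weighted_dataset(scale_attributes(raw, schema), labels) else NULL
  list(data = dat, labels = labels, schema = schema, raw = raw)
}

#' Write instances back in the UCI comma-separated dialect
#'
#' @param X Predictor matrix (13 columns for the heart-disease layout, any
#'   width accepted); `NA` written as `"?"`.
#' @param labels Class labels; `"healthy"` maps to num 0, anything else to 1.
#'   Numeric labels are written as given.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_uci <- function(X, labels, path) {
  X <- as.matrix(X)
  num <- if (is.numeric(labels)) labels else ifelse(labels == "healthy", 0, 1)
  chr <- cbind(apply(X, 2, function(v) ifelse(is.na(v), "?", format(v, digits = 15, trim = TRUE))),
               as.character(num))
  writeLines(apply(chr, 1, paste, collapse = ","), path)
  invisible(path)
}

#' Specification of a planted-rule synthetic dataset
#'
#' Describes data drawn uniformly on the unit hypercube and labeled by
#' winner-rule inference over a small set of planted fuzzy rules (certainty
#' factors fixed to 1 for generation), with optional independent label noise.
#' Planted rules must occupy disjoint high-membership regions: the
#' compatibility of each rule's apex point (non-don't-care attributes at
#' their apexes, others at 0.5) with every other rule must fall below
#' `overlap_threshold`.
#'
#' @param n_attributes Number of attributes.
#' @param n_instances Number of instances to draw.
#' @param rules List of [fuzzy_rule()] with consequents (cf ignored).
#' @param noise Label-flip probability in \eqn{[0, 0.5)}.
#' @param fallback_class Label for instances no planted rule covers.
#' @param overlap_threshold Maximum allowed cross-rule apex compatibility.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_attributes, n_instances, rules,
                           noise = 0, fallback_class = NULL,
                           overlap_threshold = 0.5) {
  stopifnot(n_attributes >= 1L, n_instances >= 0L, length(rules) >= 1L)
  if (noise < 0 || noise >= 0.5) stop("noise rate must be in [0, 0.5)")
  for (r in rules) {
    if (length(r$antecedents) != n_attributes) {
      stop("planted rule length does not match n_attributes")
    }
    if (is.na(r$consequent)) stop("planted rules need consequents")
  }
  apexes <- t(vapply(rules, function(r) {
    x <- rep(0.5, n_attributes)
    act <- which(r$antecedents != 0L)
    for (j in act) {
      s <- r$antecedents[j] + 1L
      x[j] <- (.SYMBOL_TABLE$index[s] - 1) / (.SYMBOL_TABLE$granularity[s] - 1)
    }
    x
  }, numeric(n_attributes)))
  apexes <- matrix(apexes, nrow = length(rules))
  for (i in seq_along(rules)) {
    for (k in seq_along(rules)) {
      if (i == k) next
      ov <- compat_matrix(rules[[k]]$antecedents,
                          apexes[i, , drop = FALSE])
      if (ov >= overlap_threshold) {
        stop(sprintf("planted rules %d and %d overlap (apex compatibility %.3f >= %.3f)",
                     i, k, ov, overlap_threshold))
      }
    }
  }
  if (is.null(fallback_class)) {
    fallback_class <- rules[[1]]$consequent
  }
  structure(list(n_attributes = as.integer(n_attributes),
                 n_instances = as.integer(n_instances),
                 rules = rules, noise = noise,
                 fallback_class = as.character(fallback_class),
                 overlap_threshold = overlap_threshold),
            class = "synthetic_spec")
}

#' Canonical planted-rule benchmark conditions
#'
#' The reference synthetic conditions used throughout the package's own
#' validation: five attributes, two planted single-antecedent rules splitting
#' the first attribute with the granularity-3 partition (S3 -> `"healthy"`,
#' L3 -> `"patient"`; disjoint supports meeting at 0.5), 200 instances and 5%
#' label noise. The Bayes-optimal accuracy under these conditions is about
#' 95%.
#'
#' @param n_instances Number of instances (default 200).
#' @param noise Label-flip probability (default 0.05).
#' @return A [synthetic_spec()].
#' @export
planted_demo_spec <- function(n_instances = 200L, noise = 0.05) {
  synthetic_spec(
    n_attributes = 5L, n_instances = n_instances,
    rules = list(fuzzy_rule("30000", "healthy"),
                 fuzzy_rule("50000", "patient")),
    noise = noise, fallback_class = "healthy"
  )
}

#' Generate a planted-rule synthetic dataset
#'
#' Draws instances uniformly on \eqn{[0,1]^n}, labels each by the planted
#' winner rule (falling back to `spec$fallback_class` when no rule has
#' positive compatibility), then flips each label independently to a
#' different class with probability `spec$noise`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed.
#' @return List with `data` (a [weighted_dataset()]), `truth` (the noiseless
#'   labels) and `rules` (the planted ground-truth rules, cf = 1).
#' @export
generate_synthetic <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_attributes
  m <- spec$n_instances
  X <- matrix(stats::runif(m * n), m, n)
  colnames(X) <- paste0("x", seq_len(n))
  gen_rules <- lapply(spec$rules, function(r) fuzzy_rule(r$antecedents, r$consequent, 1))
  truth <- if (m > 0) classify(gen_rules, X) else character(0)
  truth[is.na(truth)] <- spec$fallback_class
  labels <- truth
  if (spec$noise > 0 && m > 0) {
    classes <- sort(unique(c(truth, vapply(gen_rules, `[[`, character(1), "consequent"))))
    flip <- stats::runif(m) < spec$noise
    if (any(flip)) {
      labels[flip] <- vapply(labels[flip], function(cl) {
        others <- setdiff(classes, cl)
        if (length(others) == 1L) others else sample(others, 1L)
      }, character(1), USE.NAMES = FALSE)
    }
  }
  list(data = weighted_dataset(X, labels), truth = truth, rules = gen_rules)
}
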