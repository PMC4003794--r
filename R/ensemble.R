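# Outer ensemble loop: repeated swarm runs accumulate fuzzy rules while the
# boosting update shrinks the weights of instances the accepted rules already
# classify correctly; training stops once the total remaining weight falls to
# the threshold K (or on the safety guards).

#' Training configuration
#'
#' @param K Total-weight stopping threshold: training ends once the summed
#'   boosting weights drop to `K` or below (default 12).
#' @param max_runs Safety cap on the number of swarm runs (default 50).
#' @param swarm A [swarm_config()] for the inner runs.
#' @param seed Optional integer seed controlling the whole training run.
#' @return A list of class `train_config`.
#' @export
train_config <- function(K = 12, max_runs = 50L, swarm = swarm_config(),
                         seed = NULL) {
  stopifnot(K > 0, max_runs >= 1L, inherits(swarm, "swarm_config"))
  structure(list(K = K, max_runs = as.integer(max_runs), swarm = swarm,
                 seed = seed),
            class = "train_config")
}

#' Train a fuzzy rule set by boosted swarm runs
#'
#' Initializes every instance weight to 1, then loops: run the discrete PSO
#' on the current weights, append its acceptable rules (skipping any rule the
#' set already contains), and for each newly appended rule reduce the weights
#' of the instances it classifies correctly ([update_weights()], with the
#' rule's error recomputed on the weights current at that moment). The loop
#' exits when the total weight is at most `cfg$K`, after `cfg$max_runs` runs,
#' or after two consecutive runs that contribute no new rule.
#'
#' @param data A [weighted_dataset()] with at least two classes.
#' @param cfg A [train_config()].
#' @param verbose Emit a progress message per run.
#' @return A `fuzzy_ruleset`: list with `rules`, `provenance` (run index per
#'   rule), `n_attributes`, `attribute_names`, `classes` and `log` (per run:
#'   rules added, total weight, cumulative training accuracy).
#' @export
train <- function(data, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(data, "weighted_dataset"), inherits(cfg, "train_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  data$weights <- rep(1, nrow(data$X))
  cache <- build_membership_cache(data$X)
  swarm <- cfg$swarm
  swarm$seed <- NULL  # the inner runs share the training run's generator

  rules <- list()
  provenance <- integer(0)
  keys <- character(0)
  empty_streak <- 0L
  log <- data.frame(run = integer(0), rules_added = integer(0),
                    total_weight = numeric(0), train_accuracy = numeric(0))
  run <- 0L
  while (run < cfg$max_runs && total_weight(data) > cfg$K) {
    run <- run + 1L
    found <- pso_run(data, swarm, cache = cache)
    added <- 0L
    for (r in found) {
      key <- paste(encode_rule(r), r$consequent)
      if (key %in% keys) next  # already accepted: no second weight update
      rules[[length(rules) + 1L]] <- r
      keys <- c(keys, key)
      provenance <- c(provenance, run)
      added <- added + 1L
      data <- update_weights(r, data)
    }
    pred <- classify_cached(rules, cache)
    acc <- mean(!is.na(pred) & pred == data$labels)
    log <- rbind(log, data.frame(run = run, rules_added = added,
                                 total_weight = total_weight(data),
                                 train_accuracy = acc))
    if (verbose) {
      message(sprintf("run %d: +%d rules (%d total), weight %.3f, train acc %.3f",
                      run, added, length(rules), total_weight(data), acc))
    }
    if (added == 0L) {
      empty_streak <- empty_streak + 1L
      if (empty_streak >= 2L) break
    } else {
      empty_streak <- 0L
    }
  }

  structure(list(rules = rules, provenance = provenance,
                 n_attributes = ncol(data$X),
                 attribute_names = colnames(data$X),
                 classes = sort(unique(data$labels)),
                 log = log),
            class = "fuzzy_ruleset")
}

#' @export
print.fuzzy_ruleset <- function(x, ...) {
  st <- ruleset_stats(x)
  cat(sprintf("fuzzy_ruleset: %d rules over %d attributes (mean length %.2f), classes: %s\n",
              st$count, x$n_attributes, st$mean_length,
              paste(x$classes, collapse = "/")))
  for (r in x$rules) print(r)
  invisible(x)
}

#' Predict classes with a trained rule set
#'
#' Winner-rule inference over the trained rules; instances no rule covers
#' with positive product are returned as `NA` (unclassified).
#'
#' @param object A `fuzzy_ruleset` from [train()].
#' @param newdata Numeric matrix (values in \eqn{[0,1]}) or
#'   [weighted_dataset()].
#' @param ... Unused.
#' @return Character vector of predicted classes (`NA` = unclassified).
#' @export
predict.fuzzy_ruleset <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "weighted_dataset")) newdata$X else as.matrix(newdata)
  if (ncol(X) != object$n_attributes) {
    stop("rule set was trained on ", object$n_attributes,
         " attributes but newdata has ", ncol(X))
  }
  classify(object$rules, X)
}

#' Rule-set size and mean antecedent length
#'
#' The interpretability summary of a rule set: how many rules it holds and
#' the average number of active (non-don't-care) antecedents per rule.
#'
#' @param rs A `fuzzy_ruleset` or list of [fuzzy_rule()].
#' @return List with `count` and `mean_length` (0 for an empty set).
#' @export
ruleset_stats <- function(rs) {
  rules <- if (inherits(rs, "fuzzy_ruleset")) rs$rules else rs
  if (length(rules) == 0L) return(list(count = 0L, mean_length = 0))
  lens <- vapply(rules, function(r) sum(r$antecedents != 0L), numeric(1))
  list(count = length(rules), mean_length = mean(lens))
}

#' Write the per-run training log
#'
#' Tab-separated text with one row per swarm run: rules added, remaining
#' total weight and cumulative training accuracy (for plotting learning
#' curves).
#'
#' @param rs A `fuzzy_ruleset` from [train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_train_log <- function(rs, path) {
  utils::write.table(rs$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
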