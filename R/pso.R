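# Discrete particle swarm over the RAM algebra. A particle is a set of B
# candidate rules; its velocity is one RAM sequence per rule slot. Candidate
# consequents, certainty factors and pruning scores are re-derived from the
# (weighted) training data at every iteration; the particle's fitness is the
# weighted winner-rule accuracy of its acceptable rules.

#' Swarm configuration
#'
#' Defaults follow the reference parameterization: 25 particles of B = 20
#' candidate rules, inertia 1/iteration, acceleration coefficients drawn
#' uniformly on \eqn{[0,1]} each iteration, and termination when the global
#' best is unchanged for 5 consecutive iterations.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param B Candidate rules per particle.
#' @param g_threshold Pruning threshold: a candidate whose covered
#'   misclassified weight exceeds `g_threshold` times its covered correctly
#'   classified weight is excluded from the acceptable set.
#' @param stall_limit Stop after this many consecutive iterations without a
#'   global-best improvement.
#' @param max_iter Hard iteration cap.
#' @param omega Fixed inertia coefficient, or `NULL` for the 1/iteration
#'   schedule (clamped to \eqn{[0,1]}).
#' @param c1,c2 Fixed acceleration coefficients toward the local and global
#'   best, or `NULL` to redraw each from U(0,1) every iteration for every
#'   rule slot.
#' @param seed Optional integer seed for the run's random generator.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(swarm_size = 25L, B = 20L, g_threshold = 1,
                         stall_limit = 5L, max_iter = 200L,
                         omega = NULL, c1 = NULL, c2 = NULL, seed = NULL) {
  stopifnot(swarm_size >= 2L, B >= 1L, stall_limit >= 1L, max_iter >= 1L,
            g_threshold > 0)
  structure(list(swarm_size = as.integer(swarm_size), B = as.integer(B),
                 g_threshold = g_threshold, stall_limit = as.integer(stall_limit),
                 max_iter = as.integer(max_iter), omega = omega,
                 c1 = c1, c2 = c2, seed = seed),
            class = "swarm_config")
}

# per-attribute membership lookup: array of dim (m, 15, n), slice [, s+1, j]
# holding the membership of symbol s at attribute j for every instance
build_membership_cache <- function(X) {
  m <- nrow(X); n <- ncol(X)
  MEM <- array(1, dim = c(m, 15L, n))
  for (j in seq_len(n)) {
    for (s in 1:14) MEM[, s + 1L, j] <- membership(s, X[, j])
  }
  MEM
}

# compatibility of every rule row of Rmat (B x n, integer symbols) with every
# instance, via the cache; returns m x B
compat_from_cache <- function(Rmat, MEM) {
  m <- dim(MEM)[1]; n <- dim(MEM)[3]
  mu <- matrix(1, m, nrow(Rmat))
  for (j in seq_len(n)) mu <- mu * MEM[, Rmat[, j] + 1L, j]
  mu
}

# Evaluate a stack of candidate antecedent rows (R x n integer matrix)
# against weighted data: consequents and CFs from the class-compatibility
# sums, pruning scores g and the acceptable flag per row. classes/counts are
# the sorted class labels and their sizes; w the current boosting weights.
eval_rule_matrix <- function(Rmat, MEM, labels, classes, counts, w, g_threshold) {
  B <- nrow(Rmat)
  cnum <- length(classes)
  mu <- compat_from_cache(Rmat, MEM)                    # m x R
  beta <- rowsum(mu, labels) / counts                   # c x R (sorted classes)
  total <- colSums(beta)
  bmax <- beta[1, ]
  if (cnum > 1L) for (k in 2:cnum) bmax <- pmax(bmax, beta[k, ])
  ties <- colSums(beta == rep(bmax, each = cnum))
  rejected <- total <= 0 | ties > 1L
  wi <- max.col(t(beta), ties.method = "first")
  cons <- classes[wi]
  cf <- ifelse(rejected, NA_real_, (bmax - (total - bmax) / (cnum - 1)) / total)
  # pruning score: covered (mu > 0) weight of mismatched over matched labels
  CW <- rowsum(w * (mu > 0), labels)                    # c x R
  ncp <- CW[cbind(wi, seq_len(B))]
  nmp <- colSums(CW) - ncp
  g <- ifelse(ncp == 0, Inf, nmp / ncp)
  acceptable <- !rejected & !is.na(cf) & cf > 0 & g <= g_threshold
  list(mu = mu, consequent = cons, cf = cf, g = g, acceptable = acceptable)
}

# weighted winner-rule accuracy of the acceptable columns of an evaluated
# rule block; cols indexes the block's columns within ev$mu
block_fitness <- function(ev, cols, labels, w, total_w) {
  acc <- cols[ev$acceptable[cols]]
  if (length(acc) == 0L) return(0)
  sc <- ev$mu[, acc, drop = FALSE] * rep(ev$cf[acc], each = nrow(ev$mu))
  pred <- winner_class(sc, ev$consequent[acc])
  sum(w[!is.na(pred) & pred == labels]) / total_w
}

# winner-rule predictions for a list of fitted rules via the membership
# cache (training-loop bookkeeping)
classify_cached <- function(rules, MEM) {
  m <- dim(MEM)[1]
  if (length(rules) == 0L) return(rep(NA_character_, m))
  Rmat <- do.call(rbind, lapply(rules, `[[`, "antecedents"))
  mu <- compat_from_cache(Rmat, MEM)
  cf <- vapply(rules, `[[`, numeric(1), "cf")
  sc <- mu * rep(cf, each = m)
  winner_class(sc, vapply(rules, `[[`, character(1), "consequent"))
}

#' Pruning score of a candidate rule
#'
#' Ratio of the total boosting weight of covered instances (positive
#' compatibility) whose label disagrees with the rule's consequent to the
#' total weight of covered instances whose label agrees. Candidates with a
#' score above the swarm's threshold are pruned from the acceptable set. A
#' rule covering no correctly labeled weight scores `Inf`.
#'
#' @param rule A [fuzzy_rule()] with a consequent.
#' @param data A [weighted_dataset()].
#' @return A nonnegative number (possibly `Inf`).
#' @export
g_score <- function(rule, data) {
  stopifnot(inherits(data, "weighted_dataset"))
  if (is.na(rule$consequent)) stop("rule has no consequent")
  mu <- compat_matrix(rule$antecedents, data$X)
  covered <- mu > 0
  ncp <- sum(data$weights[covered & data$labels == rule$consequent])
  nmp <- sum(data$weights[covered & data$labels != rule$consequent])
  if (ncp == 0) Inf else nmp / ncp
}

#' Weighted winner-rule accuracy of a rule set
#'
#' Fitness of a particle: the acceptable candidates (certainty factor > 0 and
#' pruning score at most `g_threshold`) classify the data by winner rule, and
#' the fraction of total instance weight classified correctly is returned.
#' Unclassified instances count as errors.
#'
#' @param rules List of [fuzzy_rule()] with consequents and certainty factors.
#' @param data A [weighted_dataset()].
#' @param g_threshold Pruning threshold (see [swarm_config()]).
#' @return Weighted accuracy in \eqn{[0,1]}.
#' @export
particle_fitness <- function(rules, data, g_threshold = 1) {
  stopifnot(inherits(data, "weighted_dataset"))
  tw <- sum(data$weights)
  if (tw == 0) stop("total instance weight is zero; fitness undefined")
  keep <- vapply(rules, function(r) {
    !is.na(r$cf) && r$cf > 0 && g_score(r, data) <= g_threshold
  }, logical(1))
  rules <- rules[keep]
  if (length(rules) == 0L) return(0)
  pred <- classify(rules, data$X)
  sum(data$weights[!is.na(pred) & pred == data$labels]) / tw
}

#' Extract fuzzy rules with a discrete particle swarm
#'
#' Runs the discrete PSO: particles hold B candidate rules whose consequents,
#' certainty factors and pruning scores are re-derived from the weighted data
#' each iteration; velocities are RAM sequences updated as
#' `omega * V + c1 * brams(r, local best) + c2 * brams(r, global best)`
#' (coefficient times sequence = independent per-edit retention) and applied
#' to the positions. The run stops when the global best has not improved for
#' `stall_limit` consecutive iterations (or at `max_iter`). Returns the
#' acceptable rules of the global best, deduplicated, with certainty factors
#' fitted on the supplied weights.
#'
#' @param data A [weighted_dataset()] with at least two classes.
#' @param cfg A [swarm_config()].
#' @param cache Optional precomputed membership cache (internal reuse).
#' @return A list of [fuzzy_rule()]; attribute `"trace"` holds a data frame
#'   of per-iteration global-best fitness and `"fitness"` the final value.
#' @export
pso_run <- function(data, cfg = swarm_config(), cache = NULL) {
  stopifnot(inherits(data, "weighted_dataset"), inherits(cfg, "swarm_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  labels <- data$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes in the data")
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  w <- data$weights
  if (sum(w) == 0) stop("total instance weight is zero")
  if (is.null(cache)) cache <- build_membership_cache(data$X)
  m <- nrow(data$X); n <- ncol(data$X)
  L <- cfg$swarm_size; B <- cfg$B

  # All particles are stacked into one (L*B) x n matrix of antecedent
  # symbols; slot (h, j) is row (h-1)*B + j. A velocity kept in basic form
  # (at most one RAM per position) is a partial position -> symbol map, so
  # the whole swarm's velocities live in one (L*B) x n matrix with NA
  # meaning "no edit at this position". Merging then overwrites non-NA
  # cells (later term wins) and coefficient scaling is per-cell Bernoulli
  # retention -- the matrix form of scale_rams()/ram_merge().
  nslots <- L * B
  pos <- matrix(sample(0:14, nslots * n, replace = TRUE), nslots, n)
  invisible(stats::runif(nslots))   # the random initial pruning scores
  vel <- matrix(sample(0:14, nslots * n, replace = TRUE), nslots, n)
  vel[stats::runif(nslots * n) < 0.5] <- NA_integer_
  lbest_pos <- pos
  lbest_fit <- rep(-Inf, L)
  gbest_rows <- NULL          # B x n matrix copied from the best particle
  gbest_fit <- -Inf
  stall <- 0L
  total_w <- sum(w)
  slot_of <- function(h) (h - 1L) * B + seq_len(B)
  trace_fit <- numeric(0)

  for (t in seq_len(cfg$max_iter)) {
    ev <- eval_rule_matrix(pos, cache, labels, classes, counts, w,
                           cfg$g_threshold)
    for (h in seq_len(L)) {
      rows <- slot_of(h)
      fit <- block_fitness(ev, rows, labels, w, total_w)
      if (fit > lbest_fit[h]) {
        lbest_fit[h] <- fit
        lbest_pos[rows, ] <- pos[rows, ]
      }
    }
    top <- which.max(lbest_fit)   # earliest index on ties
    if (lbest_fit[top] > gbest_fit) {
      gbest_fit <- lbest_fit[top]
      gbest_rows <- lbest_pos[slot_of(top), , drop = FALSE]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace_fit <- c(trace_fit, gbest_fit)
    if (stall >= cfg$stall_limit) break

    omega <- if (is.null(cfg$omega)) min(1, 1 / t) else cfg$omega
    # acceleration coefficients are redrawn each iteration for every rule
    # slot (a slot is one coordinate of a particle's position, mirroring the
    # per-dimension stochastic factors of classical PSO)
    c1v <- rep(if (is.null(cfg$c1)) stats::runif(nslots) else rep(cfg$c1, nslots), n)
    c2v <- rep(if (is.null(cfg$c2)) stats::runif(nslots) else rep(cfg$c2, nslots), n)
    # velocity update: omega * V (+) c1 * brams(r, local best)
    # (+) c2 * brams(r, global best)
    vel[stats::runif(nslots * n) >= omega] <- NA_integer_
    gb <- gbest_rows[rep(seq_len(B), L), , drop = FALSE]
    m1 <- pos != lbest_pos & stats::runif(nslots * n) < c1v
    vel[m1] <- lbest_pos[m1]
    m2 <- pos != gb & stats::runif(nslots * n) < c2v
    vel[m2] <- gb[m2]
    edit <- !is.na(vel)
    pos[edit] <- vel[edit]
  }
  trace <- data.frame(iteration = seq_along(trace_fit), best_fitness = trace_fit)

  # final acceptable rules of the global best, deduplicated
  ev <- eval_rule_matrix(gbest_rows, cache, labels, classes, counts, w,
                         cfg$g_threshold)
  idx <- which(ev$acceptable)
  rules <- lapply(idx, function(j) {
    fuzzy_rule(gbest_rows[j, ], ev$consequent[j], ev$cf[j])
  })
  if (length(rules) > 1L) {
    key <- vapply(rules, function(r) paste(encode_rule(r), r$consequent),
                  character(1))
    rules <- rules[!duplicated(key)]
  }
  attr(rules, "trace") <- trace
  attr(rules, "fitness") <- gbest_fit
  rules
}
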