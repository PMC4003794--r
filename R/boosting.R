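# Boosting re-weighting: after a rule is accepted, the weights of the
# instances it classifies correctly are multiplicatively reduced, the more so
# the better the instance matches the rule's antecedent and the smaller the
# rule's weighted error, so that the next swarm run concentrates on
# misclassified or uncovered instances. Weights of misclassified and
# uncovered instances are left exactly unchanged.

#' Weighted error of a rule
#'
#' The compatibility-weighted error: the summed `weight * compatibility` of
#' instances whose label disagrees with the rule's consequent, divided by the
#' same sum over all instances. A rule that covers nothing (all
#' compatibilities zero) has error 0 by convention and triggers no weight
#' change.
#'
#' @param rule A [fuzzy_rule()] with a consequent.
#' @param data A [weighted_dataset()].
#' @return Error in \eqn{[0,1]}.
#' @export
rule_error <- function(rule, data) {
  stopifnot(inherits(data, "weighted_dataset"))
  if (is.na(rule$consequent)) stop("rule has no consequent")
  mu <- compat_matrix(rule$antecedents, data$X)
  denom <- sum(data$weights * mu)
  if (denom == 0) return(0)
  sum(data$weights[data$labels != rule$consequent] *
        mu[data$labels != rule$consequent]) / denom
}

#' Weight-reduction factor for a correctly classified instance
#'
#' The multiplicative factor applied to the weight of an instance whose label
#' matches the rule's consequent:
#' \deqn{\alpha = \left(\frac{1}{1 + e^{\mu/(ER + w)}}\right)^{\mu}}
#' where \eqn{\mu} is the instance's compatibility with the rule, ER the
#' rule's weighted error and \eqn{w} the instance's current weight. The
#' factor lies in \eqn{(0, 1]}, equals 1 exactly at \eqn{\mu = 0}, and
#' decreases as the instance matches the rule better.
#'
#' @param mu Compatibility in \eqn{[0,1]} (vectorized).
#' @param er Rule error in \eqn{[0,1]}.
#' @param w Instance weight(s), nonnegative.
#' @return Factor(s) in \eqn{(0, 1]}.
#' @export
alpha_factor <- function(mu, er, w) {
  w <- rep_len(w, length(mu))
  if (any(mu > 0 & (er + w) == 0)) {
    stop("degenerate weight-reduction denominator: er + w == 0 with mu > 0")
  }
  out <- rep(1, length(mu))
  pos <- mu > 0
  out[pos] <- (1 / (1 + exp(mu[pos] / (er + w[pos])))) ^ mu[pos]
  out
}

#' Reduce instance weights after accepting a rule
#'
#' Applies the boosting update: every instance whose label equals the rule's
#' consequent and that the rule covers (positive compatibility) has its
#' weight multiplied by [alpha_factor()]; every other instance keeps its
#' weight bitwise unchanged. The rule's error is computed on the incoming
#' weights.
#'
#' @param rule A [fuzzy_rule()] with a consequent.
#' @param data A [weighted_dataset()].
#' @return The updated [weighted_dataset()].
#' @export
update_weights <- function(rule, data) {
  stopifnot(inherits(data, "weighted_dataset"))
  mu <- compat_matrix(rule$antecedents, data$X)
  er <- rule_error(rule, data)
  # zero-weight instances stay at zero: the multiplicative factor cannot
  # move them and its exponential is unstable at w = 0
  idx <- data$labels == rule$consequent & mu > 0 & data$weights > 0
  if (any(idx)) {
    data$weights[idx] <- data$weights[idx] *
      alpha_factor(mu[idx], er, data$weights[idx])
  }
  data
}

#' Total boosting weight
#'
#' @param data A [weighted_dataset()].
#' @return Sum of instance weights.
#' @export
total_weight <- function(data) sum(data$weights)
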