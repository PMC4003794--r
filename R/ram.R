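# Rule-antecedent modification (RAM) algebra: the combinatorial "velocity"
# space of the discrete particle swarm. A RAM substitutes one antecedent
# symbol; a RAM sequence applies in order; the basic form keeps at most one
# RAM per position (the last one); the minimal sequence between two rules has
# one RAM per differing position.

#' RAM operators and sequences
#'
#' `ram()` builds a single rule-antecedent modification: "replace the symbol
#' at `position` with `symbol`". `ram_seq()` builds an ordered sequence of
#' such operators from parallel vectors. Sequences are stored as two-column
#' integer matrices (`pos`, `sym`); an empty sequence has zero rows.
#'
#' @param position 1-based antecedent position(s).
#' @param symbol Replacement symbol(s): character codes or integers 0--14.
#' @return A `ram_seq`: integer matrix with columns `pos` and `sym`.
#' @export
ram <- function(position, symbol) ram_seq(position, symbol)

#' @rdname ram
#' @export
ram_seq <- function(position = integer(0), symbol = integer(0)) {
  sym <- if (is.character(symbol)) symbol_int(symbol) else as.integer(symbol)
  pos <- as.integer(position)
  if (length(pos) != length(sym)) stop("position and symbol lengths differ")
  if (any(pos < 1L)) stop("RAM position must be >= 1")
  if (length(sym) && any(sym < 0L | sym > 14L)) stop("RAM symbol out of alphabet")
  structure(cbind(pos = pos, sym = sym), class = "ram_seq")
}

as_ram_seq <- function(x) {
  if (!inherits(x, "ram_seq")) stop("expected a ram_seq")
  x
}

#' @export
print.ram_seq <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("ram_seq: (empty)\n")
  } else {
    cat(sprintf("ram_seq: %s\n",
                paste(sprintf("RAM(%d, %s)", x[, "pos"], symbol_code(x[, "sym"])),
                      collapse = " -> ")))
  }
  invisible(x)
}

#' @export
length.ram_seq <- function(x) nrow(unclass(x))

#' Apply RAM operators to a rule
#'
#' `apply_ram()` applies a single substitution; `apply_rams()` applies a
#' sequence left to right, so a later operator at the same position
#' overrides an earlier one. The input rule is not modified. The consequent
#' and certainty factor are carried over unchanged; callers that need them
#' for the new antecedents must re-derive them from data.
#'
#' @param rule A [fuzzy_rule()].
#' @param op,seq A `ram_seq` (for `apply_ram()`, of length 1).
#' @return A new `fuzzy_rule`.
#' @export
apply_ram <- function(rule, op) {
  op <- as_ram_seq(op)
  if (nrow(op) != 1L) stop("apply_ram() takes exactly one operator")
  apply_rams(rule, op)
}

#' @rdname apply_ram
#' @export
apply_rams <- function(rule, seq) {
  seq <- as_ram_seq(seq)
  ant <- rule$antecedents
  if (nrow(seq) > 0L) {
    if (any(seq[, "pos"] > length(ant))) stop("RAM position exceeds rule length")
    ant[seq[, "pos"]] <- seq[, "sym"]  # duplicate positions: last assignment wins
  }
  fuzzy_rule(ant, rule$consequent, rule$cf)
}

# reduce a sequence to basic form: at most one op per position, keeping the
# last occurrence (application order makes earlier ones dead writes)
basic_form <- function(seq) {
  seq <- as_ram_seq(seq)
  if (nrow(seq) <= 1L) return(seq)
  keep <- !duplicated(seq[, "pos"], fromLast = TRUE)
  structure(seq[keep, , drop = FALSE], class = "ram_seq")
}

#' Merge two RAM sequences
#'
#' Concatenates `a` then `b` and reduces to basic form, producing the
#' shortest sequence with the same effect as applying `a` followed by `b`.
#'
#' @param a,b `ram_seq` objects.
#' @return A `ram_seq` in basic form.
#' @export
ram_merge <- function(a, b) {
  a <- as_ram_seq(a); b <- as_ram_seq(b)
  basic_form(structure(rbind(a, b), class = "ram_seq"))
}

#' Minimal RAM sequence between two rules
#'
#' The basic sequence transforming `from`'s antecedents into `to`'s: one
#' substitution per position where the symbols differ, taking the new symbol
#' from `to`. Its length equals the Hamming distance between the two
#' antecedent strings, and `apply_rams(from, brams(from, to))` reproduces
#' `to`'s antecedents.
#'
#' @param from,to [fuzzy_rule()] objects with equal antecedent length.
#' @return A `ram_seq`.
#' @export
brams <- function(from, to) {
  a <- from$antecedents; b <- to$antecedents
  if (length(a) != length(b)) stop("rules have different antecedent lengths")
  d <- which(a != b)
  ram_seq(d, b[d])
}

#' Scale a RAM sequence by a coefficient
#'
#' Multiplying a velocity sequence by a coefficient `c` in \eqn{[0,1]} keeps
#' each operator independently with probability `c` (order preserved), so the
#' expected number of retained edits is `c` times the sequence length.
#' Coefficients outside \eqn{[0,1]} are clamped with a warning.
#'
#' @param c Retention probability.
#' @param seq A `ram_seq`.
#' @return A `ram_seq`.
#' @export
scale_rams <- function(c, seq) {
  seq <- as_ram_seq(seq)
  if (is.na(c)) stop("coefficient must be a number")
  if (c < 0 || c > 1) {
    warning("coefficient clamped to [0,1]")
    c <- min(max(c, 0), 1)
  }
  if (nrow(seq) == 0L || c == 1) return(seq)
  if (c == 0) return(ram_seq())
  keep <- stats::runif(nrow(seq)) < c
  structure(seq[keep, , drop = FALSE], class = "ram_seq")
}
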