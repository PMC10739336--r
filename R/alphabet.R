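## Nucleotide alphabet, IUPAC ambiguity expansion and the bit encoding used
## by the diagnostic-site scanner.
##
## Every alignment cell is one symbol over {A,C,G,T, IUPAC codes, N, ?, -}.
## A symbol denotes a *state set*: a subset of {A,C,G,T,-} (IUPAC codes
## expand to their canonical nucleotide sets, '-' is the literal gap state),
## or "missing" (N and '?' under the default policy). State sets are encoded
## as 5-bit integers (A=1, C=2, G=4, T=8, gap=16); missing cells encode to 0
## so that they contribute nothing to unions and are easy to drop.

#' IUPAC state sets
#'
#' Named list mapping each admissible alignment symbol (other than the
#' missing-data symbols `N` and `?`) to the set of character states it
#' denotes. The gap symbol `-` denotes the literal gap state.
#'
#' @format A named list of character vectors.
#' @export
IUPAC_STATES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  `-` = "-"
)

#' Variation-event types
#'
#' The eight event types, in reporting order: the four single-column
#' categories and their `multi_` counterparts for runs of two or more
#' consecutive diagnostic columns.
#'
#' @format Character vector of length 8.
#' @export
MDC_EVENT_TYPES <- c(
  "substitution", "deletion", "insertion", "mixed",
  "multi_substitution", "multi_deletion", "multi_insertion", "multi_mixed"
)

.STATE_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L, `-` = 16L)
.GAP_BIT <- 16L
.NUC_BITS <- 15L

.ALLOWED_SYMBOLS <- c(names(IUPAC_STATES), "N", "?")

## Symbol -> bitmask lookup under a missing-data policy.
## "ignore": N/? encode to 0 (the specimen contributes nothing there);
## "strict": N/? expand to {A,C,G,T}.
.symbol_bits <- function(missing = c("ignore", "strict")) {
  missing <- match.arg(missing)
  bits <- vapply(IUPAC_STATES, function(st) sum(.STATE_BIT[st]), integer(1))
  miss <- if (missing == "ignore") 0L else .NUC_BITS
  c(bits, N = miss, `?` = miss)
}

.states_to_bits <- function(states) {
  states <- unique(as.character(states))
  bad <- setdiff(states, names(.STATE_BIT))
  if (length(bad) > 0) {
    abort(paste0("unknown character state(s): ", paste(bad, collapse = ", ")))
  }
  sum(.STATE_BIT[states])
}

.bits_to_states <- function(bits) {
  names(.STATE_BIT)[bitwAnd(bits, .STATE_BIT) > 0L]
}

.bits_to_label <- function(bits) {
  vapply(bits, function(b) paste(.bits_to_states(b), collapse = "/"),
         character(1))
}

.complement_symbol <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `?` = "?", `-` = "-"
)

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented to their partner codes; `N`, `?`
#' and `-` are preserved.
#'
#' @param x A single nucleotide string.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  out <- .complement_symbol[ch]
  if (anyNA(out)) {
    abort(paste0("non-nucleotide symbol at position ",
                 which(is.na(out))[1], ": '", ch[which(is.na(out))[1]], "'"))
  }
  paste(rev(unname(out)), collapse = "")
}
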