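## Mean pairwise sequence identity and consensus per genus alignment.
##
## Identity convention (switchable): columns gapped in BOTH sequences are
## not compared; a gap against a residue counts as a mismatch under the
## default "mismatch" mode and is excluded under "exclude"; columns with
## N/? in either sequence are never compared.

#' Pairwise identity of two aligned sequences
#'
#' @param a,b Aligned sequences of equal length.
#' @param gap_mode `"mismatch"` (gap vs residue is a mismatch, default) or
#'   `"exclude"` (any gapped column is dropped from the comparison).
#' @return Percentage of identical symbols among compared columns.
#' @export
pairwise_identity <- function(a, b, gap_mode = c("mismatch", "exclude")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(is.character(a), is.character(b),
            length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) abort("sequences must have equal length")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  drop <- ca %in% c("N", "?") | cb %in% c("N", "?")
  drop <- drop | if (gap_mode == "mismatch") {
    ca == "-" & cb == "-"
  } else {
    ca == "-" | cb == "-"
  }
  keep <- !drop
  if (!any(keep)) abort("no comparable columns between the two sequences")
  mean(ca[keep] == cb[keep]) * 100
}

#' Mean pairwise identity of a genus alignment
#'
#' Averages [pairwise_identity()] over all unordered specimen pairs
#' (specimen records, not species means).
#'
#' @param alignment An alignment tibble with at least 2 records.
#' @param gap_mode Passed to [pairwise_identity()].
#' @param per_pair Keep the full symmetric matrix of pairwise identities.
#' @return An `identity_result`: list with `genus`, `mean_identity_pct`,
#'   `n_pairs` and (optionally) `per_pair`, a symmetric matrix with 100 on
#'   the diagonal.
#' @export
mean_pairwise_identity <- function(alignment,
                                   gap_mode = c("mismatch", "exclude"),
                                   per_pair = FALSE) {
  gap_mode <- match.arg(gap_mode)
  alignment <- as_alignment(alignment)
  n <- nrow(alignment)
  if (n < 2) abort("mean pairwise identity needs at least 2 records")
  pairs <- combn(n, 2)
  vals <- vapply(seq_len(ncol(pairs)), function(k) {
    pairwise_identity(alignment$sequence[pairs[1, k]],
                      alignment$sequence[pairs[2, k]], gap_mode)
  }, numeric(1))
  mat <- NULL
  if (per_pair) {
    mat <- matrix(100, n, n,
                  dimnames = list(alignment$specimen_id,
                                  alignment$specimen_id))
    for (k in seq_len(ncol(pairs))) {
      mat[pairs[1, k], pairs[2, k]] <- vals[k]
      mat[pairs[2, k], pairs[1, k]] <- vals[k]
    }
  }
  structure(
    list(genus = alignment$genus[1],
         mean_identity_pct = mean(vals),
         n_pairs = ncol(pairs),
         per_pair = mat),
    class = "identity_result"
  )
}

#' @export
print.identity_result <- function(x, ...) {
  cat("Mean pairwise identity for", x$genus, ":",
      sprintf("%.2f%%", x$mean_identity_pct),
      "over", x$n_pairs, "pairs\n")
  invisible(x)
}

#' Consensus sequence of a genus alignment
#'
#' Per column, the most frequent symbol among `A, C, G, T, -` wins
#' (ambiguity codes and `N`/`?` do not vote); ties are broken by the fixed
#' order given in `tie_order`. Columns whose winner is the gap are dropped
#' from the emitted sequence (support is recorded before dropping). An
#' all-missing column emits `N` with support 0.
#'
#' @param alignment An alignment tibble.
#' @param tie_order Symbol ranking used to break ties.
#' @return A `consensus_sequence`: list with `genus`, `seq` (gap-stripped),
#'   `column_support` (per alignment column, majority fraction among
#'   voters) and `kept` (logical, which columns made it into `seq`).
#' @export
consensus <- function(alignment, tie_order = c("A", "C", "G", "T", "-")) {
  alignment <- as_alignment(alignment)
  stopifnot(setequal(tie_order, c("A", "C", "G", "T", "-")))
  m <- .char_matrix(alignment)
  ncols <- ncol(m)
  winners <- character(ncols)
  support <- numeric(ncols)
  counts <- vapply(tie_order, function(sym) colSums(m == sym),
                   numeric(ncols))
  if (ncols == 1) counts <- matrix(counts, nrow = 1,
                                   dimnames = list(NULL, tie_order))
  voters <- rowSums(counts)
  win_idx <- apply(counts, 1, which.max)  # first max, i.e. tie_order rank
  winners <- tie_order[win_idx]
  support <- ifelse(voters > 0,
                    counts[cbind(seq_len(ncols), win_idx)] / voters, 0)
  winners[voters == 0] <- "N"
  kept <- winners != "-"
  structure(
    list(genus = alignment$genus[1],
         seq = paste(winners[kept], collapse = ""),
         column_support = support,
         kept = kept),
    class = "consensus_sequence"
  )
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat("Consensus for", x$genus, ":", nchar(x$seq), "bp (",
      sum(!x$kept), "gap-majority columns dropped )\n")
  invisible(x)
}

#' Write genus consensus sequences to FASTA
#'
#' @param consensuses A list of [consensus()] results (or a single one).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensuses, path) {
  if (inherits(consensuses, "consensus_sequence")) {
    consensuses <- list(consensuses)
  }
  seqinr::write.fasta(lapply(consensuses, `[[`, "seq"),
                      names = vapply(consensuses, `[[`, character(1), "genus"),
                      file.out = path, nbchar = 80)
  invisible(path)
}
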