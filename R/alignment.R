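## A genus alignment is a plain tibble with one row per specimen:
## columns genus, species, specimen_id, sequence (aligned, equal lengths).

#' Coerce and validate a genus alignment
#'
#' An alignment is a data frame with columns `genus`, `species`,
#' `specimen_id` and `sequence` (one row per specimen). Sequences are
#' uppercased and checked for equal length and for admissible symbols
#' (`A C G T`, IUPAC ambiguity codes, `N`, `?`, `-`).
#'
#' @param x A data frame with the four alignment columns.
#' @param min_species Minimum number of distinct species required
#'   (the study inclusion rule is 3; the default here is 1 so that
#'   low-level operations stay usable on reduced alignments).
#' @return A validated tibble.
#' @export
as_alignment <- function(x, min_species = 1) {
  need <- c("genus", "species", "specimen_id", "sequence")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("alignment is missing column(s): ", paste(miss, collapse = ", ")))
  }
  x <- as_tibble(x)[, need]
  if (nrow(x) == 0) abort("alignment has no records")
  x$sequence <- toupper(x$sequence)
  lens <- nchar(x$sequence)
  if (length(unique(lens)) != 1) {
    abort("aligned sequences must all have equal length")
  }
  if (lens[1] == 0) abort("alignment has zero columns")
  bad <- str_detect(x$sequence, "[^ACGTRYSWKMBDHVN?-]")
  if (any(bad)) {
    rec <- x$specimen_id[which(bad)[1]]
    sym <- str_match(x$sequence[which(bad)[1]], "([^ACGTRYSWKMBDHVN?-])")[, 2]
    abort(paste0("record '", rec, "' contains invalid symbol '", sym, "'"))
  }
  if (length(unique(x$species)) < min_species) {
    abort(paste0("alignment has fewer than ", min_species, " species"))
  }
  x
}

#' Number of columns of an alignment
#' @param alignment An alignment tibble (see [as_alignment()]).
#' @return Integer column count.
#' @export
n_alignment_columns <- function(alignment) {
  nchar(as_alignment(alignment)$sequence[1])
}

## Specimens-by-columns character matrix.
.char_matrix <- function(alignment) {
  ch <- strsplit(alignment$sequence, "", fixed = TRUE)
  m <- matrix("", nrow = length(ch), ncol = length(ch[[1]]))
  for (i in seq_along(ch)) m[i, ] <- ch[[i]]
  rownames(m) <- alignment$specimen_id
  m
}

## Specimens-by-columns bitmask matrix under a missing-data policy.
## mask_terminal_gaps turns leading/trailing gap runs (alignment end-trim
## artifacts) into missing cells.
.encode_bits <- function(alignment, missing = "ignore",
                         mask_terminal_gaps = FALSE) {
  m <- .char_matrix(alignment)
  tab <- .symbol_bits(missing)
  bm <- matrix(tab[m], nrow = nrow(m))
  if (anyNA(bm)) {
    idx <- which(is.na(bm), arr.ind = TRUE)[1, ]
    abort(paste0("record '", alignment$specimen_id[idx[1]],
                 "' has invalid symbol '", m[idx[1], idx[2]],
                 "' at column ", idx[2] - 1L, " (0-based)"))
  }
  if (mask_terminal_gaps) {
    for (i in seq_len(nrow(m))) {
      nong <- which(m[i, ] != "-")
      if (length(nong) == 0) {
        bm[i, ] <- 0L
      } else {
        if (nong[1] > 1) bm[i, seq_len(nong[1] - 1L)] <- 0L
        last <- nong[length(nong)]
        if (last < ncol(m)) bm[i, (last + 1L):ncol(m)] <- 0L
      }
    }
  }
  bm
}

#' Read a genus alignment from aligned FASTA
#'
#' Headers are parsed with a configurable regular expression whose three
#' capture groups give genus, species epithet and specimen id. The default
#' matches the `Genus_species|specimen` convention.
#'
#' @param path Path to an aligned FASTA file.
#' @param header_pattern Regular expression with three capture groups
#'   (genus, species, specimen).
#' @return An alignment tibble; `species` holds `Genus_epithet`.
#' @export
read_alignment_fasta <- function(path,
                                 header_pattern = "^([^_]+)_([^|]+)\\|(.+)$") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  if (length(recs) == 0) abort(paste0("malformed or empty FASTA: ", path))
  headers <- vapply(recs, function(r) attr(r, "name"), character(1))
  parts <- str_match(headers, header_pattern)
  if (anyNA(parts[, 1])) {
    abort(paste0("FASTA header does not match pattern: '",
                 headers[which(is.na(parts[, 1]))[1]], "'"))
  }
  as_alignment(tibble(
    genus = parts[, 2],
    species = paste(parts[, 2], parts[, 3], sep = "_"),
    specimen_id = parts[, 4],
    sequence = unname(toupper(vapply(recs, as.character, character(1))))
  ))
}

#' Write a genus alignment to FASTA
#'
#' Headers follow the `Genus_species|specimen` convention (the genus prefix
#' already embedded in `species` is used as-is).
#'
#' @param alignment An alignment tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  alignment <- as_alignment(alignment)
  seqinr::write.fasta(as.list(alignment$sequence),
                      names = paste0(alignment$species, "|",
                                     alignment$specimen_id),
                      file.out = path, nbchar = 80)
  invisible(path)
}
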