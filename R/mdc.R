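## Molecular diagnostic characters (MDCs): "pure diagnostic sites".
##
## For a query species against all congeners, a column is diagnostic when
## (i) every non-missing query specimen carries the identical state set,
## (ii) that state set is disjoint from the union of all non-missing
## reference state sets, and (iii) at least one non-missing specimen exists
## on each side. Columns polymorphic within the query species are excluded
## by (i). Maximal runs of consecutive diagnostic columns form variation
## events; runs of length >= 2 are "multi" variations.

#' Per-specimen character states at one alignment column
#'
#' @param alignment An alignment tibble (see [as_alignment()]).
#' @param column 0-based column index.
#' @param species Species whose specimens to report.
#' @param missing Missing-data policy: `"ignore"` treats `N`/`?` as missing,
#'   `"strict"` expands them to `{A,C,G,T}`.
#' @return A tibble with `specimen_id`, `symbol`, `states` (list column of
#'   character state sets) and `missing`.
#' @export
column_states <- function(alignment, column, species,
                          missing = c("ignore", "strict")) {
  missing <- match.arg(missing)
  alignment <- as_alignment(alignment)
  ncols <- nchar(alignment$sequence[1])
  if (column < 0 || column >= ncols) {
    abort(paste0("column ", column, " outside alignment [0, ", ncols, ")"))
  }
  rows <- alignment[alignment$species == species, , drop = FALSE]
  if (nrow(rows) == 0) abort(paste0("species not in alignment: ", species))
  sym <- str_sub(rows$sequence, column + 1, column + 1)
  bad <- !(sym %in% .ALLOWED_SYMBOLS)
  if (any(bad)) {
    abort(paste0("record '", rows$specimen_id[which(bad)[1]],
                 "' has invalid symbol '", sym[which(bad)[1]],
                 "' at column ", column))
  }
  bits <- unname(.symbol_bits(missing)[sym])
  tibble(
    specimen_id = rows$specimen_id,
    symbol = sym,
    states = map(bits, .bits_to_states),
    missing = bits == 0L
  )
}

#' Classify one diagnostic site
#'
#' Given a query state set and the union of reference state sets (disjoint
#' by the diagnostic-site contract), returns the variation category:
#' `deletion` when the query state is the gap alone, `insertion` when the
#' reference union is the gap alone, `substitution` when neither side
#' contains the gap, and `mixed` when gap and nucleotide states co-occur
#' across the two sides.
#'
#' @param query_state Character vector of query states (subset of
#'   `A,C,G,T,-`).
#' @param reference_union Character vector of reference states.
#' @return One of `"substitution"`, `"deletion"`, `"insertion"`, `"mixed"`.
#' @export
classify_site <- function(query_state, reference_union) {
  qb <- .states_to_bits(query_state)
  rb <- .states_to_bits(reference_union)
  if (bitwAnd(qb, rb) != 0L) {
    abort("query and reference state sets must be disjoint")
  }
  .classify_bits(qb, rb)
}

.classify_bits <- function(qb, rb) {
  ifelse(qb == .GAP_BIT, "deletion",
         ifelse(rb == .GAP_BIT, "insertion",
                ifelse(bitwAnd(rb, .GAP_BIT) == 0L &
                         bitwAnd(qb, .GAP_BIT) == 0L,
                       "substitution", "mixed")))
}

## Core scanner on a pre-encoded bit matrix. Returns a tibble of sites.
.diagnostic_sites_bits <- function(bits, species_vec, query) {
  qrows <- which(species_vec == query)
  rrows <- which(species_vec != query)
  qb <- bits[qrows, , drop = FALSE]
  rb <- bits[rrows, , drop = FALSE]
  q_nm <- colSums(qb != 0L)
  r_nm <- colSums(rb != 0L)
  qn <- qb
  qn[qn == 0L] <- NA_integer_
  qrow_list <- lapply(seq_len(nrow(qn)), function(i) qn[i, ])
  qmax <- do.call(pmax, c(qrow_list, list(na.rm = TRUE)))
  qmin <- do.call(pmin, c(qrow_list, list(na.rm = TRUE)))
  runion <- Reduce(bitwOr, lapply(seq_len(nrow(rb)), function(i) rb[i, ]),
                   accumulate = FALSE)
  ok <- q_nm >= 1L & r_nm >= 1L
  mono <- ok & qmax == qmin
  mono[is.na(mono)] <- FALSE
  diag <- mono & bitwAnd(ifelse(mono, qmax, 0L), runion) == 0L
  cols <- which(diag)
  skipped <- sum(q_nm == 0L | r_nm == 0L)
  out <- tibble(
    column = cols - 1L,
    query_state = .bits_to_label(qmax[cols]),
    reference_state = .bits_to_label(runion[cols]),
    category = as.character(.classify_bits(qmax[cols], runion[cols]))
  )
  attr(out, "n_skipped_all_missing") <- skipped
  out
}

#' Find diagnostic sites for one species
#'
#' Scans every alignment column and reports those diagnostic for the query
#' species against all other species in the alignment (the reference set).
#'
#' @inheritParams column_states
#' @param query Query species (must be present in `alignment$species`).
#' @param mask_terminal_gaps Treat leading/trailing gap runs of each
#'   sequence as missing data (alignment end-trim artifacts).
#' @return A tibble with one row per diagnostic column: `column` (0-based),
#'   `query_state`, `reference_state` and `category`. The count of columns
#'   skipped because one side was all-missing is stored in attribute
#'   `n_skipped_all_missing`.
#' @export
find_diagnostic_sites <- function(alignment, query,
                                  missing = c("ignore", "strict"),
                                  mask_terminal_gaps = FALSE) {
  missing <- match.arg(missing)
  alignment <- as_alignment(alignment)
  if (!query %in% alignment$species) {
    abort(paste0("species not in alignment: ", query))
  }
  if (all(alignment$species == query)) {
    abort("alignment has no reference species")
  }
  bits <- .encode_bits(alignment, missing, mask_terminal_gaps)
  .diagnostic_sites_bits(bits, alignment$species, query)
}

#' Merge diagnostic sites into variation events
#'
#' Maximal runs of consecutive diagnostic columns become one event. A
#' single-column run keeps its site category; a multi-column run of uniform
#' category becomes `multi_substitution` / `multi_deletion` /
#' `multi_insertion`; heterogeneous runs, or runs containing a `mixed`
#' site, become `multi_mixed`.
#'
#' @param sites A site tibble from [find_diagnostic_sites()] (sorted by
#'   column, one species).
#' @return A tibble with `start`, `end` (0-based half-open), `length` and
#'   `event_type`.
#' @export
merge_events <- function(sites) {
  if (!all(c("column", "category") %in% names(sites))) {
    abort("`sites` must have columns `column` and `category`")
  }
  if (nrow(sites) == 0) {
    return(tibble(start = integer(), end = integer(),
                  length = integer(), event_type = character()))
  }
  if (is.unsorted(sites$column, strictly = TRUE)) {
    abort("site columns must be strictly increasing")
  }
  run <- cumsum(c(1L, diff(sites$column) != 1L))
  sites |>
    mutate(.run = run) |>
    group_by(.run) |>
    summarise(
      start = min(.data$column),
      end = max(.data$column) + 1L,
      length = dplyr::n(),
      event_type = .run_type(.data$category),
      .groups = "drop"
    ) |>
    select("start", "end", "length", "event_type")
}

.run_type <- function(categories) {
  if (length(categories) == 1) return(categories)
  u <- unique(categories)
  if (length(u) == 1 && u != "mixed") paste0("multi_", u) else "multi_mixed"
}

#' Per-species MDC profile
#'
#' Diagnostic sites, merged events and the site tally per event type for
#' one species. The MDC count is the number of diagnostic *columns* (sites,
#' not events); events are the derived layer.
#'
#' @inheritParams find_diagnostic_sites
#' @param species Query species.
#' @return An object of class `mdc_profile`: a list with `species`,
#'   `mdc_count`, `sites`, `events` and `type_tally` (named integer over
#'   the eight event types, counting sites by the event containing them).
#' @export
species_mdc_profile <- function(alignment, species,
                                missing = c("ignore", "strict"),
                                mask_terminal_gaps = FALSE) {
  sites <- find_diagnostic_sites(alignment, species, missing,
                                 mask_terminal_gaps)
  events <- merge_events(sites)
  tally <- stats::setNames(integer(length(MDC_EVENT_TYPES)), MDC_EVENT_TYPES)
  if (nrow(events) > 0) {
    agg <- tapply(events$length, factor(events$event_type,
                                        levels = MDC_EVENT_TYPES), sum)
    agg[is.na(agg)] <- 0L
    tally[] <- as.integer(agg)
  }
  structure(
    list(species = species, mdc_count = nrow(sites),
         sites = sites, events = events, type_tally = tally),
    class = "mdc_profile"
  )
}

#' @export
print.mdc_profile <- function(x, ...) {
  cat("MDC profile for", x$species, "\n")
  cat("  diagnostic sites:", x$mdc_count,
      " in", nrow(x$events), "events\n")
  nz <- x$type_tally[x$type_tally > 0]
  if (length(nz) > 0) {
    cat("  sites by event type:",
        paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-species MDC table for a genus alignment
#'
#' Runs [species_mdc_profile()] for every species and assembles the
#' per-species summary table: specimen counts, MDC site counts, event
#' counts and per-event-type site counts.
#'
#' @inheritParams find_diagnostic_sites
#' @return A tibble with one row per species: `genus`, `species`,
#'   `n_specimens`, `mdc_sites`, `n_events`, and one column per event type
#'   (site counts).
#' @export
mdc_table <- function(alignment, missing = c("ignore", "strict"),
                      mask_terminal_gaps = FALSE) {
  missing <- match.arg(missing)
  alignment <- as_alignment(alignment)
  bits <- .encode_bits(alignment, missing, mask_terminal_gaps)
  species <- unique(alignment$species)
  if (length(species) < 2) abort("alignment must contain at least 2 species")
  map_dfr(species, function(sp) {
    sites <- .diagnostic_sites_bits(bits, alignment$species, sp)
    events <- merge_events(sites)
    tally <- stats::setNames(integer(length(MDC_EVENT_TYPES)),
                             MDC_EVENT_TYPES)
    if (nrow(events) > 0) {
      agg <- tapply(events$length, factor(events$event_type,
                                          levels = MDC_EVENT_TYPES), sum)
      agg[is.na(agg)] <- 0L
      tally[] <- as.integer(agg)
    }
    bind_cols(
      tibble(genus = alignment$genus[1], species = sp,
             n_specimens = sum(alignment$species == sp),
             mdc_sites = nrow(sites), n_events = nrow(events)),
      as_tibble(as.list(tally))
    )
  })
}

#' Per-event table for a genus alignment
#'
#' BED-like event coordinates (0-based half-open alignment columns) for
#' every species in the alignment.
#'
#' @inheritParams find_diagnostic_sites
#' @return A tibble with `genus`, `species`, `start`, `end`, `length`,
#'   `event_type`.
#' @export
mdc_events_table <- function(alignment, missing = c("ignore", "strict"),
                             mask_terminal_gaps = FALSE) {
  missing <- match.arg(missing)
  alignment <- as_alignment(alignment)
  bits <- .encode_bits(alignment, missing, mask_terminal_gaps)
  map_dfr(unique(alignment$species), function(sp) {
    ev <- merge_events(.diagnostic_sites_bits(bits, alignment$species, sp))
    if (nrow(ev) == 0) return(NULL)
    bind_cols(tibble(genus = alignment$genus[1], species = sp), ev)
  })
}
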