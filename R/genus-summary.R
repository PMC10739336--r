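## Per-genus aggregation of MDC profiles into the master summary table.

#' Summarise a genus
#'
#' Aggregates a per-species MDC table (from [mdc_table()]), a mean pairwise
#' identity result and genus metadata into one summary row. The
#' per-alignment-length normalisation is the mean per-species MDC site
#' count divided by the alignment column count, times 1e4 (MDCs per 10 kb
#' of alignment).
#'
#' @param profiles Per-species tibble with at least `species`,
#'   `n_specimens` and `mdc_sites` (as produced by [mdc_table()]).
#' @param identity An `identity_result` from [mean_pairwise_identity()],
#'   or a bare percentage.
#' @param alignment_columns Number of alignment columns; taken from
#'   `profiles$alignment_columns` or required explicitly.
#' @param metadata Optional one-row data frame or list with `family`,
#'   `habitat` (one of open/woodland/mixed) and `described_species`.
#' @param min_species Study inclusion rule (default 3 species per genus).
#' @return A one-row tibble with the genus summary fields.
#' @export
summarize_genus <- function(profiles, identity, alignment_columns,
                            metadata = NULL, min_species = 3) {
  stopifnot(all(c("species", "n_specimens", "mdc_sites") %in%
                  names(profiles)))
  if (nrow(profiles) < min_species) {
    abort(paste0("genus has fewer than ", min_species,
                 " species (study inclusion rule)"))
  }
  ident <- if (inherits(identity, "identity_result")) {
    identity$mean_identity_pct
  } else {
    as.numeric(identity)
  }
  genus <- if ("genus" %in% names(profiles)) profiles$genus[1] else NA_character_
  fam <- hab <- NA_character_
  described <- NA_real_
  if (!is.null(metadata)) {
    fam <- metadata$family %||% NA_character_
    hab <- metadata$habitat %||% NA_character_
    described <- metadata$described_species %||% NA_real_
    if (!is.na(hab) && !hab %in% c("open", "woodland", "mixed")) {
      abort(paste0("unknown habitat category: ", hab))
    }
  } else {
    warn(paste0("no metadata for genus ", genus,
                "; habitat and representativeness left blank"))
  }
  n_sp <- nrow(profiles)
  mdc_mean <- mean(profiles$mdc_sites)
  tibble(
    genus = genus,
    family = as.character(fam),
    n_species_analyzed = n_sp,
    n_specimens = sum(profiles$n_specimens),
    alignment_columns = as.integer(alignment_columns),
    mdc_sum = sum(profiles$mdc_sites),
    mdc_mean = mdc_mean,
    mdc_min = min(profiles$mdc_sites),
    mdc_max = max(profiles$mdc_sites),
    mdc_per_length_e4 = mdc_mean / alignment_columns * 1e4,
    mean_identity_pct = ident,
    zero_mdc_share_pct = mean(profiles$mdc_sites == 0) * 100,
    representativeness_pct = if (is.na(described)) NA_real_ else
      n_sp / described * 100,
    habitat = as.character(hab)
  )
}

#' Bin species by MDC count
#'
#' The study's reporting bins: 0, 1-10, 11-100 and >100 MDCs per species.
#'
#' @param profiles Per-species tibble with an `mdc_sites` column.
#' @return A tibble with `bin` (ordered factor) and `n_species`.
#' @export
bin_species <- function(profiles) {
  stopifnot("mdc_sites" %in% names(profiles))
  labs <- c("0", "1-10", "11-100", ">100")
  b <- cut(profiles$mdc_sites, breaks = c(-Inf, 0, 10, 100, Inf),
           labels = labs)
  tibble(bin = factor(labs, levels = labs),
         n_species = as.integer(table(b)[labs]))
}

#' Cap specimens per species
#'
#' Species represented by more than `max_specimens` specimens are randomly
#' downsampled to the cap (seeded, reproducible); smaller species are left
#' untouched. Mirrors the cap of 50 sequences applied to very densely
#' sampled species.
#'
#' @param alignment An alignment tibble.
#' @param max_specimens Cap per species (default 50).
#' @param seed Optional integer seed for reproducible selection.
#' @return The downsampled alignment tibble (original row order kept).
#' @export
subsample_species <- function(alignment, max_specimens = 50, seed = NULL) {
  stopifnot(max_specimens >= 1)
  alignment <- as_alignment(alignment)
  if (!is.null(seed)) withr::local_seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(alignment)), alignment$species),
                        function(idx) {
    if (length(idx) <= max_specimens) idx else
      sort(sample(idx, max_specimens))
  }), use.names = FALSE)
  alignment[sort(keep), , drop = FALSE]
}
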