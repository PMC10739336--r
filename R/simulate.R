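## Synthetic genus alignments with planted, exactly recoverable ground
## truth, plus a genus-cohort generator for the statistical layer.
##
## All species share a random backbone; each planted event perturbs one
## species so that its columns become diagnostic for exactly that species:
##   substitution - the species gets an alternative base;
##   deletion     - the species is gapped;
##   insertion    - every OTHER species is gapped (alignment-space view);
##   mixed        - the species gets an alternative base while two other
##                  species are gapped and at least two keep the backbone
##                  (needs >= 5 species; with fewer, a planted "mixed"
##                  column unavoidably leaks diagnostic gap states into
##                  reference species).
## Events are required to be non-overlapping with at least one spacer
## column between any two events, across species, so recovery is exact.

#' Build and validate a genus simulation configuration
#'
#' @param n_species Number of species (>= 3).
#' @param specimens_per_species Single count or per-species vector.
#' @param backbone_length Alignment columns (default 10000, a desk-scale
#'   stand-in for ~130 kb plastome alignments).
#' @param planted Tibble of planted events: `species` (index or name
#'   `sp<i>`), `start` (0-based), `length`, `kind` (substitution /
#'   deletion / insertion / mixed).
#' @param polymorphism_rate Per-cell probability of a specimen-private
#'   base change (within-species polymorphism).
#' @param missing_rate Per-specimen probability of one injected N-run
#'   (geometric length, mean 50, emulating assembly gaps).
#' @param twin_species Optional 2-column matrix/tibble of species index
#'   pairs forced to identical sequence sets (zero-MDC twins). Twin
#'   members cannot carry planted events.
#' @param genus Genus name used in labels.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `genus_sim_config` list.
#' @export
genus_sim_config <- function(n_species, specimens_per_species = 2,
                             backbone_length = 10000, planted = NULL,
                             polymorphism_rate = 0, missing_rate = 0,
                             twin_species = NULL, genus = "Simulatia",
                             seed = 1) {
  if (n_species < 3) abort("n_species must be >= 3")
  if (polymorphism_rate < 0 || polymorphism_rate > 1 ||
      missing_rate < 0 || missing_rate > 1) {
    abort("rates must be in [0, 1]")
  }
  spn <- rep(specimens_per_species, length.out = n_species)
  if (any(spn < 1)) abort("each species needs >= 1 specimen")
  planted <- if (is.null(planted)) {
    tibble(species = character(), start = integer(),
           length = integer(), kind = character())
  } else {
    as_tibble(planted)
  }
  if (nrow(planted) > 0) {
    if (is.numeric(planted$species)) {
      planted$species <- paste0("sp", planted$species)
    }
    stopifnot(all(c("species", "start", "length", "kind") %in%
                    names(planted)))
    if (!all(planted$kind %in% c("substitution", "deletion", "insertion",
                                 "mixed"))) {
      abort("unknown planted event kind")
    }
    if (any(planted$length < 1) || any(planted$start < 0) ||
        any(planted$start + planted$length > backbone_length)) {
      abort("planted event outside sequence bounds")
    }
    if (any(planted$kind == "mixed") && n_species < 5) {
      abort("mixed events need n_species >= 5 for exact truth")
    }
    ord <- order(planted$start)
    p <- planted[ord, ]
    if (nrow(p) > 1 &&
        any(p$start[-1] <= p$start[-nrow(p)] + p$length[-nrow(p)])) {
      abort("planted events must be non-overlapping with >= 1 spacer column")
    }
    spp <- paste0("sp", seq_len(n_species))
    if (!all(planted$species %in% spp)) {
      abort("planted event references an unknown species")
    }
  }
  twins <- NULL
  if (!is.null(twin_species)) {
    twins <- as.matrix(twin_species)
    storage.mode(twins) <- "integer"
    if (ncol(twins) != 2 || any(twins < 1) || any(twins > n_species)) {
      abort("twin_species must be a 2-column matrix of species indices")
    }
    twin_names <- paste0("sp", as.vector(twins))
    if (any(planted$species %in% twin_names)) {
      abort("twin species cannot carry planted events")
    }
    if (any(planted$kind == "mixed") &&
        n_species - 1L - length(twin_names) < 2) {
      abort("mixed events need >= 2 non-twin reference species to gap")
    }
  }
  structure(
    list(n_species = as.integer(n_species),
         specimens_per_species = as.integer(spn),
         backbone_length = as.integer(backbone_length),
         planted = planted,
         polymorphism_rate = polymorphism_rate,
         missing_rate = missing_rate,
         twin_species = twins,
         genus = genus,
         seed = as.integer(seed)),
    class = "genus_sim_config"
  )
}

#' Generate a synthetic genus alignment with planted truth
#'
#' @param config A [genus_sim_config()].
#' @return A list with `alignment` (tibble), `truth` (the planted event
#'   tibble with species names), `polymorphism` (specimen-private changes:
#'   `specimen_id`, `column`, `from`, `to`) and `missing_runs`
#'   (`specimen_id`, `start`, `length`).
#' @export
generate_genus <- function(config) {
  stopifnot(inherits(config, "genus_sim_config"))
  withr::local_seed(config$seed)
  L <- config$backbone_length
  nsp <- config$n_species
  spn <- config$specimens_per_species
  species <- paste0("sp", seq_len(nsp))
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, L, replace = TRUE)
  sp_of_row <- rep(species, spn)
  n_rows <- length(sp_of_row)
  m <- matrix(rep(backbone, each = n_rows), nrow = n_rows)

  planted <- config$planted
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      ev <- planted[i, ]
      cols <- seq.int(ev$start + 1L, ev$start + ev$length)
      focal <- sp_of_row == ev$species
      others <- which(!focal)
      other_sp <- setdiff(species, ev$species)
      if (ev$kind == "substitution") {
        alt <- vapply(cols, function(cc)
          sample(setdiff(bases, backbone[cc]), 1), character(1))
        m[focal, cols] <- rep(alt, each = sum(focal))
      } else if (ev$kind == "deletion") {
        m[focal, cols] <- "-"
      } else if (ev$kind == "insertion") {
        m[!focal, cols] <- "-"
      } else {  # mixed
        alt <- vapply(cols, function(cc)
          sample(setdiff(bases, backbone[cc]), 1), character(1))
        m[focal, cols] <- rep(alt, each = sum(focal))
        ## gap only non-twin references: the twin copy applied later would
        ## otherwise rewrite gap patterns and leak diagnostic states
        twin_names <- if (is.null(config$twin_species)) character() else
          paste0("sp", as.vector(config$twin_species))
        gapped <- sample(setdiff(other_sp, twin_names), 2)
        m[sp_of_row %in% gapped, cols] <- "-"
      }
    }
  }

  ## specimen-private polymorphism (nucleotide cells only)
  poly <- tibble(specimen_id = character(), column = integer(),
                 from = character(), to = character())
  if (config$polymorphism_rate > 0) {
    hits <- which(matrix(stats::runif(n_rows * L), n_rows) <
                    config$polymorphism_rate & m %in% bases, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      from <- m[hits]
      to <- vapply(from, function(b) sample(setdiff(bases, b), 1),
                   character(1))
      m[hits] <- to
      poly <- tibble(row = hits[, 1], column = hits[, 2] - 1L,
                     from = from, to = to)
    }
  }

  ## N-run injection (assembly gaps)
  miss <- tibble(specimen_id = character(), start = integer(),
                 length = integer())
  if (config$missing_rate > 0) {
    miss_rows <- list()
    for (r in seq_len(n_rows)) {
      if (stats::runif(1) < config$missing_rate) {
        len <- min(stats::rgeom(1, 1 / 50) + 1L, L)
        st <- sample.int(L - len + 1L, 1) - 1L
        m[r, (st + 1L):(st + len)] <- "N"
        miss_rows[[length(miss_rows) + 1]] <-
          tibble(row = r, start = st, length = len)
      }
    }
    if (length(miss_rows) > 0) miss <- bind_rows(miss_rows)
  }

  ## twins copy each other exactly (after noise, so identity is exact)
  if (!is.null(config$twin_species)) {
    for (i in seq_len(nrow(config$twin_species))) {
      a <- config$twin_species[i, 1]; b <- config$twin_species[i, 2]
      rows_a <- which(sp_of_row == species[a])
      rows_b <- which(sp_of_row == species[b])
      m[rows_b, ] <- m[rep(rows_a, length.out = length(rows_b)), ]
    }
  }

  specimen_id <- paste0(sp_of_row, "-", stats::ave(seq_len(n_rows),
                                                   sp_of_row,
                                                   FUN = seq_along))
  full_species <- paste0(config$genus, "_", sp_of_row)
  aln <- tibble(
    genus = config$genus,
    species = full_species,
    specimen_id = specimen_id,
    sequence = apply(m, 1, paste, collapse = "")
  )
  truth <- planted
  if (nrow(truth) > 0) {
    truth$species <- paste0(config$genus, "_", truth$species)
  }
  if (nrow(poly) > 0 && "row" %in% names(poly)) {
    poly$specimen_id <- specimen_id[poly$row]
    poly <- poly[, c("specimen_id", "column", "from", "to")]
  }
  if (nrow(miss) > 0 && "row" %in% names(miss)) {
    miss$specimen_id <- specimen_id[miss$row]
    miss <- miss[, c("specimen_id", "start", "length")]
  }
  list(alignment = as_alignment(aln), truth = truth,
       polymorphism = poly, missing_runs = miss)
}

#' Expected event type of a planted event
#'
#' Maps a planted event (kind, length) to the event type the scanner
#' reports: single-column events keep their kind; multi-column events gain
#' the `multi_` prefix (`multi_mixed` for mixed).
#'
#' @param kind Planted kind.
#' @param length Event length in columns.
#' @return Event type string.
#' @export
planted_event_type <- function(kind, length) {
  ifelse(length == 1, kind, paste0("multi_", kind))
}

#' Generate a genus-cohort summary table from a known covariate model
#'
#' Per-genus covariates (species count, specimen count, mean identity) are
#' drawn from study-like ranges and MDC sums are drawn from a Poisson
#' log-link model on the log10-scaled predictors, so that
#' [poisson_glm()] recovery can be checked against known truth.
#'
#' @param n_genera Number of genera (>= 10).
#' @param intercept Intercept on the log-mean scale (default 8.0; mean MDC
#'   sums in the low thousands, matching whole-plastome magnitudes).
#' @param slope_species Slope on log10(species count).
#' @param slope_identity Slope on log10(mean identity).
#' @param seed Integer seed.
#' @return A list with `table` (tibble: genus, n_species, n_specimens,
#'   mean_identity_pct, mdc_sum) and `truth` (the model parameters).
#' @importFrom stats rpois runif
#' @export
generate_cohort <- function(n_genera = 96, intercept = 8,
                            slope_species = 0.028, slope_identity = 0,
                            seed = 1) {
  if (n_genera < 10) abort("n_genera must be >= 10")
  withr::local_seed(seed)
  n_species <- sample(3:41, n_genera, replace = TRUE)
  n_specimens <- n_species + stats::rpois(n_genera, lambda = 2 * n_species)
  identity <- runif(n_genera, 96, 100)
  mu <- exp(intercept + slope_species * log10(n_species) +
              slope_identity * log10(identity))
  tab <- tibble(
    genus = sprintf("genus%02d", seq_len(n_genera)),
    n_species = n_species,
    n_specimens = n_specimens,
    mean_identity_pct = identity,
    mdc_sum = rpois(n_genera, mu)
  )
  list(table = tab,
       truth = list(intercept = intercept,
                    slope_species = slope_species,
                    slope_identity = slope_identity))
}
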