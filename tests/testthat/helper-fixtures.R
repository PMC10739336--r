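## Fixture builders and independent oracles used across the suite.
## Everything here is deliberately naive and self-contained: the oracles
## re-derive expectations from first principles and never call the
## package's scanning internals.

`%||%` <- function(x, y) if (is.null(x)) y else x

BASES <- c("A", "C", "G", "T")
.CMP <- c(A = "T", C = "G", G = "C", T = "A")

## Quick inline alignment from per-species specimen sequences.
## seqs: named list species -> character vector of aligned sequences.
make_aln <- function(seqs, genus = "Toy") {
  tibble::tibble(
    genus = genus,
    species = rep(names(seqs), lengths(seqs)),
    specimen_id = unlist(lapply(names(seqs), function(sp) {
      paste0(sp, "-", seq_along(seqs[[sp]]))
    }), use.names = FALSE),
    sequence = unlist(seqs, use.names = FALSE)
  )
}

## ---- inverted-repeat fixtures -------------------------------------------

## A toy quadripartite genome LSC + R + SSC + revcomp(R) with *sealed*
## boundaries: the bases flanking each arm (in circular space: the SSC ends
## inside, the LSC ends outside) are forced non-complementary, so the
## planted arm length is the unique answer a detector can return.
make_ir_toy <- function(lsc_len = 2000, ir_len = 400, ssc_len = 800,
                        seed = 1) {
  set.seed(seed)
  lsc <- sample(BASES, lsc_len, TRUE)
  R <- sample(BASES, ir_len, TRUE)
  ssc <- sample(BASES, ssc_len, TRUE)
  if (ssc[ssc_len] == .CMP[ssc[1]]) {
    ssc[ssc_len] <- setdiff(BASES, c(ssc[ssc_len], .CMP[ssc[1]]))[1]
  }
  if (lsc[lsc_len] == .CMP[lsc[1]]) {
    lsc[lsc_len] <- setdiff(BASES, c(lsc[lsc_len], .CMP[lsc[1]]))[1]
  }
  Rs <- paste(R, collapse = "")
  list(seq = paste0(paste(lsc, collapse = ""), Rs,
                    paste(ssc, collapse = ""), mdcscan::revcomp(Rs)),
       lsc_len = lsc_len, ir_len = ir_len, ssc_len = ssc_len)
}

rotate_string <- function(s, r) {
  L <- nchar(s)
  r <- r %% L
  if (r == 0) return(s)
  paste0(substr(s, r + 1, L), substr(s, 1, r))
}

## Brute-force inverted-repeat presence scan: walks every anti-diagonal of
## the sequence against its complement and slides a window of exactly
## `min_len` columns, allowing floor(max_mm * min_len) mismatches. By an
## averaging argument any qualifying repeat of length >= min_len contains
## such a window, so this certifies absence.
bf_has_inverted_repeat <- function(s, min_len, max_mm = 0.02) {
  x <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  cx <- unname(.CMP[x])
  L <- length(x)
  budget <- floor(max_mm * min_len)
  for (D in seq(2L, 2L * L)) {
    lo <- max(1L, D - L)
    hi <- (D - 1L) %/% 2L
    if (hi - lo + 1L < min_len) next
    i <- seq.int(lo, hi)
    mism <- as.integer(x[i] != cx[D - i])
    cs <- cumsum(mism)
    n <- length(mism)
    w <- min_len
    windows <- cs[w:n] - c(0L, cs[seq_len(n - w)])
    if (any(windows <= budget)) return(TRUE)
  }
  FALSE
}

## ---- diagnostic-site oracle ---------------------------------------------

.ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  `-` = "-"
)
.STATE_ORDER <- c("A", "C", "G", "T", "-")

## Literal per-column reimplementation of the pure-diagnostic-site rule:
## every non-missing query specimen carries the identical state set, and
## that set shares no state with any non-missing reference specimen.
oracle_diagnostic_sites <- function(aln, query, missing = "ignore") {
  rows <- strsplit(toupper(aln$sequence), "", fixed = TRUE)
  is_q <- aln$species == query
  ncols <- length(rows[[1]])
  out <- list()
  states_of <- function(sym) {
    if (sym %in% c("N", "?")) {
      if (missing == "ignore") NULL else BASES
    } else {
      .ORACLE_IUPAC[[sym]]
    }
  }
  label <- function(states) {
    paste(.STATE_ORDER[.STATE_ORDER %in% states], collapse = "/")
  }
  for (col in seq_len(ncols)) {
    qs <- lapply(rows[is_q], `[[`, col)
    rs <- lapply(rows[!is_q], `[[`, col)
    qsets <- Filter(Negate(is.null), lapply(qs, states_of))
    rsets <- Filter(Negate(is.null), lapply(rs, states_of))
    if (length(qsets) == 0 || length(rsets) == 0) next
    keys <- vapply(qsets, function(s) paste(sort(s), collapse = ""),
                   character(1))
    if (length(unique(keys)) != 1) next      # query-polymorphic
    qset <- qsets[[1]]
    runi <- unique(unlist(rsets))
    if (any(qset %in% runi)) next            # shared state
    category <- if (identical(qset, "-") && !("-" %in% runi)) {
      "deletion"
    } else if (identical(sort(runi), "-")) {
      "insertion"
    } else if (!("-" %in% qset) && !("-" %in% runi)) {
      "substitution"
    } else {
      "mixed"
    }
    out[[length(out) + 1]] <- tibble::tibble(
      column = col - 1L,
      query_state = label(qset),
      reference_state = label(runi),
      category = category
    )
  }
  if (length(out) == 0) {
    tibble::tibble(column = integer(), query_state = character(),
                   reference_state = character(), category = character())
  } else {
    dplyr::bind_rows(out)
  }
}

## Random small alignment with species-level signal, specimen noise,
## ambiguity codes, gaps and missing symbols.
random_alignment <- function(n_species = NULL, n_specimens = NULL,
                             n_cols = NULL) {
  n_species <- n_species %||% sample(2:6, 1)
  n_cols <- n_cols %||% sample(20:200, 1)
  syms <- c(BASES, "R", "Y", "W", "K", "-", "N", "?")
  wts <- c(rep(10, 4), 1, 1, 1, 1, 4, 2, 1)
  backbone <- sample(syms, n_cols, TRUE, prob = wts)
  seqs <- list()
  for (sp in seq_len(n_species)) {
    nspec <- n_specimens %||% sample(1:4, 1)
    spvec <- backbone
    mut <- runif(n_cols) < 0.15
    spvec[mut] <- sample(syms, sum(mut), TRUE, prob = wts)
    seqs[[paste0("sp", sp)]] <- vapply(seq_len(nspec), function(k) {
      v <- spvec
      noise <- runif(n_cols) < 0.04
      v[noise] <- sample(syms, sum(noise), TRUE, prob = wts)
      paste(v, collapse = "")
    }, character(1))
  }
  make_aln(seqs, genus = "Rnd")
}

## ---- planted-truth configs ----------------------------------------------

## Random planted events: non-overlapping with >= 1 spacer, mixed kind only
## when n_species >= 5, never on twin species.
random_planted <- function(n_events, L, n_species, twin_idx = integer()) {
  kinds <- c("substitution", "deletion", "insertion")
  if (n_species >= 5) kinds <- c(kinds, "mixed")
  lens <- sample(1:5, n_events, TRUE)
  slack <- L - sum(lens) - (n_events - 1)
  stopifnot(slack > 0)
  gaps <- as.vector(stats::rmultinom(1, slack, rep(1, n_events + 1)))
  starts <- integer(n_events)
  pos <- gaps[1]
  for (i in seq_len(n_events)) {
    starts[i] <- pos
    pos <- pos + lens[i] + 1 + gaps[i + 1]
  }
  eligible <- setdiff(seq_len(n_species), twin_idx)
  tibble::tibble(
    species = sample(eligible, n_events, TRUE),
    start = starts,
    length = lens,
    kind = sample(kinds, n_events, TRUE)
  )
}

random_sim_config <- function(seed, polymorphism_rate = 0,
                              missing_rate = 0, twins = FALSE) {
  set.seed(seed)
  n_species <- sample(3:6, 1)
  twin_idx <- integer()
  twin_mat <- NULL
  if (twins && n_species >= 4) {
    twin_mat <- matrix(sample(n_species, 2), ncol = 2)
    twin_idx <- as.vector(twin_mat)
  }
  L <- sample(300:800, 1)
  planted <- random_planted(sample(3:8, 1), L, n_species, twin_idx)
  genus_sim_config(
    n_species = n_species,
    specimens_per_species = sample(1:3, n_species, TRUE),
    backbone_length = L,
    planted = planted,
    polymorphism_rate = polymorphism_rate,
    missing_rate = missing_rate,
    twin_species = twin_mat,
    seed = seed
  )
}

## Expected per-species site tally from a planted truth table (rates 0).
planted_site_tally <- function(truth, species) {
  ev <- truth[truth$species == species, , drop = FALSE]
  tally <- stats::setNames(integer(8), mdcscan::MDC_EVENT_TYPES)
  if (nrow(ev) > 0) {
    types <- mdcscan::planted_event_type(ev$kind, ev$length)
    agg <- tapply(ev$length, factor(types, levels = names(tally)), sum)
    agg[is.na(agg)] <- 0
    tally[] <- as.integer(agg)
  }
  tally
}

## ---- IRLS oracle for the Poisson GLM ------------------------------------

irls_poisson <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- c(log(mean(y) + 0.1), rep(0, ncol(X) - 1))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    W <- mu
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  drop(beta)
}

## Plain data-frame view of a site tibble (drops bookkeeping attributes).
sites_df <- function(x) {
  out <- as.data.frame(x)
  attr(out, "n_skipped_all_missing") <- NULL
  out
}
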