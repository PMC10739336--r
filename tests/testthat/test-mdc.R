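test_that("pure diagnostic sites follow the query-vs-reference rule", {
  ## one substitution column, fixed states on both sides
  aln <- make_aln(list(q = c("ACGT", "ACGT"), r = c("ACCT", "ACTT")))
  sites <- find_diagnostic_sites(aln, "q")
  expect_equal(sites$column, 2L)
  expect_equal(sites$query_state, "G")
  expect_equal(sites$reference_state, "C/T")
  expect_equal(sites$category, "substitution")

  ## query-polymorphic columns are excluded
  aln2 <- make_aln(list(q = c("ACGT", "ACTT"), r = "ACCT"))
  expect_equal(nrow(find_diagnostic_sites(aln2, "q")), 0L)

  ## a state shared with any reference kills the site
  aln3 <- make_aln(list(q = "ACGT", r = c("ACGT", "ACGA")))
  expect_equal(nrow(find_diagnostic_sites(aln3, "q")), 0L)

  ## gap in the query against residues is a deletion site
  aln4 <- make_aln(list(q = "A-GT", r = "ACGT"))
  s4 <- find_diagnostic_sites(aln4, "q")
  expect_equal(s4$column, 1L)
  expect_equal(s4$query_state, "-")
  expect_equal(s4$category, "deletion")

  expect_error(find_diagnostic_sites(aln, "nope"), "not in alignment")
})

test_that("ambiguity codes compare as state sets", {
  ## {R,R} is monomorphic; disjointness is set-based
  aln <- make_aln(list(q = c("R", "R"), r = c("C", "T")))
  s <- find_diagnostic_sites(aln, "q")
  expect_equal(s$query_state, "A/G")
  expect_equal(s$category, "substitution")
  ## {R,A} is polymorphic even though A is inside R
  aln2 <- make_aln(list(q = c("R", "A"), r = "C"))
  expect_equal(nrow(find_diagnostic_sites(aln2, "q")), 0L)
  ## overlapping sets are not diagnostic: R = {A,G} meets A
  aln3 <- make_aln(list(q = "R", r = "A"))
  expect_equal(nrow(find_diagnostic_sites(aln3, "q")), 0L)
})

test_that("missing-data policies behave as declared", {
  ## ignore: an all-N reference specimen contributes nothing
  aln <- make_aln(list(q = c("AAAA", "AAAA"), r = "CCCC", junk = "NNNN"))
  s <- find_diagnostic_sites(aln, "q", missing = "ignore")
  expect_equal(nrow(s), 4L)
  ## strict: N expands to {A,C,G,T} and erases every site
  s2 <- find_diagnostic_sites(aln, "q", missing = "strict")
  expect_equal(nrow(s2), 0L)
  ## all-missing query columns are skipped, not errors
  aln3 <- make_aln(list(q = "NNAA", r = "CCCC"))
  s3 <- find_diagnostic_sites(aln3, "q")
  expect_equal(s3$column, c(2L, 3L))
  expect_equal(attr(s3, "n_skipped_all_missing"), 2L)
})

test_that("terminal gap masking turns end-trim gaps into missing data", {
  aln <- make_aln(list(q = "--GTA", r = "CCTTA"))
  ## default: leading gaps are ordinary states -> deletion sites
  expect_equal(find_diagnostic_sites(aln, "q")$category,
               c("deletion", "deletion", "substitution"))
  masked <- find_diagnostic_sites(aln, "q", mask_terminal_gaps = TRUE)
  expect_equal(masked$column, 2L)
})

test_that("site classification covers the four categories", {
  expect_equal(classify_site("A", c("C", "T")), "substitution")
  expect_equal(classify_site("-", c("A", "C")), "deletion")
  expect_equal(classify_site("G", "-"), "insertion")
  expect_equal(classify_site("T", c("C", "-")), "mixed")
  expect_error(classify_site("A", c("A", "C")), "disjoint")
})

test_that("events merge maximal runs and classify multi types", {
  del3 <- tibble::tibble(column = c(5L, 6L, 7L),
                         category = rep("deletion", 3))
  ev <- merge_events(del3)
  expect_equal(ev$start, 5L)
  expect_equal(ev$end, 8L)
  expect_equal(ev$length, 3L)
  expect_equal(ev$event_type, "multi_deletion")

  ## non-adjacent columns stay separate single events
  sub2 <- tibble::tibble(column = c(5L, 7L),
                         category = rep("substitution", 2))
  ev2 <- merge_events(sub2)
  expect_equal(ev2$event_type, rep("substitution", 2))

  ## substitution adjacent to deletion -> one multi_mixed event
  mix <- tibble::tibble(column = c(5L, 6L),
                        category = c("substitution", "deletion"))
  expect_equal(merge_events(mix)$event_type, "multi_mixed")

  ## a mixed site inside a run forces multi_mixed too
  mix2 <- tibble::tibble(column = c(5L, 6L),
                         category = c("mixed", "mixed"))
  expect_equal(merge_events(mix2)$event_type, "multi_mixed")

  ## single mixed column keeps its own category
  expect_equal(merge_events(tibble::tibble(column = 3L,
                                           category = "mixed"))$event_type,
               "mixed")

  expect_equal(nrow(merge_events(del3[0, ])), 0L)
  expect_error(merge_events(tibble::tibble(column = c(5L, 5L),
                                           category = rep("deletion", 2))),
               "strictly increasing")
})

test_that("profiles count sites, not events, and tally by event type", {
  aln <- make_aln(list(q = "ACGTAAAA", twin1 = "ACCTAAAA",
                       twin2 = "ACCTAAAA"))
  ## twin1/twin2 identical: no MDCs possible
  expect_equal(species_mdc_profile(aln, "twin1")$mdc_count, 0L)
  p <- species_mdc_profile(aln, "q")
  expect_equal(p$mdc_count, 1L)
  expect_equal(unname(p$type_tally["substitution"]), 1L)

  ## single specimen vs single specimen differing everywhere
  aln2 <- make_aln(list(a = "AAAA", b = "CCCC", c = "CCCC"))
  expect_equal(species_mdc_profile(aln2, "a")$mdc_count, 4L)
})

test_that("mdc_table aggregates per species with event-type site counts", {
  cfg <- genus_sim_config(3, 2, 500, planted = tibble::tibble(
    species = c(1, 1, 1, 1, 2), start = c(10, 50, 100, 200, 300),
    length = c(1, 1, 1, 4, 2), kind = c("substitution", "substitution",
                                        "substitution", "deletion",
                                        "insertion")), seed = 11)
  g <- generate_genus(cfg)
  tab <- mdc_table(g$alignment)
  sp1 <- tab[tab$species == "Simulatia_sp1", ]
  expect_equal(sp1$mdc_sites, 7L)
  expect_equal(sp1$n_events, 4L)
  expect_equal(sp1$substitution, 3L)
  expect_equal(sp1$multi_deletion, 4L)
  sp2 <- tab[tab$species == "Simulatia_sp2", ]
  expect_equal(sp2$multi_insertion, 2L)
  expect_equal(tab[tab$species == "Simulatia_sp3", ]$mdc_sites, 0L)
  ev <- mdc_events_table(g$alignment)
  expect_equal(sum(ev$length), 9L)
})

test_that("scanner matches the literal per-column oracle on random data", {
  set.seed(401)
  for (i in 1:40) {
    aln <- random_alignment()
    for (sp in unique(aln$species)) {
      got <- find_diagnostic_sites(aln, sp)
      want <- oracle_diagnostic_sites(aln, sp)
      expect_equal(sites_df(got), sites_df(want))
    }
  }
})

test_that("scanner is invariant to specimen and species permutations", {
  set.seed(77)
  for (i in 1:10) {
    aln <- random_alignment(n_species = 4)
    perm <- aln[sample(nrow(aln)), ]
    for (sp in unique(aln$species)) {
      expect_equal(sites_df(find_diagnostic_sites(aln, sp)),
                   sites_df(find_diagnostic_sites(perm, sp)))
    }
  }
})

test_that("adding reference specimens never adds diagnostic sites", {
  set.seed(88)
  for (i in 1:10) {
    aln <- random_alignment(n_species = 4)
    sp <- unique(aln$species)[1]
    base_cols <- find_diagnostic_sites(aln, sp)$column
    extra <- aln[aln$species != sp, ][1, ]
    extra$specimen_id <- "extra-1"
    ch <- strsplit(extra$sequence, "")[[1]]
    flip <- sample(length(ch), max(1, length(ch) %/% 10))
    ch[flip] <- sample(c(BASES, "-"), length(flip), TRUE)
    extra$sequence <- paste(ch, collapse = "")
    grown <- find_diagnostic_sites(dplyr::bind_rows(aln, extra), sp)$column
    expect_true(all(grown %in% base_cols))
  }
})

test_that("duplicating a query specimen leaves the profile unchanged", {
  set.seed(99)
  aln <- random_alignment(n_species = 4)
  sp <- unique(aln$species)[2]
  dup <- aln[aln$species == sp, ][1, ]
  dup$specimen_id <- "dup-1"
  before <- species_mdc_profile(aln, sp)
  after <- species_mdc_profile(dplyr::bind_rows(aln, dup), sp)
  expect_equal(before$mdc_count, after$mdc_count)
  expect_equal(as.data.frame(before$events), as.data.frame(after$events))
})

test_that("two monomorphic species mirror each other's diagnostic columns", {
  set.seed(123)
  for (i in 1:5) {
    s1 <- paste(sample(BASES, 60, TRUE), collapse = "")
    ch <- strsplit(s1, "")[[1]]
    flip <- sample(60, 8)
    ch[flip] <- vapply(ch[flip], function(b) sample(setdiff(BASES, b), 1), "")
    s2 <- paste(ch, collapse = "")
    aln <- make_aln(list(a = c(s1, s1), b = c(s2, s2)))
    expect_equal(find_diagnostic_sites(aln, "a")$column,
                 find_diagnostic_sites(aln, "b")$column)
  }
})
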