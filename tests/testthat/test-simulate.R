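test_that("configs are validated before generation", {
  expect_error(genus_sim_config(2), "n_species")
  expect_error(genus_sim_config(3, polymorphism_rate = 1.2), "rates")
  overlap <- tibble::tibble(species = c(1, 2), start = c(10, 12),
                            length = c(3, 2), kind = "substitution")
  expect_error(genus_sim_config(3, planted = overlap), "non-overlapping")
  adjacent <- tibble::tibble(species = c(1, 2), start = c(10, 13),
                             length = c(3, 2), kind = "substitution")
  expect_error(genus_sim_config(3, planted = adjacent), "non-overlapping")
  oob <- tibble::tibble(species = 1, start = 990, length = 20,
                        kind = "deletion")
  expect_error(genus_sim_config(3, backbone_length = 1000, planted = oob),
               "bounds")
  mixed <- tibble::tibble(species = 1, start = 10, length = 1,
                          kind = "mixed")
  expect_error(genus_sim_config(4, planted = mixed), "n_species >= 5")
  expect_silent(genus_sim_config(5, planted = mixed))
  twinev <- tibble::tibble(species = 2, start = 10, length = 1,
                           kind = "substitution")
  expect_error(genus_sim_config(4, planted = twinev,
                                twin_species = cbind(2, 3)),
               "twin species")
})

test_that("planted events are recovered exactly at zero noise", {
  cfg <- genus_sim_config(3, 2, 1000, planted = tibble::tibble(
    species = c(1, 1, 1, 1), start = c(10, 50, 100, 200),
    length = c(1, 1, 1, 4),
    kind = c("substitution", "substitution", "substitution", "deletion")),
    seed = 42)
  g <- generate_genus(cfg)
  p1 <- species_mdc_profile(g$alignment, "Simulatia_sp1")
  expect_equal(p1$mdc_count, 7L)
  expect_equal(p1$events$start, c(10L, 50L, 100L, 200L))
  expect_equal(p1$events$event_type,
               c("substitution", "substitution", "substitution",
                 "multi_deletion"))
  expect_equal(species_mdc_profile(g$alignment, "Simulatia_sp2")$mdc_count, 0L)
  expect_equal(species_mdc_profile(g$alignment, "Simulatia_sp3")$mdc_count, 0L)
})

test_that("each planted kind maps to its event type, mixed included", {
  cfg <- genus_sim_config(5, 2, 600, planted = tibble::tibble(
    species = c(1, 1, 1, 1, 1, 1, 1, 1),
    start = c(10, 30, 50, 70, 90, 110, 140, 170),
    length = c(1, 1, 1, 1, 2, 3, 2, 2),
    kind = c("substitution", "deletion", "insertion", "mixed",
             "substitution", "deletion", "insertion", "mixed")), seed = 8)
  g <- generate_genus(cfg)
  p <- species_mdc_profile(g$alignment, "Simulatia_sp1")
  expect_equal(p$mdc_count, 13L)
  expect_equal(sort(p$events$event_type),
               sort(c("substitution", "deletion", "insertion", "mixed",
                      "multi_substitution", "multi_deletion",
                      "multi_insertion", "multi_mixed")))
  ## no leakage into reference species
  for (sp in paste0("Simulatia_sp", 2:5)) {
    expect_equal(species_mdc_profile(g$alignment, sp)$mdc_count, 0L)
  }
})

test_that("twin species never acquire diagnostic characters", {
  cfg <- genus_sim_config(
    4, 2, 800,
    planted = tibble::tibble(species = 1, start = c(20, 60),
                             length = c(2, 1), kind = "substitution"),
    twin_species = cbind(2, 3), seed = 13)
  g <- generate_genus(cfg)
  a2 <- g$alignment[g$alignment$species == "Simulatia_sp2", ]
  a3 <- g$alignment[g$alignment$species == "Simulatia_sp3", ]
  expect_equal(a2$sequence, a3$sequence)
  expect_equal(species_mdc_profile(g$alignment, "Simulatia_sp2")$mdc_count, 0L)
  expect_equal(species_mdc_profile(g$alignment, "Simulatia_sp3")$mdc_count, 0L)
  expect_equal(species_mdc_profile(g$alignment, "Simulatia_sp1")$mdc_count, 3L)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- random_sim_config(555, polymorphism_rate = 0.01,
                           missing_rate = 0.3)
  g1 <- generate_genus(cfg)
  g2 <- generate_genus(cfg)
  expect_identical(g1$alignment, g2$alignment)
  expect_identical(g1$polymorphism, g2$polymorphism)
  g3 <- generate_genus(random_sim_config(556, polymorphism_rate = 0.01))
  expect_false(identical(g1$alignment$sequence, g3$alignment$sequence))
})

test_that("polymorphism hitting a planted column masks that site", {
  cfg <- genus_sim_config(3, 2, 200, planted = tibble::tibble(
    species = 1, start = c(50, 120), length = 1, kind = "substitution"),
    seed = 3)
  g <- generate_genus(cfg)
  ## manually flip one sp1 specimen at the first planted column
  aln <- g$alignment
  i <- which(aln$species == "Simulatia_sp1")[1]
  ch <- strsplit(aln$sequence[i], "")[[1]]
  ch[51] <- setdiff(BASES, ch[51])[1]
  aln$sequence[i] <- paste(ch, collapse = "")
  p <- species_mdc_profile(aln, "Simulatia_sp1")
  expect_equal(p$mdc_count, 1L)
  expect_equal(p$sites$column, 120L)
})

test_that("missing runs are injected as recorded N blocks", {
  cfg <- random_sim_config(777, missing_rate = 1)
  g <- generate_genus(cfg)
  expect_gt(nrow(g$missing_runs), 0)
  for (i in seq_len(nrow(g$missing_runs))) {
    run <- g$missing_runs[i, ]
    seqrow <- g$alignment$sequence[g$alignment$specimen_id ==
                                     run$specimen_id]
    block <- substr(seqrow, run$start + 1, run$start + run$length)
    expect_equal(block, strrep("N", run$length))
  }
})

test_that("cohort generation is deterministic and recoverable", {
  c1 <- generate_cohort(n_genera = 96, seed = 10)
  c2 <- generate_cohort(n_genera = 96, seed = 10)
  expect_identical(c1$table, c2$table)
  expect_equal(c1$truth$slope_species, 0.028)
  fit <- poisson_glm(c1$table, mdc_sum, n_species)
  expect_lt(abs(fit$slope - 0.028), 3 * fit$slope_se)
  expect_error(generate_cohort(5), "n_genera")
})
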