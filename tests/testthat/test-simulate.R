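test_that("catalog simulation is deterministic and honors planted truth sizes", {
  cfg <- catalog_sim_config(n_proteins = 80, cell_types = c("A", "B", "C"),
                            n_core = 5, k_core = 2, frac_exclusive = 0.05,
                            seed = 11)
  c1 <- simulate_catalog(cfg)
  c2 <- simulate_catalog(cfg)
  expect_identical(c1$abundance, c2$abundance)
  expect_identical(c1$truth$membership, c2$truth$membership)

  n_ex <- round(0.05 * 80)
  expect_true(all(lengths(c1$truth$exclusive) == n_ex))
  expect_length(c1$truth$core, 5)
  core_counts <- table(c1$truth$membership$protein[
    c1$truth$membership$protein %in% c1$truth$core])
  expect_true(all(core_counts >= 2))
  # planted exclusive sets are pairwise disjoint
  ex <- unlist(c1$truth$exclusive)
  expect_equal(anyDuplicated(ex), 0)
  # every planted identifier exists in the generated table
  expect_true(all(c1$truth$membership$protein %in% c1$abundance$protein))
})

test_that("catalog with no planted members yields empty truth sets", {
  cfg <- catalog_sim_config(n_proteins = 30, cell_types = c("A", "B"),
                            frac_exclusive = 0, n_core = 0, k_core = 1, seed = 2)
  cat_ <- simulate_catalog(cfg)
  expect_equal(nrow(cat_$truth$membership), 0)
  expect_length(cat_$truth$core, 0)
  expect_true(all(lengths(cat_$truth$exclusive) == 0))
})

test_that("catalog config rejects impossible planted sets", {
  expect_error(catalog_sim_config(n_proteins = 10, frac_exclusive = 0.5,
                                  n_core = 5, cell_types = c("A", "B", "C"),
                                  k_core = 2),
               "disjoint")
  expect_error(catalog_sim_config(n_proteins = 0), "integer")
  expect_error(catalog_sim_config(frac_exclusive = 1.5), "\\[0, 1\\]")
  expect_error(catalog_sim_config(k_core = 20), "cannot exceed")
})

test_that("planted members carry the configured log2 fold-change", {
  cfg <- catalog_sim_config(n_proteins = 60, cell_types = c("A", "B"),
                            frac_exclusive = 0.1, n_core = 0, k_core = 1,
                            effect_log2fc = 2, noise_sd = 0.3, seed = 5)
  cat_ <- simulate_catalog(cfg)
  memb <- cat_$truth$membership
  means <- cat_$abundance |>
    dplyr::group_by(protein, cell_type, induction, arm) |>
    dplyr::summarise(m = mean(log2_intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = arm, values_from = m) |>
    dplyr::mutate(lfc = senescent - proliferating,
                  member = paste(protein, cell_type) %in%
                    paste(memb$protein, memb$cell_type))
  expect_lt(abs(mean(means$lfc[means$member]) - 2), 0.25)
  expect_lt(abs(mean(means$lfc[!means$member])), 0.1)
})

test_that("cohort simulation is deterministic with sane marginals", {
  cfg <- cohort_sim_config(n_participants = 300, seed = 9)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$data, s2$data)
  expect_true(all(s1$data$age >= 22 & s1$data$age <= 96))
  # sex fraction within binomial tolerance (4 SDs)
  p_f <- mean(s1$data$sex == "female")
  expect_lt(abs(p_f - 0.5), 4 * sqrt(0.25 / 300))
  # delayed entry: event/censoring age strictly beyond entry
  expect_true(all(s1$data$death_age > s1$data$entry_age))
  expect_true(all(s1$data$diabetes_onset_age > s1$data$entry_age))
  # planted identifiers exist in the table
  expect_true(all(s1$truth$sap %in% names(s1$data)))
})

test_that("cohort aligns with catalog truth when supplied", {
  cat_ <- simulate_catalog(catalog_sim_config(
    n_proteins = 60, cell_types = c("A", "B"), frac_exclusive = 0.1,
    n_core = 4, k_core = 2, seed = 3))
  coh <- simulate_cohort(cohort_sim_config(n_participants = 100,
                                           n_changepoint_proteins = 2, seed = 4),
                         cat_$truth)
  expect_true(all(cat_$truth$proteins %in% names(coh$data)))
  expect_setequal(coh$truth$sap, unique(cat_$truth$membership$protein))
})

test_that("cohort config rejects signal requests without planted sets", {
  cat0 <- simulate_catalog(catalog_sim_config(
    n_proteins = 30, cell_types = c("A", "B"), frac_exclusive = 0, n_core = 0,
    k_core = 1, seed = 2))
  expect_error(simulate_cohort(cohort_sim_config(n_participants = 50), cat0$truth),
               "no planted members")
  expect_error(cohort_sim_config(n_participants = 100, n_proteins = 50,
                                 n_sap = 60) |> simulate_cohort(),
               "exceed")
})

test_that("tissue atlas is deterministic and plants section enrichment", {
  sigs <- list(lung_cell = sprintf("P%02d", 1:30),
               kidney_cell = sprintf("P%02d", 31:60))
  a1 <- simulate_tissue_atlas(sigs, seed = 7)
  a2 <- simulate_tissue_atlas(sigs, seed = 7)
  expect_identical(a1, a2)
  sup <- tissue_support_proportion(sigs$lung_cell, a1)
  expect_equal(sup$section[1], "lung_cell_matched")

  # no enrichment: matched support equals unmatched support on average
  sigs_big <- list(lung_cell = sprintf("Q%03d", 1:150))
  a0 <- simulate_tissue_atlas(sigs_big, enrichment = 0, base_prob = 0.4, seed = 8)
  sup0 <- tissue_support_proportion(sigs_big$lung_cell, a0)
  matched0 <- sup0$proportion[sup0$section == "lung_cell_matched"]
  expect_lt(abs(matched0 - mean(sup0$proportion[sup0$section != "lung_cell_matched"])),
            0.12)
  expect_error(simulate_tissue_atlas(list()), "non-empty")
  expect_error(simulate_tissue_atlas(list(a = character(0))), "empty")
})
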