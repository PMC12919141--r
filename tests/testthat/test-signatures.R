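test_that("rule-forced classifications follow the two-induction rule", {
  elev <- data.frame(protein = c("sap1", "sap1", "inc1", "neg_none"),
                     cell_type = c("astrocyte", "astrocyte", "astrocyte", ""),
                     induction = c("IR", "ETO", "IR", ""))[1:3, ]
  rec <- make_records(c("sap1", "inc1", "dn1"), elevated = elev)
  st <- classify_senescence_status(rec)
  expect_equal(as.character(st$status[st$protein == "sap1"]), "SAP")
  expect_equal(as.character(st$status[st$protein == "inc1"]), "inconclusive")
  expect_equal(as.character(st$status[st$protein == "dn1"]), "non-SAP")
})

test_that("elevation in one induction each of two cell types is inconclusive", {
  elev <- data.frame(protein = "p1", cell_type = c("astrocyte", "PBMC"),
                     induction = c("IR", "ETO"))
  st <- classify_senescence_status(make_records("p1", elevated = elev))
  expect_equal(as.character(st$status), "inconclusive")
})

test_that("status always partitions the universe on randomized tables", {
  withr::with_seed(10, {
    for (i in 1:50) {
      prot <- sprintf("P%02d", 1:8)
      rec <- make_records(prot, cell_types = c("A", "B", "C"))
      flip <- runif(nrow(rec)) < 0.3
      rec$log2fc[flip] <- runif(sum(flip), -2, 2)
      rec$p_adj[flip] <- runif(sum(flip))
      st <- classify_senescence_status(rec)
      expect_setequal(st$protein, prot)
      expect_false(any(is.na(st$status)))
      expect_equal(nrow(st), length(prot))
    }
  })
})

test_that("cell-type signature reports the mean qualifying fold-change", {
  elev <- data.frame(protein = c("p1", "p1"), cell_type = "astrocyte",
                     induction = c("IR", "ETO"))
  rec <- make_records(c("p1", "p2"), elevated = elev)
  rec$log2fc[rec$protein == "p1" & rec$induction == "IR"] <- 1
  rec$log2fc[rec$protein == "p1" & rec$induction == "ETO"] <- 2
  sig <- cell_type_signature(rec, "astrocyte")
  expect_equal(sig$protein, "p1")
  expect_equal(sig$mean_log2fc, 1.5)
  expect_error(cell_type_signature(rec, "nope"), "Unknown cell type")
})

test_that("the default rule needs IR plus a chemical inducer; any_two relaxes it", {
  elev <- data.frame(protein = c("p1", "p1"), cell_type = "astrocyte",
                     induction = c("ETO", "DOXO"))
  rec <- make_records("p1", inductions = c("IR", "ETO", "DOXO"), elevated = elev)
  expect_equal(nrow(cell_type_signature(rec, "astrocyte")), 0)
  expect_equal(cell_type_signature(rec, "astrocyte", rule = "any_two")$protein,
               "p1")
  # IR alone never qualifies
  elev_ir <- data.frame(protein = "p1", cell_type = "astrocyte", induction = "IR")
  rec_ir <- make_records("p1", elevated = elev_ir)
  expect_equal(nrow(cell_type_signature(rec_ir, "astrocyte")), 0)
})

test_that("exclusivity removes proteins shared between cell types", {
  sigs <- list(A = c("p1", "p2"), B = c("p2", "p3"), C = character(0))
  expect_equal(exclusive_signature(sigs, "A"), "p1")
  expect_equal(exclusive_signature(sigs, "B"), "p3")
  expect_equal(exclusive_signature(sigs, "C"), character(0))
  # exclusive sets are pairwise disjoint
  ex <- lapply(names(sigs), exclusive_signature, signatures = sigs)
  expect_equal(anyDuplicated(unlist(ex)), 0)
  # degenerate one-cell-type universe: exclusive = full signature
  expect_equal(exclusive_signature(sigs["A"], "A"), c("p1", "p2"))
})

test_that("core signature applies the membership threshold and is monotone", {
  # "deep" is a member of 9 of 14 cell types, "deep8" of 8, "shallow" of 5
  sigs <- lapply(sprintf("ct%02d", 1:14), function(ct) {
    i <- as.integer(sub("ct", "", ct))
    c(if (i <= 9) "deep", if (i <= 8) "deep8", if (i <= 5) "shallow")
  })
  names(sigs) <- sprintf("ct%02d", 1:14)
  expect_true("deep" %in% core_signature(sigs, 9))
  expect_false("deep8" %in% core_signature(sigs, 9))
  expect_setequal(core_signature(sigs, 1), c("deep", "deep8", "shallow"))
  # monotone: a stricter threshold yields a subset
  for (k in 2:14) {
    expect_true(all(core_signature(sigs, k) %in% core_signature(sigs, k - 1)))
  }
  expect_error(core_signature(sigs, 0), "integer")
})

test_that("derived signature bundle keeps the set invariants", {
  cat_ <- simulate_catalog(catalog_sim_config(
    n_proteins = 60, cell_types = c("A", "B", "C"), frac_exclusive = 0.1,
    n_core = 5, k_core = 2, effect_log2fc = 3, noise_sd = 0.3,
    n_replicates = 6, seed = 13))
  sg <- derive_signatures(catalog_differential(cat_), k_core = 2)
  expect_equal(nrow(sg$status), 60)
  # exclusive(c) is a subset of the signature and disjoint across cell types
  for (ct in names(sg$signatures)) {
    expect_true(all(sg$exclusive[[ct]] %in% sg$signatures[[ct]]))
  }
  expect_equal(anyDuplicated(unlist(sg$exclusive)), 0)
  # every core protein is a member of >= k_core signatures
  counts <- table(unlist(sg$signatures))
  expect_true(all(counts[sg$core] >= 2))
})

test_that("detection crosstab returns exact p-values with degenerate cases", {
  st <- tibble::tibble(
    protein = sprintf("P%02d", 1:30),
    status = factor(rep(c("SAP", "non-SAP", "inconclusive"), each = 10),
                    levels = c("SAP", "non-SAP", "inconclusive")))
  same <- detection_crosstab(st, st$protein, st$protein)
  expect_equal(same$overall_p, 1.0, tolerance = 1e-12)
  expect_equal(same$pairwise$p_value, rep(1, 3), tolerance = 1e-12)
  # balanced 5/5/5 in both panels
  half_a <- st$protein[c(1:5, 11:15, 21:25)]
  half_b <- st$protein[c(6:10, 16:20, 26:30)]
  bal <- detection_crosstab(st, half_a, half_b)
  expect_equal(unname(bal$table), matrix(5, 3, 2))
  expect_equal(bal$overall_p, 1.0, tolerance = 1e-12)
  expect_error(detection_crosstab(st, character(0), half_b), "non-empty")
})

test_that("tissue support proportions are computed per section and ranked", {
  atlas <- tibble::tibble(
    protein = rep(c("p1", "p2", "p3", "p4"), 2),
    section = rep(c("kidney", "lung"), each = 4),
    level = c("high", "medium", "medium", "low",
              rep("not detected", 4)))
  sup <- tissue_support_proportion(c("p1", "p2", "p3", "p4"), atlas)
  expect_equal(sup$proportion[sup$section == "kidney"], 0.75)
  expect_equal(sup$proportion[sup$section == "lung"], 0)
  expect_equal(sup$rank[sup$section == "kidney"], 1)
  expect_error(tissue_support_proportion(c("zz"), atlas), "no proteins")
  expect_error(tissue_support_proportion(character(0), atlas), "empty")
})
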