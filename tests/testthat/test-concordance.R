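test_that("the published 10-isolate comparison partitions 4 / 3 / 3", {
  calls <- pumilus_group_calls()
  expect_equal(nrow(calls), 10)
  res <- concordance_from_table(calls)
  counts <- res$summary$counts
  expect_equal(unname(counts["species_concordant"]), 4L)
  expect_equal(unname(counts["maldi_confident_discordant"]), 3L)
  expect_equal(unname(counts["potentially_novel"]), 3L)
  expect_equal(res$summary$genus_agreement, 10L)

  by_cat <- split(vapply(res$records, `[[`, character(1), "isolate_id"),
                  vapply(res$records, `[[`, character(1), "category"))
  expect_setequal(by_cat$species_concordant,
                  c("PF9-10.2.1", "PF9-10.1.1", "MER_TA_110.2", "AMY_31.2"))
  expect_setequal(by_cat$maldi_confident_discordant,
                  c("AMY_17.1", "MER_178", "MER_114.2"))
  expect_setequal(by_cat$potentially_novel,
                  c("MSL_3001", "IN_293", "V45.5"))
})

test_that("category assignment follows the score threshold and name matching", {
  reg <- read_taxgroup_registry()
  rec <- categorize_call(
    list(best_ref_id = "B. safensis", percent_identity = 100, level = "species"),
    list(entry = "Bacillus safensis_FO36b^T", top_scores = c(2.3, 2.3, 2.3, 2.3)),
    registry = reg, isolate_id = "PF9-10.2.1")
  expect_equal(rec$category, "species_concordant")

  rec2 <- categorize_call(
    list(best_ref_id = "B. australimaris", percent_identity = 99.8, level = "species"),
    list(entry = "Bacillus safensis_FO36b^T", top_scores = 2.24),
    registry = reg, isolate_id = "MER_178")
  expect_equal(rec2$category, "maldi_confident_discordant")

  rec3 <- categorize_call(
    list(best_ref_id = "B. pumilus", percent_identity = 99.8, level = "species"),
    list(entry = "Bacillus pumilus_DSM 27^T", top_scores = 2.03),
    registry = reg, isolate_id = "V45.5")
  expect_equal(rec3$category, "potentially_novel")

  # 16S species inside a registered group without competing type strains
  rec4 <- categorize_call(
    list(best_ref_id = "B. pumilus", percent_identity = 99.9, level = "species"),
    list(entry = "Bacillus pumilus_DSM 27^T", top_scores = 2.5),
    registry = reg, typed_species = "Bacillus pumilus", isolate_id = "tg1")
  expect_equal(rec4$category, "taxgroup_unresolved")

  rec5 <- categorize_call(
    list(best_ref_id = "B. firmus", percent_identity = 96.2, level = "genus"),
    list(entry = "Bacillus firmus_X^T", top_scores = 2.4),
    registry = reg, isolate_id = "g1")
  expect_equal(rec5$category, "genus_only")

  expect_warning(categorize_call(
    list(best_ref_id = "Staphylococcus aureus", percent_identity = 99, level = "species"),
    list(entry = "Bacillus safensis_FO36b^T", top_scores = 2.5),
    registry = reg, isolate_id = "odd"), "genus-level disagreement")
})

test_that("tabulation conserves counts, ignores order and reproduces the
           species-level partition arithmetic", {
  reg <- read_taxgroup_registry()
  mk <- function(category_seed, i) {
    if (category_seed == "concordant")
      categorize_call(list(best_ref_id = "Bacillus firmus", percent_identity = 99.5,
                           level = "species"),
                      list(entry = "Bacillus firmus_X^T", top_scores = 2.5),
                      registry = reg, isolate_id = paste0("c", i))
    else if (category_seed == "taxgroup")
      categorize_call(list(best_ref_id = "Bacillus safensis", percent_identity = 99.9,
                           level = "species"),
                      list(entry = "Bacillus safensis_FO36b^T", top_scores = 2.4),
                      registry = reg, typed_species = "Bacillus safensis",
                      isolate_id = paste0("t", i))
    else
      categorize_call(list(best_ref_id = "Bacillus firmus", percent_identity = 99.2,
                           level = "species"),
                      list(entry = "Bacillus firmus_X^T", top_scores = 1.9),
                      registry = reg, isolate_id = paste0("n", i))
  }
  records <- c(lapply(1:244, mk, category_seed = "concordant"),
               lapply(1:101, mk, category_seed = "taxgroup"),
               lapply(1:75, mk, category_seed = "novel"))
  s <- tabulate_concordance(records)
  expect_equal(s$n, 420)
  expect_equal(sum(s$counts), 420L)
  expect_equal(unname(s$counts["species_concordant"]), 244L)
  expect_equal(unname(s$counts["taxgroup_unresolved"]), 101L)
  expect_equal(unname(s$counts["potentially_novel"]), 75L)
  expect_equal(s$genus_agreement, 420L)

  set.seed(77)
  s2 <- tabulate_concordance(sample(records))
  expect_identical(s$counts, s2$counts)
})

test_that("raising the MALDI threshold only moves records toward potentially novel", {
  reg <- read_taxgroup_registry()
  cats <- vapply(c(2.0, 2.2, 2.4, 2.6), function(th)
    categorize_call(list(best_ref_id = "Bacillus firmus", percent_identity = 99.5,
                         level = "species"),
                    list(entry = "Bacillus firmus_X^T", top_scores = 2.3),
                    registry = reg, threshold = th, isolate_id = "m")$category,
    character(1))
  expect_equal(cats, c("species_concordant", "species_concordant",
                       "potentially_novel", "potentially_novel"))
})

test_that("registry rejects species assigned to two groups and maps members", {
  expect_error(taxgroup_registry(list(g1 = "Bacillus pumilus",
                                      g2 = c("Bacillus pumilus", "Bacillus cereus"))),
               "more than one")
  reg <- read_taxgroup_registry()
  expect_equal(taxgroup_of(reg, "B. safensis"), "pumilus_group")
  expect_equal(taxgroup_of(reg, "Bacillus anthracis"), "cereus_group")
  expect_true(is.na(taxgroup_of(reg, "Bacillus firmus")))
})
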