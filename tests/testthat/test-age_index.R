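test_that("the AGE-Index is the ratio of old to young mean expression", {
  fx <- ratio_fixture(young_vals = c(10, 20), old_vals = c(30, 60))
  tab <- compute_age_index(fx$matrix, fx$meta, "female")
  rec <- tab[tab$gene == "DptA", ]
  expect_equal(rec$young_mean, 15)
  expect_equal(rec$old_mean, 45)
  expect_equal(rec$age_index, 3)
  expect_equal(rec$n_young, 2L)
  expect_equal(rec$n_old, 2L)
  expect_true(rec$defined)
  # identical expression in both stages
  same <- ratio_fixture(young_vals = c(7, 7), old_vals = c(7, 7))
  expect_equal(compute_age_index(same$matrix, same$meta, "male")$age_index[1], 1)
})

test_that("zero young means are flagged undefined unless a pseudocount is used", {
  fx <- ratio_fixture(young_vals = c(0, 0), old_vals = c(5, 5))
  tab0 <- compute_age_index(fx$matrix, fx$meta, "female", pseudocount = 0)
  expect_false(tab0$defined[tab0$gene == "DptA"])
  expect_true(is.na(tab0$age_index[tab0$gene == "DptA"]))
  tab1 <- compute_age_index(fx$matrix, fx$meta, "female", pseudocount = 0.1)
  expect_equal(tab1$age_index[tab1$gene == "DptA"], (5 + 0.1) / (0 + 0.1))
})

test_that("sex stratification is mandatory and windows must be populated", {
  fx <- ratio_fixture()
  expect_error(compute_age_index(fx$matrix, fx$meta, "mixed"), "separately")
  expect_error(compute_age_index(fx$matrix, fx$meta, "female", young = c(8, 9)),
               "young window")
  expect_error(compute_age_index(fx$matrix, fx$meta, "female", old = 100),
               "old window")
  # old ages can also be an explicit set
  tab <- compute_age_index(fx$matrix, fx$meta, "female", old = 35, old_mode = "exact")
  expect_equal(tab$n_old[1], 1L)
})

test_that("the index is scale-invariant and reciprocal under window swap", {
  fx <- ratio_fixture(young_vals = c(3, 9), old_vals = c(18, 36))
  base <- compute_age_index(fx$matrix, fx$meta, "female")$age_index
  for (c_ in c(0.01, 3, 1e4)) {
    scaled <- expression_matrix(fx$matrix * c_, unit = "raw")
    expect_equal(compute_age_index(scaled, fx$meta, "female")$age_index, base)
  }
  # swap young and old ages in the metadata: index inverts exactly
  swapped <- fx$meta
  swapped$age_days <- ifelse(swapped$age_days <= 10, 40, 5)
  inv <- compute_age_index(fx$matrix, swapped, "female")$age_index
  expect_equal(inv, 1 / base)
})

test_that("per-line aggregation averages line-level indices, not pooled samples", {
  ids <- sprintf("s%d", 1:8)
  meta <- meta_for(ids, sex = "female", age_days = rep(c(5, 40), 4),
                   line = rep(c("L1", "L1", "L2", "L2"), 2))
  # L1: young 10 -> old 20 (index 2); L2: young 10 -> old 80 (index 8)
  m <- tiny_matrix(c(10, 20, 10, 80, 10, 20, 10, 80,
                     rep(1, 8)), genes = c("g", "flat"), samples = ids)
  by_line <- compute_age_index(m, meta, "female", line_col = "line")
  expect_equal(by_line$age_index[by_line$gene == "g"], mean(c(2, 8)))
  pooled <- compute_age_index(m, meta, "female")
  expect_equal(pooled$age_index[pooled$gene == "g"], 50 / 10)
  expect_error(compute_age_index(m, meta, "female", line_col = "nope"), "nope")
})

test_that("marker ranking sorts by index with lexicographic tie-breaks", {
  tab <- structure(data.frame(gene = c("A", "B", "C", "D"),
                              sex = "female",
                              young_mean = 1, old_mean = 1, n_young = 1L, n_old = 1L,
                              age_index = c(10, 3, 7, NA),
                              defined = c(TRUE, TRUE, TRUE, FALSE),
                              stringsAsFactors = FALSE),
                   class = c("age_index_table", "data.frame"))
  expect_equal(rank_top_markers(tab, n = 2), c("A", "C"))
  expect_equal(rank_top_markers(tab, n = 10), c("A", "C", "B"))   # NA excluded
  expect_equal(rank_top_markers(tab, n = 2, restrict_to = c("B", "C")), c("C", "B"))
  ties <- tab; ties$age_index <- c(5, 5, 5, 5); ties$defined <- TRUE
  expect_equal(rank_top_markers(ties, n = 4), c("A", "B", "C", "D"))
  expect_error(rank_top_markers(tab, n = 0), "positive")
})

test_that("shared markers require support in enough datasets", {
  mk <- function(idx) structure(
    data.frame(gene = names(idx), sex = "female", young_mean = 1, old_mean = 1,
               n_young = 1L, n_old = 1L, age_index = unname(idx), defined = TRUE,
               stringsAsFactors = FALSE),
    class = c("age_index_table", "data.frame"))
  tabs <- list(d1 = mk(c(SPH93 = 40, DptA = 8, AttB = 2)),
               d2 = mk(c(SPH93 = 25, DptA = 6, AttB = 9)),
               d3 = mk(c(SPH93 = 12, DptA = 3, AttB = 1)),
               d4 = mk(c(SPH93 = 30, DptA = 7, AttB = 2)))
  res <- shared_markers(tabs, threshold = 5, min_datasets = 3)
  expect_equal(res$gene, c("SPH93", "DptA"))       # AttB only 1/4, DptA 3/4
  expect_equal(res$n_datasets, c(4, 3))
  res2 <- shared_markers(tabs, threshold = 5, min_datasets = 4)
  expect_equal(res2$gene, "SPH93")
  expect_error(shared_markers(tabs, min_datasets = 5), "exceeds")
  expect_error(shared_markers(tabs[1], min_datasets = 1), "at least two")
})

test_that("two simulated cohorts recover exactly the planted genes as shared markers", {
  cfg <- function(seed) sim_config(n_samples = 80, n_genes = 400, n_inflammaging = 12,
                                   inflammaging_fold = 10, n_male_biased = 0,
                                   n_female_suppressed = 0, noise_sd = 0.05,
                                   special_baseline_scale = 0.05, seed = seed)
  s1 <- simulate_cohort(cfg(21)); s2 <- simulate_cohort(cfg(22))
  tabs <- list(a = compute_age_index(s1$matrix, s1$meta, "female", old = 30),
               b = compute_age_index(s2$matrix, s2$meta, "female", old = 30))
  res <- shared_markers(tabs, threshold = 5, min_datasets = 2)
  planted <- s1$truth$genes$gene[s1$truth$genes$group == "inflammaging"]
  expect_setequal(res$gene, planted)
})

test_that("log2 transformation maps indices through log2 and refuses undefined ones", {
  fx <- ratio_fixture(young_vals = c(8, 8), old_vals = c(64, 64))
  tab <- compute_age_index(fx$matrix, fx$meta, "female")
  lt <- log2_table(tab)
  expect_equal(lt$age_index[lt$gene == "DptA"], 3)
  expect_equal(lt$age_index[lt$gene == "filler"], 0)
  expect_equal(attr(lt, "provenance")$transformed, "log2")
  dec <- ratio_fixture(young_vals = c(8, 8), old_vals = c(2, 2))
  expect_equal(log2_table(compute_age_index(dec$matrix, dec$meta, "female"))$age_index[1], -2)
  undef <- ratio_fixture(young_vals = c(0, 0), old_vals = c(5, 5))
  expect_error(log2_table(compute_age_index(undef$matrix, undef$meta, "female")),
               "pseudocount")
})

test_that("planted inflammaging genes dominate the ranking in a noisy cohort", {
  sim <- simulate_cohort(sim_config(n_samples = 120, n_genes = 2000,
                                    n_inflammaging = 40, inflammaging_fold = 10,
                                    n_male_biased = 0, n_female_suppressed = 0,
                                    noise_sd = 0.2, seed = 9))
  planted <- sim$truth$genes$gene[sim$truth$genes$group == "inflammaging"]
  for (sex in c("female", "male")) {
    tab <- compute_age_index(sim$matrix, sim$meta, sex, old = 30)
    top50 <- rank_top_markers(tab, n = 50)
    expect_true(all(planted %in% top50))
    expect_true(all(rank_top_markers(tab, n = 12) %in% planted))
  }
})

test_that("AGE-Index tables survive a TSV round trip", {
  fx <- ratio_fixture()
  tab <- compute_age_index(fx$matrix, fx$meta, "female")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_age_index(tab, path)
  back <- read_age_index(path)
  expect_equal(back$age_index, tab$age_index)
  expect_equal(back$gene, tab$gene)
})
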