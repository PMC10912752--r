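test_that("a null screen at vanishing dispersion concentrates guide LFCs at zero", {
  lib <- sim_library(10, 5, 0, pathway_map = default_pathway_map(10), seed = 1)
  sc <- sim_screen_counts(
    lib, screen_design(genotypes = "WT", replicates = 1, depth = 5e6,
                       dispersion = 0), seed = 2)
  nc <- normalize_counts(sc)
  lfc <- guide_lfc(nc)
  expect_lt(max(abs(lfc$lfc)), 0.05)
})

test_that("an injected selection coefficient is recovered as the mean guide LFC in its arm", {
  # one gene with 100 guides, effect -2 in (KO, TMZ) only; a large control
  # pool anchors the per-sample normalization
  pm <- tibble::tibble(gene = "TGT", pathway = "P")
  lib <- sim_library(1, 100, 2000, pathway_map = pm, seed = 3)
  eff <- effect_spec(tibble::tibble(gene = "TGT", genotype = "KO",
                                    treatment = "TMZ", effect = -2))
  sc <- sim_screen_counts(lib, screen_design(depth = 1e6), eff, seed = 4)
  lfc <- guide_lfc(normalize_counts(sc))
  by_arm <- lfc |>
    dplyr::filter(!is_control) |>
    dplyr::group_by(genotype, treatment) |>
    dplyr::summarise(m = mean(lfc), .groups = "drop")
  hit <- by_arm$m[by_arm$genotype == "KO" & by_arm$treatment == "TMZ"]
  others <- by_arm$m[!(by_arm$genotype == "KO" & by_arm$treatment == "TMZ")]
  expect_lt(abs(hit - (-2)), 0.15)
  expect_lt(max(abs(others)), 0.1)
})

test_that("positively selected MMR genes land in the enriched tail of the gene ranking", {
  lib <- sim_library(30, 5, 100, pathway_map = default_pathway_map(30), seed = 5)
  mmr <- c("MLH1", "MSH2", "MSH6", "PMS1", "PMS2")
  eff <- effect_spec(tidyr::crossing(gene = mmr, genotype = c("WT", "KO"),
                                     treatment = "TMZ") |>
                       dplyr::mutate(effect = 2))
  sc <- sim_screen_counts(lib, screen_design(depth = 1e6), eff, seed = 6)
  lfc <- guide_lfc(normalize_counts(sc))
  sfc <- gene_sigma_fc(lfc) |> dplyr::filter(treatment == "TMZ")
  for (g in c("WT", "KO")) {
    ranked <- sfc |> dplyr::filter(genotype == g) |> dplyr::arrange(-sigma_fc)
    expect_setequal(ranked$gene[1:5], mmr)
  }
})

test_that("screen count generation is deterministic and records effect truth", {
  lib <- sim_library(5, 2, 5, pathway_map = default_pathway_map(5), seed = 7)
  eff <- effect_spec(tibble::tibble(gene = "MLH1", genotype = "WT",
                                    treatment = "TMZ", effect = -1))
  a <- sim_screen_counts(lib, screen_design(replicates = 2, depth = 1e5), eff, seed = 8)
  b <- sim_screen_counts(lib, screen_design(replicates = 2, depth = 1e5), eff, seed = 8)
  expect_identical(a$counts, b$counts)
  expect_equal(nrow(a$truth), 5 * 2 * 2)
  expect_equal(a$truth$effect[a$truth$gene == "MLH1" &
                                a$truth$genotype == "WT" &
                                a$truth$treatment == "TMZ"], -1)
  expect_equal(sum(a$truth$effect != 0), 1)
  expect_error(sim_screen_counts(
    lib, screen_design(),
    effect_spec(tibble::tibble(gene = "NOPE", genotype = "WT",
                               treatment = "TMZ", effect = 1))),
    "absent from the library")
})

test_that("cassette reads contain the spacer and round-trip through counting", {
  lib <- tiny_library(c("A1", "B1"), guides_per_gene = 2, n_controls = 1)
  counts <- tibble::tibble(guide_id = lib$guide_id[1], count = 3L)
  rd <- sim_cassette_reads(lib, counts, seed = 9)
  expect_equal(nrow(rd), 3)
  expect_true(all(grepl(lib$spacer[1], rd$seq, fixed = TRUE)))
  full <- tibble::tibble(guide_id = lib$guide_id, count = c(4L, 2L, 0L, 1L, 5L))
  rd2 <- sim_cassette_reads(lib, full, read_len = 80, seed = 10)
  res <- count_guides(rd2, lib)
  expect_equal(res$counts$count, full$count)
  expect_equal(res$unmapped, 0)
})

test_that("substitution errors reduce exact-match recovery by the binomial retention", {
  lib <- tiny_library("A1", guides_per_gene = 1)
  f5 <- "ACGTAC"; f3 <- "TTGACC"
  n <- 8000L
  rd <- sim_cassette_reads(lib, tibble::tibble(guide_id = lib$guide_id,
                                               count = n),
                           flank5 = f5, flank3 = f3,
                           error_rate = 0.01, seed = 11)
  res <- count_guides(rd, lib, flank5 = f5, flank3 = f3)
  expect_lt(res$counts$count, n)
  # a read maps iff flank5 + spacer + the in-read part of flank3 are error-free
  p_keep <- (1 - 0.01)^(nchar(f5) + 20 + nchar(f3))
  se <- sqrt(p_keep * (1 - p_keep) / n)
  expect_lt(abs(res$counts$count / n - p_keep), 5 * se)
})

test_that("non-ACGT flanks are rejected", {
  lib <- tiny_library("A1")
  expect_error(sim_cassette_reads(lib, tibble::tibble(guide_id = lib$guide_id,
                                                      count = 1L),
                                  flank5 = "ACGTN"), "only A, C, G, T")
})
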