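# one gene, configurable per-arm PD0/PD20 normalized values
lfc_fixture <- function(pd0, pd20, genes = NULL, guides_per_gene = NULL) {
  n <- length(pd0)
  if (is.null(genes)) {
    lib <- tiny_library("G1", guides_per_gene = n)
  } else {
    lib <- tiny_library(genes, guides_per_gene = guides_per_gene)
  }
  make_counts(lib, list(s0 = pd0, s1 = pd20),
              tibble::tibble(sample = c("s0", "s1"), genotype = "WT",
                             treatment = "TMZ", timepoint = c("PD0", "PD20"),
                             replicate = 1))
}

test_that("guide log2 fold change matches hand arithmetic with the pseudocount", {
  x <- lfc_fixture(pd0 = c(100, 50, 0), pd20 = c(25, 50, 0))
  lfc <- guide_lfc(x, pseudocount = 1)
  expect_equal(lfc$lfc[1], log2(26 / 101), tolerance = 1e-12)
  expect_equal(lfc$lfc[2], 0)
  expect_equal(lfc$lfc[3], 0)  # 0/0 guarded by the pseudocount
})

test_that("a missing timepoint in an arm is an error", {
  lib <- tiny_library("G1", guides_per_gene = 2)
  x <- make_counts(lib, list(s0 = c(1, 2), s1 = c(1, 2)),
                   tibble::tibble(sample = c("s0", "s1"), genotype = "WT",
                                  treatment = c("TMZ", "DMSO"),
                                  timepoint = "PD0", replicate = 1))
  expect_error(guide_lfc(x), "timepoint")
})

test_that("SigmaFC sums replicate-mean guide LFCs and is linear in guide count", {
  lfc <- tibble::tibble(
    guide_id = c("g1", "g2", "g3"), gene = "G", is_control = FALSE,
    genotype = "WT", treatment = "TMZ", replicate = 1,
    lfc = c(-1, -2, 0.5))
  sfc <- gene_sigma_fc(lfc)
  expect_equal(sfc$sigma_fc, -2.5)
  doubled <- dplyr::bind_rows(lfc,
                              dplyr::mutate(lfc, guide_id = paste0(guide_id, "b")))
  expect_equal(gene_sigma_fc(doubled)$sigma_fc, -5)
  # replicate averaging first: two replicates with the same values change nothing
  reps <- dplyr::bind_rows(lfc, dplyr::mutate(lfc, replicate = 2))
  expect_equal(gene_sigma_fc(reps)$sigma_fc, -2.5)
})

test_that("permutation p follows the +1-corrected enumeration and its floor", {
  lfc_ctrl <- tibble::tibble(
    guide_id = paste0("c", 1:6), gene = NA, is_control = TRUE,
    genotype = "WT", treatment = "TMZ", replicate = 1,
    lfc = c(0.1, -0.1, 0.05, -0.05, 0.02, -0.02))
  scores <- tibble::tibble(gene = "G", genotype = "WT", treatment = "TMZ",
                           n_guides = 2L, sigma_fc = 50)
  # every null |sum of 2 controls| < 50 -> p = 1/(B+1)
  p <- permutation_pvalue(scores, lfc_ctrl, B = 3, seed = 1)$perm_p
  expect_equal(p, 1 / 4)
  # observed 0 with a symmetric null -> p = 1
  scores$sigma_fc <- 0
  expect_equal(permutation_pvalue(scores, lfc_ctrl, B = 99, seed = 1)$perm_p, 1)
  # never zero, floor attained
  scores$sigma_fc <- 1e6
  expect_equal(permutation_pvalue(scores, lfc_ctrl, B = 100, seed = 1)$perm_p,
               1 / 101)
  scores$n_guides <- 10L
  expect_error(permutation_pvalue(scores, lfc_ctrl, B = 3, seed = 1),
               "fewer control guides")
})

zstat_fixture <- function(tmz, dmso) {
  tibble::tibble(
    guide_id = paste0("g", seq_along(c(tmz, dmso))), gene = "G",
    is_control = FALSE, genotype = "WT",
    treatment = rep(c("TMZ", "DMSO"), c(length(tmz), length(dmso))),
    replicate = 1, lfc = c(tmz, dmso))
}

test_that("the gene Z-statistic matches the Welch-form hand computation", {
  z <- gene_zstat(zstat_fixture(c(-1.0, -0.6), c(0.0, 0.2)))
  expect_equal(z$x, -0.9)
  expect_equal(z$s, sqrt(0.08 / 2 + 0.02 / 2), tolerance = 1e-12)
  expect_equal(z$z, -0.9 / sqrt(0.05), tolerance = 1e-12)
  # identical conditions -> X = Z = 0
  z0 <- gene_zstat(zstat_fixture(c(0.3, 0.5), c(0.3, 0.5)))
  expect_equal(z0$x, 0)
  expect_equal(z0$z, 0)
  # swapping conditions negates X and Z
  zs <- gene_zstat(zstat_fixture(c(0.0, 0.2), c(-1.0, -0.6)))
  expect_equal(zs$x, 0.9)
  expect_equal(zs$z, 0.9 / sqrt(0.05), tolerance = 1e-12)
})

test_that("degenerate gene Z inputs raise the documented errors", {
  expect_error(gene_zstat(zstat_fixture(-1, c(0, 0.2))),
               ">= 2 LFC observations")
  expect_error(gene_zstat(zstat_fixture(c(1, 1), c(0, 0))),
               "zero-variance")
})

test_that("the pathway statistic combines gene X and S exactly as printed", {
  gs <- tibble::tibble(gene = c("A", "B"), genotype = "WT",
                       n_case = 6, n_ref = 6,
                       x = c(-0.9, -0.3), s = sqrt(c(0.05, 0.04)))
  gs$z <- gs$x / gs$s
  pm <- tibble::tibble(gene = c("A", "B"), pathway = "P")
  zp <- pathway_zstat(gs, pm)
  expect_equal(zp$z_p, -1.2 / 0.3)
  expect_equal(zp$p_z, 2 * pnorm(-4))
  # single-gene pathway reduces to the gene statistic
  zp1 <- pathway_zstat(gs[1, ], tibble::tibble(gene = "A", pathway = "solo"))
  expect_equal(zp1$z_p, gs$z[1])
  # invariant to gene order; singleton split recombines to the same value
  zp_rev <- pathway_zstat(gs[2:1, ], pm)
  expect_equal(zp_rev$z_p, zp$z_p)
  expect_error(pathway_zstat(gs, tibble::tibble(gene = "C", pathway = "empty")),
               "scored member gene")
})

test_that("pathway dropout pairs match an independent paired-t computation", {
  withr::with_seed(31, {
    lib <- tiny_library("G1", guides_per_gene = 10)
    pd0 <- rep(1000, 10)
    d <- rnorm(10, -0.1, 0.01)
    pd20 <- 10^(log10(pd0 + 1) + d) - 1
    x <- make_counts(lib, list(s0 = pd0, s1 = pd20),
                     tibble::tibble(sample = c("s0", "s1"), genotype = "WT",
                                    treatment = "TMZ",
                                    timepoint = c("PD0", "PD20"),
                                    replicate = 1))
    pm <- tibble::tibble(gene = "G1", pathway = "P")
    ds <- pathway_dropout_stats(x, pm)
    expect_equal(ds$paired_t_p,
                 oracle_paired_t_p(log10(pd20 + 1), log10(pd0 + 1)),
                 tolerance = 1e-10)
  })
})

test_that("pathway dropout handles unchanged and exactly halved guides", {
  lib <- tiny_library("G1", guides_per_gene = 4)
  pm <- tibble::tibble(gene = "G1", pathway = "P")
  same <- make_counts(lib, list(s0 = c(10, 20, 30, 40), s1 = c(10, 20, 30, 40)),
                      tibble::tibble(sample = c("s0", "s1"), genotype = "WT",
                                     treatment = "TMZ",
                                     timepoint = c("PD0", "PD20"),
                                     replicate = 1))
  ds <- pathway_dropout_stats(same, pm)
  expect_equal(ds$paired_t_p, 1)
  expect_equal(ds$pooled_log2fc, 0)
  halved <- make_counts(lib, list(s0 = c(10, 20, 30, 40), s1 = c(5, 10, 15, 20)),
                        tibble::tibble(sample = c("s0", "s1"), genotype = "WT",
                                       treatment = "TMZ",
                                       timepoint = c("PD0", "PD20"),
                                       replicate = 1))
  expect_equal(pathway_dropout_stats(halved, pm)$pooled_log2fc, -1)
})

test_that("screen statistics are invariant to the normalization constant", {
  lib <- sim_library(8, 4, 20, pathway_map = default_pathway_map(8), seed = 41)
  sc <- sim_screen_counts(lib, screen_design(genotypes = "WT", replicates = 2,
                                             depth = 1e6), seed = 42)
  z6 <- gene_zstat(guide_lfc(normalize_counts(sc, 1e6)))
  z8 <- gene_zstat(guide_lfc(normalize_counts(sc, 1e8)))
  # pseudocount 1 on normalized counts: invariance is exact in the limit of
  # counts >> 1, numerically tight at screen-scale depth
  expect_equal(z6$z, z8$z, tolerance = 0.02)
})

test_that("a strongly depleted pathway yields a negative, significant Z_P", {
  lib <- sim_library(12, 10, 50, pathway_map = default_pathway_map(12), seed = 51)
  mmr <- default_pathway_map(12)
  mmr_genes <- mmr$gene[mmr$pathway == "MMR"]
  eff <- effect_spec(tidyr::crossing(gene = mmr_genes, genotype = "WT",
                                     treatment = "TMZ") |>
                       dplyr::mutate(effect = -1.5))
  sc <- sim_screen_counts(lib, screen_design(genotypes = "WT", replicates = 3,
                                             depth = 1e6), eff, seed = 52)
  zp <- pathway_zstat(gene_zstat(guide_lfc(normalize_counts(sc))), mmr)
  hit <- zp[zp$pathway == "MMR", ]
  expect_lt(hit$z_p, 0)
  expect_lt(hit$p_z, 0.01)
})
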