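vr <- function(pos = 100, ref = "C", alt = "T", depth = 30L, alt_reads = 10L,
               sample = "s1", chrom = "chr1", context = "ACG", filter = "PASS") {
  tibble::tibble(sample = sample, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, depth = depth, alt_reads = alt_reads,
                 context = context, filter = filter)
}

test_that("thresholds are inclusive at the printed boundaries", {
  # depth 9 fails coverage even at good VAF
  res <- apply_filter_chain(vr(depth = 9L, alt_reads = 3L))
  expect_equal(nrow(res$variants), 0)
  expect_equal(res$tally$removed[res$tally$filter == "coverage"], 1)
  # depth 30, alt 3, VAF exactly 0.10 passes every threshold
  res2 <- apply_filter_chain(vr(depth = 30L, alt_reads = 3L))
  expect_equal(nrow(res2$variants), 1)
  # VAF just below 10% fails
  res3 <- apply_filter_chain(vr(depth = 31L, alt_reads = 3L))
  expect_equal(nrow(res3$variants), 0)
  expect_equal(res3$tally$removed[res3$tally$filter == "allele_frequency"], 1)
  # alt reads 2 fails even at high VAF
  res4 <- apply_filter_chain(vr(depth = 10L, alt_reads = 2L))
  expect_equal(nrow(res4$variants), 0)
})

test_that("indels longer than 10 bp are removed, 10 bp kept", {
  ins11 <- vr(ref = "C", alt = paste0("C", strrep("A", 11)), alt_reads = 15L,
              context = "ACG")
  ins10 <- vr(ref = "C", alt = paste0("C", strrep("A", 10)), alt_reads = 15L)
  expect_equal(nrow(apply_filter_chain(ins11)$variants), 0)
  expect_equal(nrow(apply_filter_chain(ins10)$variants), 1)
})

test_that("known sites match on exact tuples and exon overlap uses BED semantics", {
  ks <- tibble::tibble(chrom = "chr1", pos = 100, ref = "C", alt = "T")
  expect_equal(nrow(apply_filter_chain(vr(), known_sites = ks)$variants), 0)
  # same position, different alt: kept
  expect_equal(nrow(apply_filter_chain(vr(alt = "G", context = "ACG"),
                                       known_sites = ks)$variants), 1)
  # BED [10, 20) covers 1-based 11..20
  bed <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L)
  keep <- function(p) nrow(apply_filter_chain(vr(pos = p),
                                              exon_regions = bed)$variants)
  expect_equal(keep(10), 0)
  expect_equal(keep(11), 1)
  expect_equal(keep(20), 1)
  expect_equal(keep(21), 0)
  expect_error(apply_filter_chain(vr(), exon_regions = tibble::tibble(
    chrom = "chr1", start = 5L, end = 5L)), "malformed interval")
})

test_that("caller FILTER is honored, conjunction tally attributes once, malformed records error", {
  v <- dplyr::bind_rows(
    vr(filter = "germline"),                     # caller filter
    vr(depth = 9L, alt_reads = 0L),              # fails several: tallied once
    vr())
  res <- apply_filter_chain(v)
  expect_equal(nrow(res$variants), 1)
  expect_equal(sum(res$tally$removed), 2)
  expect_equal(res$tally$removed[res$tally$filter == "caller_filter"], 1)
  expect_equal(res$tally$removed[res$tally$filter == "allele_frequency"], 1)
  res_off <- apply_filter_chain(v, pass_only = FALSE)
  expect_equal(nrow(res_off$variants), 2)
  expect_error(apply_filter_chain(vr(depth = 0L, alt_reads = 0L)), "zero depth")
  expect_error(apply_filter_chain(vr(depth = 10L, alt_reads = 11L)),
               "malformed")
})

test_that("the filter chain is idempotent and monotone", {
  withr::with_seed(61, {
    sim <- sim_mutation_catalogs(catalog_design(clones_per_arm = 1))
    once <- apply_filter_chain(sim$variants)
    twice <- apply_filter_chain(once$variants)
    expect_equal(once$variants, twice$variants)
    # adding a filter never enlarges the surviving set
    stricter <- apply_filter_chain(sim$variants, maf = 0.4)
    expect_lte(nrow(stricter$variants), nrow(once$variants))
  })
})

test_that("purine-reference SNVs are reverse-complemented to the pyrimidine classes", {
  r <- classify_snv("G", "A", "TGC")
  expect_equal(r$class, "C>T")
  expect_equal(r$context96, "G[C>T]A")
  r2 <- classify_snv("C", "T", "ACG")
  expect_equal(r2$context96, "A[C>T]G")
  # strand symmetry: a record and its reverse complement classify identically
  withr::with_seed(62, {
    for (i in 1:25) {
      ctx <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
      ref <- substr(ctx, 2, 2)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      fwd <- classify_snv(ref, alt, ctx)
      rc_ctx <- tmzscreen:::revcomp(ctx)
      rev <- classify_snv(chartr("ACGT", "TGCA", ref),
                          chartr("ACGT", "TGCA", alt), rc_ctx)
      expect_identical(fwd, rev)
    }
  })
  expect_error(classify_snv("C", "C", "ACG"), "ref equals alt")
  expect_error(classify_snv("N", "A", "ANG"), "non-ACGT")
})

test_that("catalogs count one cell per SNV and conserve per-sample totals", {
  one <- build_catalog(vr())
  expect_equal(sum(one$s1), 1)
  expect_equal(one$s1[one$context == "A[C>T]G"], 1)
  withr::with_seed(63, {
    sim <- sim_mutation_catalogs(catalog_design(clones_per_arm = 2))
    cat_ <- build_catalog(sim$variants)
    sums <- colSums(as.matrix(cat_[setdiff(names(cat_), "context")]))
    expect_equal(unname(sums[sim$truth$sample]), sim$truth$total)
  })
})

test_that("attached-context and reference-lookup catalogs agree", {
  ref <- sim_context_reference(seed = 64)
  sim <- sim_mutation_catalogs(catalog_design(clones_per_arm = 1),
                               reference = ref, seed = 65)
  a <- build_catalog(sim$variants)
  b <- build_catalog(dplyr::select(sim$variants, -context), reference = ref)
  expect_equal(as.matrix(a[-1]), as.matrix(b[-1]))
  # chromosome-edge records are skipped with a warning
  edge <- vr(pos = 1, chrom = ref$name, ref = substr(ref$seq, 1, 1),
             alt = setdiff(c("A", "C", "G", "T"), substr(ref$seq, 1, 1))[1])
  expect_warning(c_edge <- build_catalog(dplyr::select(edge, -context),
                                         reference = ref), "edge")
  expect_equal(attr(c_edge, "skipped"), 1L)
})

test_that("pattern decomposition splits C>T from the rest and conserves totals", {
  counts <- tibble::tibble(
    sample = "s",
    class = c("C>T", "C>A", "C>G", "T>A", "T>C", "T>G"),
    n = c(10, 1, 2, 3, 4, 0))
  pd <- pattern_decomposition(counts)
  expect_equal(pd$pattern_I, 10)
  expect_equal(pd$pattern_II, 10)
  expect_equal(pd$total, 20)
  empty <- build_catalog(vr()[0, ])
  expect_equal(nrow(pattern_decomposition(empty)), 0)
  # a pure C>T catalog has no Pattern II
  pure <- build_catalog(vr(ref = "C", alt = "T", context = "ACT"))
  pdp <- pattern_decomposition(pure)
  expect_equal(pdp$pattern_II, 0)
  expect_equal(pdp$pattern_I + pdp$pattern_II, pdp$total)
})
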