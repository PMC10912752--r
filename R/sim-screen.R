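# Synthetic pooled-screen count and read generation. PD0 abundances are
# drawn log-normal around uniform (libraries are never perfectly balanced);
# PD20 expectations apply per-gene multiplicative selection on the log2
# scale; counts are negative-binomial with variance mu + alpha * mu^2.

#' Screen design
#'
#' Describes the factorial layout of a dropout screen: genotypes x
#' treatments x replicates, each arm sequenced at two population-doubling
#' timepoints (PD0 before selection, PD20 after).
#'
#' @param genotypes,treatments Character label sets.
#' @param timepoints Ordered pair of timepoint labels, early first.
#' @param replicates Number of independent screens per arm (default 3).
#' @param depth Expected total reads per sample (default 5e6, keeping
#'   several-hundred-fold representation of a ~6000-guide library).
#' @param dispersion Negative-binomial dispersion alpha in
#'   `var = mu + alpha * mu^2`; 0 gives Poisson counts. Default 0.05.
#' @param pd0_skew_sd Log-normal sd of PD0 guide abundances around uniform
#'   (default 0.25).
#' @return A `screen_design` list.
#' @export
screen_design <- function(genotypes = c("WT", "KO"),
                          treatments = c("TMZ", "DMSO"),
                          timepoints = c("PD0", "PD20"),
                          replicates = 3,
                          depth = 5e6,
                          dispersion = 0.05,
                          pd0_skew_sd = 0.25) {
  stopifnot(length(timepoints) == 2, replicates >= 1, depth > 0,
            dispersion >= 0, pd0_skew_sd >= 0)
  structure(
    list(genotypes = genotypes, treatments = treatments,
         timepoints = timepoints, replicates = as.integer(replicates),
         depth = depth, dispersion = dispersion, pd0_skew_sd = pd0_skew_sd),
    class = "screen_design"
  )
}

#' Per-gene selection effects for the screen generator
#'
#' @param effects Tibble with columns `gene`, `genotype`, `treatment`,
#'   `effect`: the log2 fold change applied to the gene's guides' PD20
#'   expectation in that arm. Genes/arms not listed get effect 0. Control
#'   guides always have effect 0.
#' @param guide_noise_sd Sd of per-guide log2 noise added to the gene effect
#'   where one exists (guide-to-guide variability of the selection
#'   coefficient; shared across replicates; default 0.2). Guides of genes
#'   with no effect in an arm, and control guides, get no noise, so a fully
#'   null screen is exchangeable with the control pool.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(effects = NULL, guide_noise_sd = 0.2) {
  if (is.null(effects)) {
    effects <- tibble(gene = character(), genotype = character(),
                      treatment = character(), effect = numeric())
  }
  stopifnot(all(c("gene", "genotype", "treatment", "effect") %in% names(effects)))
  if (any(!is.finite(effects$effect))) abort("non-finite effect")
  structure(list(effects = as_tibble(effects),
                 guide_noise_sd = guide_noise_sd),
            class = "effect_spec")
}

# NB draw with mean mu and dispersion alpha (alpha = 0 -> Poisson)
rnb <- function(n, mu, alpha) {
  if (alpha <= 0) rpois(n, mu) else rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate guide counts for a pooled dropout screen
#'
#' PD0 counts are negative-binomial around a common log-normal abundance
#' profile; the PD20 expectation for guide i of gene g in arm a is
#' `mu0_i * 2^(effect_g(a) + noise_i(a))`. Each (genotype, treatment,
#' replicate) arm has its own PD0 and PD20 sample. The injected per-arm
#' coefficients are returned as a truth table for recovery tests.
#'
#' @param library Library manifest from [sim_library()].
#' @param design A [screen_design()].
#' @param effects An [effect_spec()]; `NULL` means no true effects.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `screen_counts` object (see [screen_counts()]) with an extra
#'   `truth` element: a tibble of the per-gene, per-arm coefficients used.
#' @export
sim_screen_counts <- function(library, design = screen_design(),
                              effects = NULL, seed = NULL) {
  if (is.null(effects)) effects <- effect_spec()
  stopifnot(inherits(design, "screen_design"), inherits(effects, "effect_spec"))
  eff <- effects$effects
  unknown <- setdiff(eff$gene, library$gene)
  if (length(unknown)) {
    abort(paste0("effects reference genes absent from the library: ",
                 paste(unknown, collapse = ", ")))
  }
  run <- function() {
    n_guides <- nrow(library)
    p0 <- exp(rnorm(n_guides, 0, design$pd0_skew_sd))
    p0 <- p0 / sum(p0)
    mu0 <- design$depth * p0
    arms <- expand.grid(replicate = seq_len(design$replicates),
                        treatment = design$treatments,
                        genotype = design$genotypes,
                        stringsAsFactors = FALSE)[, c("genotype", "treatment", "replicate")]
    counts <- tibble(guide_id = library$guide_id)
    # guide-level noise models variability of the selection coefficient
    # across a gene's guides: it is shared across replicate screens and
    # applies only where a true effect exists, so a fully null arm is
    # exchangeable with the non-targeting control pool
    combos <- unique(arms[, c("genotype", "treatment")])
    noise_list <- list()
    for (j in seq_len(nrow(combos))) {
      nz <- rnorm(n_guides, 0, effects$guide_noise_sd)
      e <- eff[eff$genotype == combos$genotype[j] &
                 eff$treatment == combos$treatment[j] & eff$effect != 0, ]
      nz[library$is_control | !library$gene %in% e$gene] <- 0
      noise_list[[paste(combos$genotype[j], combos$treatment[j], sep = "_")]] <- nz
    }
    meta <- list()
    for (i in seq_len(nrow(arms))) {
      g <- arms$genotype[i]; tr <- arms$treatment[i]; rp <- arms$replicate[i]
      # per-guide gene effect in this arm
      e <- eff[eff$genotype == g & eff$treatment == tr, c("gene", "effect")]
      gene_eff <- setNames(rep(0, n_guides), library$guide_id)
      if (nrow(e)) {
        idx <- match(library$gene, e$gene)
        gene_eff[!is.na(idx)] <- e$effect[idx[!is.na(idx)]]
      }
      gene_eff[library$is_control] <- 0
      gene_eff[is.na(gene_eff)] <- 0
      noise <- noise_list[[paste(g, tr, sep = "_")]]
      mu20 <- mu0 * 2^(gene_eff + noise)
      s0 <- paste(g, tr, design$timepoints[1], rp, sep = "_")
      s20 <- paste(g, tr, design$timepoints[2], rp, sep = "_")
      counts[[s0]] <- rnb(n_guides, mu0, design$dispersion)
      counts[[s20]] <- rnb(n_guides, mu20, design$dispersion)
      meta[[length(meta) + 1]] <- tibble(
        sample = c(s0, s20), genotype = g, treatment = tr,
        timepoint = design$timepoints, replicate = rp
      )
    }
    truth <- expand.grid(gene = unique(library$gene[!library$is_control]),
                         genotype = design$genotypes,
                         treatment = design$treatments,
                         stringsAsFactors = FALSE) |> as_tibble()
    truth <- left_join(truth, eff, by = c("gene", "genotype", "treatment"))
    truth$effect[is.na(truth$effect)] <- 0
    out <- screen_counts(counts, bind_rows(meta), library = library)
    out$truth <- truth
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# default universal flanking sequences around the 20-nt spacer in the
# sequenced cassette (U6 promoter tail / tracr scaffold head)
#' @rdname sim_cassette_reads
#' @export
default_flanks <- function() {
  c(flank5 = "TTGTGGAAAGGACGAAACACCG", flank3 = "GTTTTAGAGCTAGAAATAGCAA")
}

#' Simulate cassette amplicon reads for a counted sample
#'
#' Emits, for each guide, the requested number of reads containing
#' `flank5 + spacer + flank3` (padded with random bases to `read_len`),
#' with independent per-base substitution errors at `error_rate`.
#' With `error_rate = 0` the reads round-trip exactly through
#' [count_guides()].
#'
#' @param library Library manifest.
#' @param counts Tibble with columns `guide_id`, `count` (non-negative
#'   integers) for one sample, or a named vector.
#' @param flank5,flank3 Universal flanking sequences (ACGT only).
#' @param read_len Read length; default fits flanks + spacer exactly.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A tibble with columns `read_id`, `seq`. Write to disk with
#'   [write_reads_fastq()].
#' @export
sim_cassette_reads <- function(library, counts,
                               flank5 = default_flanks()[["flank5"]],
                               flank3 = default_flanks()[["flank3"]],
                               read_len = NULL, error_rate = 0, seed = NULL) {
  if (!is.data.frame(counts)) {
    counts <- tibble(guide_id = names(counts), count = as.integer(counts))
  }
  stopifnot(all(counts$count >= 0), error_rate >= 0, error_rate < 1)
  if (grepl("[^ACGT]", flank5) || grepl("[^ACGT]", flank3)) {
    abort("flanks must contain only A, C, G, T")
  }
  spacer_len <- unique(nchar(library$spacer))
  stopifnot(length(spacer_len) == 1)
  core_len <- nchar(flank5) + spacer_len + nchar(flank3)
  if (is.null(read_len)) read_len <- core_len
  if (read_len < core_len) abort("read_len shorter than flank5 + spacer + flank3")
  run <- function() {
    idx <- match(counts$guide_id, library$guide_id)
    if (anyNA(idx)) abort("counts reference guides absent from the library")
    reps <- rep(idx, counts$count)
    n <- length(reps)
    if (n == 0) return(tibble(read_id = character(), seq = character()))
    seqs <- paste0(flank5, library$spacer[reps], flank3)
    if (read_len > core_len) {
      pad <- vapply(seq_len(n), function(i) {
        paste(sample(.BASES, read_len - core_len, replace = TRUE), collapse = "")
      }, "")
      seqs <- paste0(seqs, pad)
    }
    if (error_rate > 0) {
      mat <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
      hit <- matrix(runif(n * read_len) < error_rate, nrow = n)
      if (any(hit)) {
        # substitute with one of the three other bases
        cur <- mat[hit]
        mat[hit] <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1), "")
      }
      seqs <- apply(mat, 1, paste, collapse = "")
    }
    tibble(read_id = sprintf("read_%06d", seq_len(n)), seq = seqs)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
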