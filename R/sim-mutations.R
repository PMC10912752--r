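# Synthetic clone mutation catalogs. Each arm of the mutagenesis design
# (RAD18 x MLH1 genotype x TMZ/DMSO) yields clones whose de novo SNV totals
# are negative-binomial around basal (+ TMZ-induced) means, with
# trinucleotide contexts drawn from a per-arm signature mixture. Drawn
# exposures are retained as ground truth for refitting tests.

#' Primary-lesion spectrum of a DNA-methylating agent
#'
#' Default proportions of the three primary TMZ lesions: ~70% N7-methyl
#' guanine, ~25% N3-methyl adenine and ~5% O6-methyl guanine (the
#' mutagenic, MGMT-reversible species).
#'
#' @return Named numeric simplex over `N7mG`, `N3mA`, `O6mG`.
#' @export
lesion_spectrum <- function() {
  c(N7mG = 0.70, N3mA = 0.25, O6mG = 0.05)
}

#' Draw primary lesions from a lesion spectrum
#'
#' @param n Number of lesions to draw.
#' @param spectrum Named probability vector (default [lesion_spectrum()]).
#' @param seed Integer seed.
#' @return Factor of lesion labels, length `n`.
#' @export
sim_lesions <- function(n, spectrum = lesion_spectrum(), seed = NULL) {
  stopifnot(n >= 1, all(spectrum >= 0), abs(sum(spectrum) - 1) < 1e-8)
  run <- function() {
    factor(sample(names(spectrum), n, replace = TRUE, prob = spectrum),
           levels = names(spectrum))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.RAD18 <- c("RAD18+/+", "RAD18-/-")
.MLH1 <- c("MLH1+/+", "MLH1-/-")

#' Default mutagenesis calibration
#'
#' Per-genotype calibration of the catalog generator: TMZ-induced
#' increments follow the reported cell-line values (396 in wild-type and
#' 378 in RAD18-null MMR-proficient cells); basal means follow the
#' qualitative ordering MLH1-/- >> MLH1+/+ and RAD18-/- > RAD18+/+; the
#' MMR-deficient double knockout gains essentially nothing from TMZ.
#' `default_signature_mix()` gives the per-arm mixture over the bundled
#' signatures: background processes only under DMSO, plus a
#' Signature-11-like component under TMZ that is larger in the RAD18-null
#' MMR-proficient arm.
#'
#' @return Named numeric vectors (means per genotype) or an arms x
#'   signatures mixture matrix.
#' @name catalog_defaults
NULL

#' @rdname catalog_defaults
#' @export
default_basal_means <- function() {
  c("RAD18+/+_MLH1+/+" = 100, "RAD18-/-_MLH1+/+" = 200,
    "RAD18+/+_MLH1-/-" = 600, "RAD18-/-_MLH1-/-" = 900)
}

#' @rdname catalog_defaults
#' @export
default_induced_means <- function() {
  c("RAD18+/+_MLH1+/+" = 396, "RAD18-/-_MLH1+/+" = 378,
    "RAD18+/+_MLH1-/-" = 420, "RAD18-/-_MLH1-/-" = 0)
}

#' @rdname catalog_defaults
#' @export
default_signature_mix <- function() {
  sigs <- colnames(synthetic_signatures())
  arms <- arm_table()
  mix <- matrix(0, nrow(arms), length(sigs),
                dimnames = list(arm_id(arms), sigs))
  for (i in seq_len(nrow(arms))) {
    if (arms$treatment[i] == "DMSO") {
      mix[i, ] <- c(TMZ11L = 0, ClockCpG = 0.35, Flat = 0.25,
                    OxoC8L = 0.2, Clock5L = 0.2)[sigs]
    } else {
      s11 <- switch(paste(arms$rad18[i], arms$mlh1[i], sep = "_"),
                    "RAD18+/+_MLH1+/+" = 0.40,
                    "RAD18-/-_MLH1+/+" = 0.65,
                    "RAD18+/+_MLH1-/-" = 0.35,
                    "RAD18-/-_MLH1-/-" = 0.40)
      rest <- (1 - s11) * c(ClockCpG = 0.35, Flat = 0.25,
                            OxoC8L = 0.2, Clock5L = 0.2)
      mix[i, ] <- c(TMZ11L = s11, rest)[sigs]
    }
  }
  mix
}

arm_table <- function() {
  expand.grid(treatment = c("DMSO", "TMZ"), mlh1 = .MLH1, rad18 = .RAD18,
              stringsAsFactors = FALSE)[, c("rad18", "mlh1", "treatment")] |>
    as_tibble()
}

arm_id <- function(arms) {
  paste(arms$rad18, arms$mlh1, arms$treatment, sep = "_")
}

#' Mutagenesis catalog design
#'
#' @param clones_per_arm Clones expanded per genotype x treatment arm
#'   (default 6).
#' @param basal_mean Named vector of expected de novo SNV counts per
#'   genotype (`"RAD18+/+_MLH1+/+"`, ...), accrued over the growth window
#'   regardless of treatment.
#' @param induced_mean Named vector of expected TMZ-added SNV counts per
#'   genotype; added to `basal_mean` in TMZ arms only.
#' @param signature_mix Matrix arms x signatures of mixture weights (rows
#'   sum to 1), rownames as produced by the default.
#' @param overdispersion NB dispersion alpha for clone totals (default
#'   0.05; 0 gives Poisson).
#' @return A `catalog_design` list with the arm table attached.
#' @export
catalog_design <- function(clones_per_arm = 6,
                           basal_mean = default_basal_means(),
                           induced_mean = default_induced_means(),
                           signature_mix = default_signature_mix(),
                           overdispersion = 0.05) {
  stopifnot(clones_per_arm >= 1, overdispersion >= 0,
            all(basal_mean >= 0), all(induced_mean >= 0))
  if (any(abs(rowSums(signature_mix) - 1) > 1e-8)) {
    abort("signature_mix rows must sum to 1")
  }
  structure(
    list(arms = arm_table(), clones_per_arm = as.integer(clones_per_arm),
         basal_mean = basal_mean, induced_mean = induced_mean,
         signature_mix = signature_mix, overdispersion = overdispersion),
    class = "catalog_design"
  )
}

#' Simulate per-clone somatic SNV catalogs with known signature exposures
#'
#' For every clone: the total de novo SNV count is drawn NB(mean =
#' basal (+ induced if TMZ), var = mu + alpha mu^2); mutations are
#' attributed to signatures by a multinomial draw from the arm's mixture;
#' each mutation's 96-context is drawn from its signature's profile. Variant
#' records are emitted with depth/VAF/supporting-read fields that pass the
#' default somatic filter chain, on a random strand representation (or at
#' real loci of a synthetic reference when one is supplied). Exactly as many
#' records are emitted per clone as its drawn total.
#'
#' @param design A [catalog_design()].
#' @param signatures 96 x K signature probability matrix (default
#'   [synthetic_signatures()]); columns referenced by
#'   `design$signature_mix`.
#' @param reference Optional [sim_context_reference()] object; when given,
#'   variant positions are genuine loci of the reference sequence so
#'   catalogs can be rebuilt by FASTA lookup.
#' @param arms Optional subset of arm rows (tibble with `rad18`, `mlh1`,
#'   `treatment`) to simulate; default all 8.
#' @param seed Integer seed.
#' @return List with `variants` (one row per emitted SNV), `truth`
#'   (per-clone drawn exposures, one column per signature, plus `total`)
#'   and `clones` (clone metadata).
#' @export
sim_mutation_catalogs <- function(design = catalog_design(),
                                  signatures = synthetic_signatures(),
                                  reference = NULL, arms = NULL, seed = NULL) {
  stopifnot(inherits(design, "catalog_design"))
  sigs <- colnames(signatures)
  if (!all(colnames(design$signature_mix) %in% sigs)) {
    abort("signature_mix references signatures absent from the matrix")
  }
  if (any(abs(colSums(signatures) - 1) > 1e-8)) {
    abort("signature columns must sum to 1")
  }
  arms <- arms %||% design$arms
  run <- function() {
    ctx_labels <- cosmic_contexts()
    variants <- list(); truth <- list(); clones <- list()
    for (i in seq_len(nrow(arms))) {
      geno <- paste(arms$rad18[i], arms$mlh1[i], sep = "_")
      aid <- paste(geno, arms$treatment[i], sep = "_")
      mu <- design$basal_mean[[geno]] +
        if (arms$treatment[i] == "TMZ") design$induced_mean[[geno]] else 0
      mix <- design$signature_mix[aid, ]
      for (k in seq_len(design$clones_per_arm)) {
        clone <- sprintf("%s_c%02d", aid, k)
        total <- rnb(1, mu, design$overdispersion)
        sig_n <- if (total > 0) {
          drop(rmultinom(1, total, mix))
        } else {
          setNames(rep(0L, length(mix)), names(mix))
        }
        ctx_idx <- unlist(lapply(names(sig_n), function(s) {
          if (sig_n[[s]] == 0) return(integer(0))
          sample.int(96, sig_n[[s]], replace = TRUE, prob = signatures[, s])
        }))
        clones[[length(clones) + 1]] <- tibble(
          sample = clone, rad18 = arms$rad18[i], mlh1 = arms$mlh1[i],
          treatment = arms$treatment[i]
        )
        truth[[length(truth) + 1]] <- bind_cols(
          tibble(sample = clone),
          as_tibble(as.list(sig_n)), tibble(total = total)
        )
        if (total > 0) {
          variants[[length(variants) + 1]] <-
            emit_variant_records(clone, ctx_labels[ctx_idx], reference)
        }
      }
    }
    list(variants = bind_rows(variants), truth = bind_rows(truth),
         clones = bind_rows(clones))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# turn drawn pyrimidine-convention 96-labels into variant records; if a
# reference is given, place each record at a genuine locus whose ref-strand
# trinucleotide matches either the pyrimidine context or its reverse
# complement (which fixes the emitted strand representation); otherwise
# attach the context directly and flip strands at random.
emit_variant_records <- function(clone, labels, reference) {
  p <- parse_context96(labels)
  ctx_py <- paste0(p$flank5, p$ref, p$flank3)
  n <- length(labels)
  if (is.null(reference)) {
    flip <- runif(n) < 0.5
    ref <- ifelse(flip, chartr("ACGT", "TGCA", p$ref), p$ref)
    alt <- ifelse(flip, chartr("ACGT", "TGCA", p$alt), p$alt)
    ctx <- ctx_py
    if (any(flip)) ctx[flip] <- revcomp(ctx_py[flip])
    chrom <- "chr1"
    pos <- sample.int(1e8, n)
  } else {
    loci <- lapply(seq_len(n), function(i) {
      fwd <- reference$index[[ctx_py[i]]]
      rc <- reference$index[[revcomp(ctx_py[i])]]
      if (is.null(fwd) && is.null(rc)) {
        abort(paste0("context with no available locus: ", ctx_py[i]))
      }
      j <- sample.int(length(fwd) + length(rc), 1)
      if (j <= length(fwd)) c(fwd[j], 0L) else c(rc[j - length(fwd)], 1L)
    })
    pos <- vapply(loci, `[`, 0L, 1)
    flip <- vapply(loci, `[`, 0L, 2) == 1L
    ref <- ifelse(flip, chartr("ACGT", "TGCA", p$ref), p$ref)
    alt <- ifelse(flip, chartr("ACGT", "TGCA", p$alt), p$alt)
    ctx <- ctx_py
    if (any(flip)) ctx[flip] <- revcomp(ctx_py[flip])
    chrom <- reference$name
  }
  depth <- 30L + rpois(n, 30)
  alt_reads <- rbinom(n, depth, 0.5)
  alt_reads <- pmin(depth, pmax(alt_reads, pmax(3L, ceiling(0.1 * depth))))
  tibble(sample = clone, chrom = chrom, pos = pos, ref = ref, alt = alt,
         depth = depth, alt_reads = alt_reads, context = ctx)
}

#' Synthetic reference sequence indexed by trinucleotide context
#'
#' A random DNA sequence long enough to contain loci for every
#' trinucleotide, with a position index by 3-mer. Used to exercise the
#' FASTA-lookup path of [build_catalog()] without a genome.
#'
#' @param length Sequence length (default 30000).
#' @param name Chromosome name (default `"chrS"`).
#' @param seed Integer seed.
#' @return A `context_reference` list with elements `seq` (character),
#'   `name` and `index` (named list of 1-based center positions per 3-mer).
#' @export
sim_context_reference <- function(length = 30000, name = "chrS", seed = NULL) {
  run <- function() {
    s <- paste(sample(.BASES, length, replace = TRUE), collapse = "")
    tri <- substring(s, seq_len(length - 2), seq_len(length - 2) + 2)
    idx <- split(seq_len(length - 2) + 1L, tri)
    missing <- setdiff(apply(expand.grid(.BASES, .BASES, .BASES), 1, paste,
                             collapse = ""), names(idx))
    if (length(missing)) {
      # append the missing trinucleotides explicitly (rare at this length)
      add <- paste(missing, collapse = "A")
      s <- paste0(s, "A", add)
      tri <- substring(s, seq_len(nchar(s) - 2), seq_len(nchar(s) - 2) + 2)
      idx <- split(seq_len(nchar(s) - 2) + 1L, tri)
    }
    structure(list(seq = s, name = name, index = idx),
              class = "context_reference")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
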