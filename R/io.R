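# Plain-text interchange: TSV schemas for library manifests, count
# matrices (with a sample-metadata sidecar), mutation catalogs, COSMIC
# v2-layout signature matrices and cohort tables; FASTQ/FASTA via
# Biostrings; known sites as VCF or 4-column TSV.

#' @rdname tsv_io
#' @export
write_library_tsv <- function(library, path) {
  readr::write_tsv(library, path)
  invisible(path)
}

#' TSV readers and writers for the pipeline's tabular formats
#'
#' Library manifests (`guide_id`, `spacer`, `gene`, `pathways`,
#' `is_control`), count matrices with a metadata sidecar, 96-row mutation
#' catalogs, and cohort tables.
#'
#' @param library,x,catalog,cohort Object to write.
#' @param path,counts_path,samples_path File paths.
#' @name tsv_io
#' @return Readers return tibbles (or a `screen_counts`); writers return
#'   the path invisibly.
#' @export
read_library_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    guide_id = "c", spacer = "c", gene = "c",
                    pathways = "c", is_control = "l"))
}

#' @rdname tsv_io
#' @export
write_counts_tsv <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "screen_counts"))
  readr::write_tsv(x$counts, counts_path)
  readr::write_tsv(x$samples, samples_path)
  invisible(counts_path)
}

#' @rdname tsv_io
#' @export
read_counts_tsv <- function(counts_path, samples_path, library = NULL) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  screen_counts(counts, samples, library = library)
}

#' @rdname tsv_io
#' @export
write_catalog_tsv <- function(catalog, path) {
  readr::write_tsv(catalog, path)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_catalog_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname tsv_io
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_cohort_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Signature matrix TSV in the COSMIC v2 layout
#'
#' First two columns `Substitution Type` (e.g. `C>T`) and `Trinucleotide`
#' (e.g. `ACG`); remaining columns one per signature. Rows may be in any
#' order on disk; reading restores the canonical 96-context order.
#'
#' @param signatures 96 x K matrix with context rownames.
#' @param path File path.
#' @return `read_signatures_tsv` returns the matrix; the writer returns the
#'   path invisibly.
#' @export
write_signatures_tsv <- function(signatures, path) {
  p <- parse_context96(rownames(signatures))
  out <- bind_cols(
    tibble(`Substitution Type` = p$class,
           Trinucleotide = paste0(p$flank5, p$ref, p$flank3)),
    as_tibble(signatures)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_signatures_tsv
#' @export
read_signatures_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- paste0(substr(d$Trinucleotide, 1, 1), "[", d$`Substitution Type`,
                   "]", substr(d$Trinucleotide, 3, 3))
  m <- as.matrix(d[setdiff(names(d), c("Substitution Type", "Trinucleotide"))])
  rownames(m) <- labels
  m[match(cosmic_contexts(), labels), , drop = FALSE]
}

#' Write simulated reads to FASTQ
#'
#' @param reads Tibble from [sim_cassette_reads()] (`read_id`, `seq`).
#' @param path Output path (`.gz` accepted).
#' @return The path, invisibly. Qualities are constant.
#' @export
write_reads_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(ss)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write a context reference to FASTA
#'
#' @param reference A `context_reference` from [sim_context_reference()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(setNames(reference$seq, reference$name))
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' Read somatic variant records from a VCF
#'
#' Extracts `chrom`, `pos`, `ref`, `alt`, the caller `filter` column, and
#' per-sample `depth` (FORMAT `DP`) and alt-supporting reads (second field
#' of FORMAT `AD`). Multi-allelic records are split into biallelic rows
#' (the AD field is indexed per alternate allele).
#'
#' @param path VCF file (v4.2; plain or gzipped).
#' @return Tibble with one row per sample x biallelic variant.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix(v)
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  samples <- colnames(dp)
  out <- list()
  for (s in samples) {
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    ads <- strsplit(ad[, s], ",", fixed = TRUE)
    for (i in seq_along(alts)) {
      for (j in seq_along(alts[[i]])) {
        out[[length(out) + 1]] <- tibble(
          sample = s, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[[i]][j],
          depth = as.integer(dp[i, s]),
          alt_reads = as.integer(ads[[i]][j + 1]),
          filter = fix$FILTER[i]
        )
      }
    }
  }
  bind_rows(out)
}

# fixed VCF columns as a data frame (vcfR returns a bare vector for
# single-record files)
vcf_fix <- function(v) {
  f <- vcfR::getFIX(v)
  if (is.null(dim(f))) f <- t(f)
  as.data.frame(f, stringsAsFactors = FALSE)
}

#' Read exon regions from a BED file
#'
#' Standard 0-based half-open BED intervals; only the first three columns
#' are used.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = "cii", col_select = 1:3,
                  comment = "#")
}

#' Read known polymorphism sites
#'
#' Accepts a VCF (matching tuples taken from CHROM/POS/REF/ALT) or a
#' 4-column TSV (`chrom`, `pos`, `ref`, `alt`).
#'
#' @param path File path.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @export
read_known_sites <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf_fix(v)
    out <- list()
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    for (i in seq_along(alts)) {
      out[[length(out) + 1]] <- tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[[i]])
    }
    return(bind_rows(out))
  }
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", pos = "i",
                                          ref = "c", alt = "c"))
}
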