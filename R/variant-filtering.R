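# Post-calling somatic filter chain and mutation-catalog construction.
# Thresholds are inclusive at the stated boundaries (VAF >= 10%, depth >=
# 10x, supporting reads >= 3); indels longer than 10 bp are removed; known
# polymorphisms match on exact (chrom, pos, ref, alt) tuples; exon overlap
# uses standard BED semantics (0-based half-open) against the 1-based
# variant start. Filters are a conjunction: the order affects only the
# removal tally, never the surviving set.

#' Apply the somatic post-calling filter chain
#'
#' A record survives iff all of: caller FILTER is PASS (when a `filter`
#' column is present and `pass_only = TRUE`); VAF = alt/depth >= `maf`;
#' depth >= `min_depth`; supporting reads >= `min_alt`; if an indel, length
#' <= `max_indel_len`; not an exact known-site tuple; variant start inside
#' an exon interval (when regions are given).
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_reads` (and optionally `sample`, `filter`, `context`).
#' @param known_sites Optional tibble of known polymorphisms with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @param exon_regions Optional BED-style tibble with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param maf Minimum variant allele fraction (default 0.10, inclusive).
#' @param min_depth Minimum total depth (default 10, inclusive).
#' @param min_alt Minimum alt-supporting reads (default 3, inclusive).
#' @param max_indel_len Longest indel retained (default 10; longer removed).
#' @param pass_only Honor an existing caller `filter` column by keeping only
#'   `"PASS"` records (default `TRUE`).
#' @return List with `variants` (surviving records) and `tally` (tibble
#'   `filter`, `removed`: removals attributed to the first failing test, in
#'   order).
#' @export
apply_filter_chain <- function(variants, known_sites = NULL,
                               exon_regions = NULL, maf = 0.10,
                               min_depth = 10, min_alt = 3,
                               max_indel_len = 10, pass_only = TRUE) {
  stopifnot(maf >= 0, min_depth >= 0, min_alt >= 0)
  v <- as_tibble(variants)
  if (any(v$depth == 0)) abort("record with zero depth")
  if (any(v$alt_reads > v$depth)) {
    abort("malformed record: alt-supporting reads exceed depth")
  }
  indel_len <- abs(nchar(v$ref) - nchar(v$alt))
  fails <- list()
  fails[["caller_filter"]] <- if (pass_only && "filter" %in% names(v)) {
    !is.na(v$filter) & v$filter != "PASS"
  } else rep(FALSE, nrow(v))
  fails[["allele_frequency"]] <- v$alt_reads / v$depth < maf
  fails[["coverage"]] <- v$depth < min_depth
  fails[["supporting_reads"]] <- v$alt_reads < min_alt
  fails[["indel_length"]] <- indel_len > max_indel_len
  fails[["known_site"]] <- if (!is.null(known_sites)) {
    key <- paste(v$chrom, v$pos, v$ref, v$alt)
    key %in% paste(known_sites$chrom, known_sites$pos,
                   known_sites$ref, known_sites$alt)
  } else rep(FALSE, nrow(v))
  fails[["exon_overlap"]] <- if (!is.null(exon_regions)) {
    if (any(exon_regions$end <= exon_regions$start)) {
      abort("malformed interval: end <= start")
    }
    !in_intervals(v$chrom, v$pos, exon_regions)
  } else rep(FALSE, nrow(v))
  fail_mat <- do.call(cbind, fails)
  first_fail <- apply(fail_mat, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  tally <- tibble(
    filter = names(fails),
    removed = vapply(seq_along(fails),
                     function(j) sum(first_fail == j, na.rm = TRUE), 0L)
  )
  list(variants = v[is.na(first_fail), ], tally = tally)
}

# 1-based point pos inside any 0-based half-open [start, end) interval:
# pos > start and pos <= end
in_intervals <- function(chrom, pos, bed) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    b <- bed[bed$chrom == ch, ]
    i <- which(chrom == ch)
    if (nrow(b) == 0) next
    out[i] <- vapply(pos[i], function(p) any(p > b$start & p <= b$end), TRUE)
  }
  out
}

#' Build a 96-context mutation catalog from variant records
#'
#' Counts passing SNVs by sample and canonical pyrimidine-convention
#' context. Contexts come either from an attached `context` column or by
#' lookup in a reference sequence; both paths give identical catalogs on
#' the same records. Indels are excluded; column sums equal the number of
#' catalogued SNVs per sample.
#'
#' @param variants Tibble of (filtered) variant records with `sample`,
#'   `chrom`, `pos`, `ref`, `alt` and either a `context` column or a
#'   reference.
#' @param reference Optional reference: a `context_reference`, a named
#'   character vector of chromosome sequences, or a FASTA path.
#' @return Tibble with a `context` column (all 96 canonical labels, in
#'   order) plus one count column per sample. A `skipped` attribute tallies
#'   records dropped at chromosome edges.
#' @export
build_catalog <- function(variants, reference = NULL) {
  v <- as_tibble(variants)
  snv <- nchar(v$ref) == 1 & nchar(v$alt) == 1
  v <- v[snv, ]
  skipped <- 0L
  if (!is.null(reference)) {
    seqs <- reference_seqs(reference)
    ctx <- rep(NA_character_, nrow(v))
    for (ch in unique(v$chrom)) {
      if (!ch %in% names(seqs)) abort(paste0("chromosome not in reference: ", ch))
      i <- which(v$chrom == ch)
      L <- nchar(seqs[[ch]])
      edge <- v$pos[i] < 2 | v$pos[i] > L - 1
      if (any(!edge)) {
        ctx[i[!edge]] <- substring(seqs[[ch]], v$pos[i[!edge]] - 1,
                                   v$pos[i[!edge]] + 1)
      }
    }
    if (anyNA(ctx)) {
      skipped <- sum(is.na(ctx))
      warn(sprintf("%d record(s) at chromosome edges skipped", skipped))
      v <- v[!is.na(ctx), ]
      ctx <- ctx[!is.na(ctx)]
    }
    mismatch <- substr(ctx, 2, 2) != v$ref
    if (any(mismatch)) abort("reference base does not match record ref allele")
    v$context <- ctx
  }
  if (!"context" %in% names(v)) abort("no context column and no reference given")
  labels <- cosmic_contexts()
  if (nrow(v) == 0) {
    out <- tibble(context = labels)
    attr(out, "skipped") <- skipped
    return(out)
  }
  cls <- classify_snv(v$ref, v$alt, v$context)
  samples <- unique(v$sample)
  out <- tibble(context = labels)
  for (s in samples) {
    out[[s]] <- as.integer(table(factor(cls$context96[v$sample == s],
                                        levels = labels)))
  }
  attr(out, "skipped") <- skipped
  out
}

reference_seqs <- function(reference) {
  if (inherits(reference, "context_reference")) {
    return(setNames(reference$seq, reference$name))
  }
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    return(setNames(as.character(ss), sub("\\s.*", "", names(ss))))
  }
  if (is.character(reference) && !is.null(names(reference))) return(reference)
  abort("unsupported reference type")
}

#' Pattern I / Pattern II decomposition of SNV classes
#'
#' Partitions catalogued SNVs into Pattern I (C>T, attributed to O6-methyl
#' guanine mispairing) and Pattern II (the other five classes, attributed
#' to N7-methyl guanine and N3-methyl adenine). The two patterns always sum
#' to the total SNV count.
#'
#' @param x A catalog from [build_catalog()] (context column + sample
#'   columns) or a tibble with columns `sample`, `class`, `n`.
#' @return Tibble with columns `sample`, `pattern_I`, `pattern_II`, `total`.
#' @export
pattern_decomposition <- function(x) {
  if ("context" %in% names(x)) {
    cls <- parse_context96(x$context)$class
    samples <- setdiff(names(x), "context")
    return(bind_rows(lapply(samples, function(s) {
      tibble(sample = s,
             pattern_I = sum(x[[s]][cls == "C>T"]),
             pattern_II = sum(x[[s]][cls != "C>T"]),
             total = sum(x[[s]]))
    })))
  }
  stopifnot(all(c("sample", "class", "n") %in% names(x)))
  x |>
    group_by(.data$sample) |>
    summarise(pattern_I = sum(.data$n[.data$class == "C>T"]),
              pattern_II = sum(.data$n[.data$class != "C>T"]),
              total = sum(.data$n), .groups = "drop")
}
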