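# Guide quantification: FASTQ -> raw count matrix -> normalized counts.
# Spacer matching is exact by default; a one-mismatch mode exists behind a
# flag. All downstream statistics are invariant to the normalization
# constant by construction.

#' Screen count container
#'
#' A light container bundling the guides x samples count table with its
#' per-sample metadata and, optionally, the library manifest.
#'
#' @param counts Tibble with a `guide_id` column plus one numeric column per
#'   sample. Raw counts must be non-negative integers.
#' @param samples Tibble with columns `sample`, `genotype`, `treatment`,
#'   `timepoint`, `replicate` describing each count column.
#' @param library Optional library manifest (see [sim_library()]).
#' @param normalized Whether the values are normalized (default `FALSE`).
#' @param constant Normalization constant, `NA` for raw counts.
#' @return A `screen_counts` object.
#' @export
screen_counts <- function(counts, samples, library = NULL,
                          normalized = FALSE, constant = NA_real_) {
  stopifnot(is.data.frame(counts), "guide_id" %in% names(counts))
  sample_cols <- setdiff(names(counts), "guide_id")
  if (anyDuplicated(counts$guide_id)) abort("duplicate guide ids")
  if (anyDuplicated(sample_cols)) abort("duplicate sample ids")
  missing <- setdiff(sample_cols, samples$sample)
  if (length(missing)) {
    abort(paste0("samples metadata missing: ", paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(counts[sample_cols])
  if (any(vals < 0)) abort("negative counts")
  if (!normalized && any(vals != round(vals))) abort("raw counts must be integers")
  structure(
    list(counts = as_tibble(counts),
         samples = as_tibble(samples[match(sample_cols, samples$sample), ]),
         library = library, normalized = normalized, constant = constant),
    class = "screen_counts"
  )
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("<screen_counts> %d guides x %d samples (%s)\n",
              nrow(x$counts), nrow(x$samples),
              if (x$normalized) sprintf("normalized to %g", x$constant) else "raw"))
  print(x$samples, n = 6)
  invisible(x)
}

# read sequences from a tibble (read_id, seq), character vector, or FASTQ path
as_read_seqs <- function(reads) {
  if (is.data.frame(reads)) return(reads$seq)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    return(as.character(Biostrings::readDNAStringSet(reads, format = "fastq")))
  }
  as.character(reads)
}

#' Count guide cassettes in reads
#'
#' A read increments exactly one guide iff it contains the 5' flank, the
#' full spacer (exact match by default) and the start of the 3' flank;
#' anything else is tallied as unmapped. Mapped + unmapped always equals the
#' number of input reads.
#'
#' @param reads FASTQ file path, character vector of sequences, or the
#'   tibble returned by [sim_cassette_reads()].
#' @param library Library manifest with unique spacers.
#' @param flank5,flank3 Universal flanking sequences.
#' @param max_mismatch 0 (exact, default) or 1 (tolerate one substitution in
#'   the spacer).
#' @param revcomp_reads Also search the reverse complement of each read
#'   (default `FALSE`).
#' @return A list with `counts` (tibble `guide_id`, `count`, one row per
#'   library guide), `unmapped` and `total`.
#' @export
count_guides <- function(reads, library, flank5 = default_flanks()[["flank5"]],
                         flank3 = default_flanks()[["flank3"]],
                         max_mismatch = 0, revcomp_reads = FALSE) {
  stopifnot(nzchar(flank5), nzchar(flank3), max_mismatch %in% c(0, 1))
  if (anyDuplicated(library$spacer)) abort("two guides share a spacer")
  seqs <- as_read_seqs(reads)
  spacer_len <- unique(nchar(library$spacer))
  stopifnot(length(spacer_len) == 1)
  if (length(seqs) == 0) {
    warn("no reads: returning empty counts")
    return(list(counts = tibble(guide_id = library$guide_id, count = 0L),
                unmapped = 0L, total = 0L))
  }
  lookup <- seq_len(nrow(library))
  names(lookup) <- library$spacer
  extract_hits <- function(ss) {
    pos <- regexpr(flank5, ss, fixed = TRUE)
    cand <- ifelse(pos > 0,
                   substr(ss, pos + nchar(flank5), pos + nchar(flank5) + spacer_len - 1),
                   NA_character_)
    after <- ifelse(pos > 0,
                    substr(ss, pos + nchar(flank5) + spacer_len,
                           pos + nchar(flank5) + spacer_len + nchar(flank3) - 1),
                    NA_character_)
    ok3 <- !is.na(after) & nzchar(after) &
      after == substr(flank3, 1, nchar(after))
    cand[!ok3 | nchar(cand) < spacer_len] <- NA_character_
    idx <- unname(lookup[cand])
    if (max_mismatch == 1) {
      miss <- which(!is.na(cand) & is.na(idx))
      for (i in miss) idx[i] <- match_one_mismatch(cand[i], lookup, spacer_len)
    }
    idx
  }
  idx <- extract_hits(seqs)
  if (revcomp_reads) {
    need <- is.na(idx)
    if (any(need)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[need])))
      idx[need] <- extract_hits(rc)
    }
  }
  tab <- tabulate(idx[!is.na(idx)], nbins = nrow(library))
  list(counts = tibble(guide_id = library$guide_id, count = as.integer(tab)),
       unmapped = sum(is.na(idx)), total = length(seqs))
}

# hamming<=1 spacer lookup by neighborhood enumeration
match_one_mismatch <- function(cand, lookup, spacer_len) {
  for (p in seq_len(spacer_len)) {
    b <- substr(cand, p, p)
    for (nb in setdiff(.BASES, b)) {
      alt <- cand
      substr(alt, p, p) <- nb
      hit <- lookup[alt]
      if (!is.na(hit)) return(unname(hit))
    }
  }
  NA_integer_
}

#' Assemble a screen_counts object from per-sample counting results
#'
#' @param count_list Named list of [count_guides()] results (or plain
#'   `guide_id`/`count` tibbles), names = sample ids.
#' @param samples Sample metadata tibble.
#' @param library Optional library manifest.
#' @return A raw `screen_counts` object.
#' @export
assemble_counts <- function(count_list, samples, library = NULL) {
  tabs <- lapply(count_list, function(x) if (is.data.frame(x)) x else x$counts)
  guide_id <- tabs[[1]]$guide_id
  counts <- tibble(guide_id = guide_id)
  for (nm in names(tabs)) {
    stopifnot(identical(tabs[[nm]]$guide_id, guide_id))
    counts[[nm]] <- tabs[[nm]]$count
  }
  screen_counts(counts, samples, library = library)
}

#' Normalize a count matrix to a fixed per-sample total
#'
#' Scales each sample column so it sums to `constant` (counts-per-10-million
#' by default). Order of guides within a sample is preserved; every
#' downstream statistic in the package is invariant to the constant.
#'
#' @param x A `screen_counts` object or a tibble with `guide_id` plus
#'   numeric sample columns.
#' @param constant Target column sum (default 1e7).
#' @return Same shape as the input, with normalized values.
#' @export
normalize_counts <- function(x, constant = 1e7) {
  stopifnot(constant > 0)
  tab <- if (inherits(x, "screen_counts")) x$counts else x
  sample_cols <- setdiff(names(tab), "guide_id")
  totals <- vapply(tab[sample_cols], sum, 0)
  if (any(totals == 0)) {
    abort(paste0("sample(s) with all-zero counts: ",
                 paste(sample_cols[totals == 0], collapse = ", ")))
  }
  for (j in seq_along(sample_cols)) {
    tab[[sample_cols[j]]] <- tab[[sample_cols[j]]] / totals[j] * constant
  }
  if (inherits(x, "screen_counts")) {
    x$counts <- tab
    x$normalized <- TRUE
    x$constant <- constant
    x
  } else {
    tab
  }
}
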