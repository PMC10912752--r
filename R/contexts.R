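# 96-channel trinucleotide context machinery shared by the catalog and
# signature modules. Contexts follow the pyrimidine convention: every SNV is
# represented with a C or T reference, reverse-complementing purine-reference
# records, and the 96 categories are ordered as in the COSMIC v2 layout
# (six substitution classes, then the 16 flank pairs alphabetically).

.BASES <- c("A", "C", "G", "T")

#' Six single-base substitution classes
#'
#' The six pyrimidine-reference substitution classes, in canonical order.
#'
#' @return Character vector `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
snv_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Canonical 96 trinucleotide context labels
#'
#' Labels of the form `"A[C>A]A"`, ordered by substitution class then
#' alphabetically by flanking bases, matching the COSMIC v2 ordering.
#'
#' @return Character vector of length 96.
#' @export
cosmic_contexts <- function() {
  unlist(lapply(snv_classes(), function(cl) {
    as.vector(t(outer(.BASES, .BASES, function(f5, f3) {
      paste0(f5, "[", cl, "]", f3)
    })))
  }))
}

# reverse complement of short upper-case DNA strings, vectorized
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, ""), function(b) paste(rev(b), collapse = ""), "")
}

#' Classify an SNV into its pyrimidine-convention class and 96-context label
#'
#' Records with a purine reference base (A or G) are reverse-complemented:
#' both alleles and the trinucleotide context are flipped so that the
#' reference is always a pyrimidine (C or T). The operation is strand
#' symmetric: a variant and its reverse-complement representation map to the
#' same class and label.
#'
#' @param ref,alt Single reference and alternate bases (vectorized).
#' @param context Reference-strand trinucleotide (3 bases) with `ref` at its
#'   center.
#' @return A tibble with columns `class` (one of [snv_classes()]) and
#'   `context96` (one of [cosmic_contexts()]).
#' @export
#' @examples
#' classify_snv("G", "A", "TGC")  # -> C>T in G[C]A
classify_snv <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  bad <- !ref %in% .BASES | !alt %in% .BASES
  if (any(bad)) {
    abort(paste0("non-ACGT base in record(s): ", paste(which(bad), collapse = ", ")))
  }
  if (any(ref == alt)) {
    abort("ref equals alt: not a variant")
  }
  if (any(nchar(context) != 3L) || any(substr(context, 2, 2) != ref)) {
    abort("context must be 3 bases with the reference allele at its center")
  }
  flip <- ref %in% c("A", "G")
  ref2 <- ifelse(flip, chartr("ACGT", "TGCA", ref), ref)
  alt2 <- ifelse(flip, chartr("ACGT", "TGCA", alt), alt)
  ctx2 <- context
  if (any(flip)) ctx2[flip] <- revcomp(context[flip])
  cls <- paste0(ref2, ">", alt2)
  tibble(
    class = cls,
    context96 = paste0(substr(ctx2, 1, 1), "[", cls, "]", substr(ctx2, 3, 3))
  )
}

# parse "A[C>T]G" labels into components (internal)
parse_context96 <- function(label) {
  tibble(
    flank5 = substr(label, 1, 1),
    ref = substr(label, 3, 3),
    alt = substr(label, 5, 5),
    flank3 = substr(label, 7, 7),
    class = substr(label, 3, 5)
  )
}
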