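# Signature refitting by non-negative least squares, hypermutation
# classification on Signature-11-style counts, and Tukey-adjusted pairwise
# group comparisons.

#' Bundled synthetic 96-channel signature matrix
#'
#' Five synthetic single-base-substitution profiles for tests and examples,
#' so no external signature download is needed:
#' `TMZ11L` (Signature-11-like: C>T concentrated at non-CpG contexts, the
#' footprint of alkylating-agent exposure), `ClockCpG` (C>T at CpG,
#' deamination-clock-like), `Flat` (uniform), `OxoC8L` (C>A-heavy) and
#' `Clock5L` (T>C-heavy). Columns are probability vectors over the 96
#' canonical contexts.
#'
#' @return A 96 x 5 numeric matrix with rownames [cosmic_contexts()].
#' @export
synthetic_signatures <- function() {
  labels <- cosmic_contexts()
  p <- parse_context96(labels)
  w <- function(weights) weights / sum(weights)
  tmz11 <- rep(0.05 / 96, 96)
  non_cpg_ct <- p$class == "C>T" & p$flank3 != "G"
  # unequal 5' preference, as real alkylation signatures skew by 5' base
  pref <- c(A = 0.3, C = 0.25, G = 0.25, T = 0.2)[p$flank5[non_cpg_ct]]
  tmz11[non_cpg_ct] <- tmz11[non_cpg_ct] + 0.95 * w(pref)
  clock_cpg <- rep(0.10 / 96, 96)
  cpg_ct <- p$class == "C>T" & p$flank3 == "G"
  clock_cpg[cpg_ct] <- clock_cpg[cpg_ct] + 0.90 / sum(cpg_ct)
  flat <- rep(1 / 96, 96)
  oxo <- rep(0.20 / 96, 96)
  oxo[p$class == "C>A"] <- oxo[p$class == "C>A"] + 0.80 / 16
  clock5 <- rep(0.20 / 96, 96)
  clock5[p$class == "T>C"] <- clock5[p$class == "T>C"] + 0.80 / 16
  m <- cbind(TMZ11L = tmz11, ClockCpG = clock_cpg, Flat = flat,
             OxoC8L = oxo, Clock5L = clock5)
  rownames(m) <- labels
  m
}

# coerce a catalog (tibble context + samples, or matrix) to a matrix whose
# rows are checked against the signature row order
catalog_matrix <- function(catalog) {
  if (is.matrix(catalog)) return(catalog)
  stopifnot("context" %in% names(catalog))
  m <- as.matrix(catalog[setdiff(names(catalog), "context")])
  rownames(m) <- catalog$context
  m
}

#' Fit signature exposures by non-negative least squares
#'
#' Per sample, finds exposures `e >= 0` minimizing `||m - S e||_2`
#' (Lawson-Hanson active set; deterministic). Exposures are reported in
#' mutation counts attributed to each signature, not proportions.
#'
#' @param catalog Mutation catalog: tibble from [build_catalog()] or a
#'   96 x samples matrix with context rownames.
#' @param signatures 96 x K signature probability matrix with matching
#'   context rownames (default [synthetic_signatures()]).
#' @return An `exposure_fit`: tibble with `sample`, one exposure column per
#'   signature and `residual` (Euclidean residual norm). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
fit_exposures <- function(catalog, signatures = synthetic_signatures()) {
  m <- catalog_matrix(catalog)
  if (!identical(rownames(m), rownames(signatures))) {
    abort("catalog and signature contexts do not match (order matters)")
  }
  if (any(signatures < 0) || any(abs(colSums(signatures) - 1) > 1e-8)) {
    abort("signature columns must be probability vectors summing to 1")
  }
  fits <- lapply(seq_len(ncol(m)), function(j) {
    f <- pracma::lsqnonneg(signatures, m[, j])
    c(f$x, sqrt(max(f$resid.norm, 0)))
  })
  out <- as_tibble(do.call(rbind, fits), .name_repair = "minimal")
  names(out) <- c(colnames(signatures), "residual")
  out <- bind_cols(tibble(sample = colnames(m)), out)
  class(out) <- c("exposure_fit", class(out))
  attr(out, "signatures") <- colnames(signatures)
  out
}

#' @method tidy exposure_fit
#' @export
tidy.exposure_fit <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[c("sample", attr(x, "signatures"))],
                      -"sample", names_to = "signature",
                      values_to = "exposure")
}

#' @method glance exposure_fit
#' @export
glance.exposure_fit <- function(x, ...) {
  tibble(n_samples = nrow(x), n_signatures = length(attr(x, "signatures")),
         total_exposure = sum(as.matrix(x[attr(x, "signatures")])),
         rss = sum(x$residual^2))
}

#' Classify samples as hypermutant by signature-attributed counts
#'
#' A sample is hypermutant iff its exposure on the given signature is
#' strictly greater than the threshold (default 500 mutations, the
#' convention for Signature-11 hypermutation; a count of exactly 500 is
#' not hypermutant).
#'
#' @param exposures An `exposure_fit` or tibble with `sample` and signature
#'   columns.
#' @param signature Signature column name (default `"TMZ11L"`).
#' @param threshold Strict lower bound (default 500).
#' @return Tibble with `sample`, `exposure`, `hypermutant`.
#' @export
classify_hypermutation <- function(exposures, signature = "TMZ11L",
                                   threshold = 500) {
  if (!signature %in% names(exposures)) {
    abort(paste0("signature not present: ", signature))
  }
  tibble(sample = exposures$sample,
         exposure = exposures[[signature]],
         hypermutant = exposures[[signature]] > threshold)
}

#' Pairwise group comparisons with Tukey HSD adjustment
#'
#' One-way layout: pairwise mean differences with pooled within-group
#' variance, t statistics, and p-values from the studentized-range
#' distribution with k groups and N - k error df (Tukey-Kramer for unequal
#' sizes). For k = 2 the adjusted p equals the ordinary pooled two-sided
#' t-test p.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the response and the
#'   group label.
#' @return Tibble with `group1`, `group2`, `diff` (group1 - group2), `se`,
#'   `statistic` (t), `p_adj`.
#' @export
compare_groups <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2) abort("need at least two groups")
  ns <- tapply(v, g, length)
  if (any(ns < 2)) abort("every group needs at least two values")
  ms <- tapply(v, g, mean)
  s2p <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / (sum(ns) - k)
  df_err <- sum(ns) - k
  pairs <- utils::combn(levels(g), 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- ms[[a]] - ms[[b]]
    se <- sqrt(s2p * (1 / ns[[a]] + 1 / ns[[b]]))
    if (s2p == 0) {
      warn("zero pooled variance; p set by convention")
      p <- if (d == 0) 1 else 0
      tstat <- if (d == 0) 0 else Inf * sign(d)
    } else {
      tstat <- d / se
      p <- ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df_err,
                  lower.tail = FALSE)
    }
    tibble(group1 = a, group2 = b, diff = unname(d), se = unname(se),
           statistic = unname(tstat), p_adj = p)
  })
  bind_rows(out)
}
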