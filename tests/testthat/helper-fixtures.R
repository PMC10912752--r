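# Shared fixtures and independent oracles used across test files.

# A minimal normalized screen_counts object built directly from per-arm
# PD0/PD20 values: `guides` is a library tibble, `values` a named list
# sample -> numeric vector.
make_counts <- function(guides, values, samples, normalized = TRUE) {
  counts <- tibble::tibble(guide_id = guides$guide_id)
  for (nm in names(values)) counts[[nm]] <- values[[nm]]
  x <- screen_counts(counts, samples, library = guides,
                     normalized = normalized,
                     constant = if (normalized) NA_real_ else NA_real_)
  x$normalized <- normalized
  x
}

tiny_library <- function(genes, guides_per_gene = 1, n_controls = 0) {
  pm <- tibble::tibble(gene = genes, pathway = "P1")
  sim_library(n_genes = length(genes), guides_per_gene = guides_per_gene,
              n_controls = n_controls, pathway_map = pm, seed = 99)
}

# textbook paired t-test (mean difference / (sd(d)/sqrt(n)), t with n-1 df)
oracle_paired_t_p <- function(a, b) {
  d <- a - b
  tval <- mean(d) / (sd(d) / sqrt(length(d)))
  2 * stats::pt(-abs(tval), df = length(d) - 1)
}

# grid-search NNLS oracle for K = 2: minimize ||m - S e|| over a fine grid
# of total scale x simplex fraction
oracle_nnls2 <- function(S, m, scale_grid = NULL, frac_step = 1e-3) {
  stopifnot(ncol(S) == 2)
  total <- sum(m)
  if (is.null(scale_grid)) total_grid <- seq(0.8, 1.2, by = 0.001) * total
  else total_grid <- scale_grid
  best <- c(NA, NA); best_r <- Inf
  for (tt in total_grid) {
    for (f in seq(0, 1, by = frac_step)) {
      e <- c(f, 1 - f) * tt
      r <- sum((m - S %*% e)^2)
      if (r < best_r) { best_r <- r; best <- e }
    }
  }
  list(e = best, rss = best_r)
}

# closed-form pooled two-sample t-test p (equal-variance)
oracle_pooled_t_p <- function(a, b) {
  stats::t.test(a, b, var.equal = TRUE)$p.value
}
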