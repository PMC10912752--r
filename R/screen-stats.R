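# Dropout-screen statistics: per-guide log2 fold changes, SigmaFC gene
# ranking, permutation p-values against the non-targeting-control pool,
# two-sample gene Z-statistics (TMZ vs DMSO) and their pathway-level
# combination Z_P = sum(X_g) / sqrt(sum(S_g^2)), which is standard normal
# under the null, plus the paired-t / pooled-log2FC pathway dropout summary.

#' Per-guide log2 fold changes between timepoints
#'
#' For each guide in each (genotype, treatment, replicate) arm, computes
#' `log2((PD20 + c) / (PD0 + c))` on normalized counts. The pseudocount `c`
#' guards guides that drop to zero.
#'
#' @param x A normalized `screen_counts` object.
#' @param library Library manifest; defaults to `x$library`.
#' @param pseudocount Added to both timepoints before the ratio (default 1).
#' @return Tibble with columns `guide_id`, `gene`, `is_control`, `genotype`,
#'   `treatment`, `replicate`, `lfc`.
#' @export
guide_lfc <- function(x, library = NULL, pseudocount = 1) {
  stopifnot(inherits(x, "screen_counts"))
  if (!x$normalized) warn("counts are not normalized; LFCs depend on depth")
  library <- library %||% x$library
  if (is.null(library)) abort("a library manifest is required")
  smp <- x$samples
  tps <- sort(unique(smp$timepoint))
  if (length(tps) != 2) abort("exactly two timepoints are required")
  t0 <- tps[order(match(tps, c("PD0", "PD20")))][1]
  t1 <- setdiff(tps, t0)
  arms <- distinct(smp[, c("genotype", "treatment", "replicate")])
  out <- vector("list", nrow(arms))
  for (i in seq_len(nrow(arms))) {
    sel <- smp$genotype == arms$genotype[i] &
      smp$treatment == arms$treatment[i] &
      smp$replicate == arms$replicate[i]
    s0 <- smp$sample[sel & smp$timepoint == t0]
    s1 <- smp$sample[sel & smp$timepoint == t1]
    if (length(s0) != 1 || length(s1) != 1) {
      abort(sprintf("arm (%s, %s, rep %s) is missing a timepoint",
                    arms$genotype[i], arms$treatment[i], arms$replicate[i]))
    }
    out[[i]] <- tibble(
      guide_id = x$counts$guide_id,
      genotype = arms$genotype[i], treatment = arms$treatment[i],
      replicate = arms$replicate[i],
      lfc = log2((x$counts[[s1]] + pseudocount) /
                   (x$counts[[s0]] + pseudocount))
    )
  }
  bind_rows(out) |>
    left_join(library[, c("guide_id", "gene", "is_control")], by = "guide_id") |>
    select("guide_id", "gene", "is_control", "genotype", "treatment",
           "replicate", "lfc")
}

#' SigmaFC gene scores
#'
#' The SigmaFC (SUMLFC) score of a gene in an arm is the sum over its guides
#' of the replicate-mean log2 fold change. Note the documented scale
#' dependence: doubling the number of guides with identical LFCs doubles
#' the score.
#'
#' @param lfc Guide LFC table from [guide_lfc()].
#' @return Tibble with columns `gene`, `genotype`, `treatment`, `n_guides`,
#'   `sigma_fc`, one row per targeted gene per arm.
#' @export
gene_sigma_fc <- function(lfc) {
  lfc |>
    filter(!.data$is_control) |>
    group_by(.data$gene, .data$genotype, .data$treatment, .data$guide_id) |>
    summarise(g_lfc = mean(.data$lfc), .groups = "drop") |>
    group_by(.data$gene, .data$genotype, .data$treatment) |>
    summarise(n_guides = dplyr::n(), sigma_fc = sum(.data$g_lfc),
              .groups = "drop")
}

#' Permutation p-values against the non-targeting-control pool
#'
#' For each gene, the null distribution of SigmaFC is built by resampling
#' `m` control guides without replacement `B` times from the arm's
#' non-targeting pool and summing their replicate-mean LFCs. The two-sided
#' empirical p-value uses the +1 correction,
#' `p = (1 + #\{|null| >= |observed|\}) / (B + 1)`, so its lower bound
#' `1/(B+1)` is attained and it is never zero.
#'
#' @param scores Gene scores from [gene_sigma_fc()].
#' @param lfc Guide LFC table (supplies the control-guide pool).
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return `scores` with a `perm_p` column added.
#' @export
permutation_pvalue <- function(scores, lfc, B = 10000, seed = NULL) {
  stopifnot(B >= 1)
  run <- function() {
    ctrl <- lfc |>
      filter(.data$is_control) |>
      group_by(.data$genotype, .data$treatment, .data$guide_id) |>
      summarise(g_lfc = mean(.data$lfc), .groups = "drop")
    arms <- distinct(scores[, c("genotype", "treatment")])
    out <- vector("list", nrow(arms))
    for (i in seq_len(nrow(arms))) {
      pool <- ctrl$g_lfc[ctrl$genotype == arms$genotype[i] &
                           ctrl$treatment == arms$treatment[i]]
      sc <- scores[scores$genotype == arms$genotype[i] &
                     scores$treatment == arms$treatment[i], ]
      sc$perm_p <- NA_real_
      for (m in unique(sc$n_guides)) {
        if (length(pool) < m) {
          abort(sprintf("fewer control guides (%d) than guides per gene (%d)",
                        length(pool), m))
        }
        null_sigma <- vapply(seq_len(B),
                             function(b) sum(sample(pool, m)), 0)
        rows <- sc$n_guides == m
        sc$perm_p[rows] <- vapply(sc$sigma_fc[rows], function(obs) {
          (1 + sum(abs(null_sigma) >= abs(obs))) / (B + 1)
        }, 0)
      }
      out[[i]] <- sc
    }
    bind_rows(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Two-sample gene Z-statistic (treatment vs control arm)
#'
#' For each gene within a genotype, pools guide x replicate LFC observations
#' and computes `X_g` (difference of sample means, treatment minus control),
#' `S_g` (standard error of that difference, Welch form
#' `sqrt(var_T/n_T + var_D/n_D)`) and `Z_g = X_g / S_g`. An alternative
#' pooling collapses replicates to one mean per guide first.
#'
#' @param lfc Guide LFC table.
#' @param treatment_case,treatment_ref Treatment labels to contrast
#'   (defaults `"TMZ"` vs `"DMSO"`).
#' @param pooling `"observations"` (guide x replicate units, default) or
#'   `"guide_means"` (replicate-mean per guide).
#' @return Tibble with columns `gene`, `genotype`, `n_case`, `n_ref`, `x`,
#'   `s`, `z`.
#' @export
gene_zstat <- function(lfc, treatment_case = "TMZ", treatment_ref = "DMSO",
                       pooling = c("observations", "guide_means")) {
  pooling <- match.arg(pooling)
  dat <- filter(lfc, !.data$is_control,
                .data$treatment %in% c(treatment_case, treatment_ref))
  if (pooling == "guide_means") {
    dat <- dat |>
      group_by(.data$gene, .data$genotype, .data$treatment, .data$guide_id) |>
      summarise(lfc = mean(.data$lfc), .groups = "drop")
  }
  dat |>
    group_by(.data$gene, .data$genotype) |>
    summarise(
      n_case = sum(.data$treatment == treatment_case),
      n_ref = sum(.data$treatment == treatment_ref),
      x = mean(.data$lfc[.data$treatment == treatment_case]) -
        mean(.data$lfc[.data$treatment == treatment_ref]),
      s = sqrt(var(.data$lfc[.data$treatment == treatment_case]) / .data$n_case +
                 var(.data$lfc[.data$treatment == treatment_ref]) / .data$n_ref),
      .groups = "drop"
    ) |>
    mutate(z = dplyr::case_when(
      .data$s > 0 ~ .data$x / .data$s,
      .data$x == 0 ~ 0,
      TRUE ~ NA_real_
    )) |>
    (\(d) {
      if (any(d$n_case < 2 | d$n_ref < 2)) {
        abort("each gene needs >= 2 LFC observations per condition")
      }
      if (any(is.na(d$z))) abort("zero-variance gene with nonzero mean difference")
      d
    })()
}

#' Pathway-combined Z-statistic
#'
#' Combines the gene statistics of a pathway's member genes as
#' `Z_P = sum(X_g) / sqrt(sum(S_g^2))` — not the mean of the `Z_g` — which
#' is standard normal under the null of no average dropout difference. The
#' two-sided normal p-value is attached. Genes in several pathways
#' contribute to each.
#'
#' @param gene_scores Output of [gene_zstat()].
#' @param pathway_map Tibble with columns `gene`, `pathway` (many-to-many
#'   allowed).
#' @return Tibble with columns `pathway`, `genotype`, `n_genes`, `z_p`,
#'   `p_z`.
#' @export
pathway_zstat <- function(gene_scores, pathway_map) {
  joined <- inner_join(gene_scores, pathway_map, by = "gene",
                       relationship = "many-to-many")
  if (nrow(joined) == 0) abort("no pathway has any scored member gene")
  empty <- setdiff(unique(pathway_map$pathway), unique(joined$pathway))
  if (length(empty)) {
    abort(paste0("pathway(s) with no scored member genes: ",
                 paste(empty, collapse = ", ")))
  }
  joined |>
    group_by(.data$pathway, .data$genotype) |>
    summarise(n_genes = dplyr::n(),
              z_p = sum(.data$x) / sqrt(sum(.data$s^2)),
              .groups = "drop") |>
    mutate(p_z = 2 * pnorm(-abs(.data$z_p)))
}

#' Pathway dropout statistics (paired t and pooled log2FC)
#'
#' For each pathway in each (genotype, treatment) group: a paired
#' two-sample t-test of `log10(PD20 + c)` vs `log10(PD0 + c)` over the
#' pathway's guide x replicate pairs, and the log2 fold change of pooled
#' counts, `log2(sum PD20 / sum PD0)`. If all paired differences are zero
#' the p-value is 1 by convention; zero variance with a nonzero mean gives
#' p = 0 with a warning.
#'
#' @param x A normalized `screen_counts` object.
#' @param pathway_map Tibble with columns `gene`, `pathway`.
#' @param library Library manifest; defaults to `x$library`.
#' @param pseudocount Added before logs (default 1).
#' @return Tibble with columns `pathway`, `genotype`, `treatment`,
#'   `n_pairs`, `paired_t_p`, `pooled_log2fc`.
#' @export
pathway_dropout_stats <- function(x, pathway_map, library = NULL,
                                  pseudocount = 1) {
  stopifnot(inherits(x, "screen_counts"))
  library <- library %||% x$library
  if (is.null(library)) abort("a library manifest is required")
  smp <- x$samples
  t0 <- "PD0" ; t1 <- "PD20"
  if (!all(c(t0, t1) %in% smp$timepoint)) {
    tps <- sort(unique(smp$timepoint)); t0 <- tps[1]; t1 <- tps[2]
  }
  guides <- inner_join(library[!library$is_control, c("guide_id", "gene")],
                       pathway_map, by = "gene",
                       relationship = "many-to-many")
  arms <- distinct(smp[, c("genotype", "treatment")])
  out <- list()
  for (i in seq_len(nrow(arms))) {
    sub <- smp[smp$genotype == arms$genotype[i] &
                 smp$treatment == arms$treatment[i], ]
    reps <- sort(unique(sub$replicate))
    for (pw in unique(guides$pathway)) {
      gid <- guides$guide_id[guides$pathway == pw]
      ridx <- match(gid, x$counts$guide_id)
      v0 <- c(); v1 <- c()
      for (rp in reps) {
        s0 <- sub$sample[sub$timepoint == t0 & sub$replicate == rp]
        s1 <- sub$sample[sub$timepoint == t1 & sub$replicate == rp]
        v0 <- c(v0, x$counts[[s0]][ridx])
        v1 <- c(v1, x$counts[[s1]][ridx])
      }
      if (length(v0) < 2) abort("pathway has fewer than 2 guide observations")
      d <- log10(v1 + pseudocount) - log10(v0 + pseudocount)
      if (isTRUE(all.equal(var(d), 0)) || var(d) == 0) {
        if (isTRUE(all.equal(mean(d), 0))) {
          p <- 1
        } else {
          warn(sprintf("pathway %s: zero-variance differences with nonzero mean", pw))
          p <- 0
        }
      } else {
        p <- t.test(log10(v1 + pseudocount), log10(v0 + pseudocount),
                    paired = TRUE)$p.value
      }
      sum0 <- sum(v0); sum1 <- sum(v1)
      if (sum0 == 0 || sum1 == 0) {
        warn(sprintf("pathway %s: zero pooled count, pseudocount applied", pw))
        sum0 <- sum0 + pseudocount; sum1 <- sum1 + pseudocount
      }
      out[[length(out) + 1]] <- tibble(
        pathway = pw, genotype = arms$genotype[i],
        treatment = arms$treatment[i], n_pairs = length(d),
        paired_t_p = p, pooled_log2fc = log2(sum1 / sum0)
      )
    }
  }
  bind_rows(out)
}

#' Full gene table for one screen contrast
#'
#' Convenience wrapper chaining [guide_lfc()], [gene_sigma_fc()],
#' [permutation_pvalue()] and [gene_zstat()] into one gene-level table per
#' genotype, mirroring the volcano-plot inputs of a dropout screen report.
#'
#' @inheritParams guide_lfc
#' @inheritParams permutation_pvalue
#' @inheritParams gene_zstat
#' @return Tibble with SigmaFC, permutation p (per arm, case treatment) and
#'   X/S/Z columns per gene x genotype.
#' @export
screen_gene_table <- function(x, library = NULL, pseudocount = 1,
                              treatment_case = "TMZ", treatment_ref = "DMSO",
                              B = 10000, seed = NULL) {
  lfc <- guide_lfc(x, library, pseudocount)
  sfc <- gene_sigma_fc(lfc) |> permutation_pvalue(lfc, B = B, seed = seed)
  z <- gene_zstat(lfc, treatment_case, treatment_ref)
  sfc |>
    filter(.data$treatment == treatment_case) |>
    select(-"treatment") |>
    left_join(z, by = c("gene", "genotype"))
}
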