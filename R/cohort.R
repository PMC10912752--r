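# Patient-cohort model: single-sample proliferation score, proliferation
# adjustment of RAD18 expression by OLS residuals, tertile stratification,
# and logistic regression of hypermutation on adjusted expression and MGMT.

#' Mean-z single-sample proliferation score
#'
#' Scores each sample as the mean of within-cohort z-scored expression over
#' a proliferation gene set (cell-cycle markers). A deliberately simple
#' single-sample score: any monotone proliferation proxy serves the
#' adjustment step. Genes constant across the cohort contribute 0.
#'
#' @param expr Expression matrix genes x samples (matrix with rownames, or
#'   tibble with a `gene` column).
#' @param gene_set Character vector of proliferation marker genes.
#' @return Tibble with `sample`, `score`.
#' @export
proliferation_score <- function(expr, gene_set) {
  if (is.data.frame(expr)) {
    m <- as.matrix(expr[setdiff(names(expr), "gene")])
    rownames(m) <- expr$gene
  } else {
    m <- expr
  }
  hits <- intersect(gene_set, rownames(m))
  if (length(hits) == 0) abort("gene set disjoint from expression matrix")
  z <- t(apply(m[hits, , drop = FALSE], 1, function(r) {
    s <- sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  tibble(sample = colnames(m), score = colMeans(z))
}

#' Adjust expression for proliferation by regression residuals
#'
#' Fits `expression ~ proliferation` by ordinary least squares (with
#' intercept) and returns the input with an `adjusted` column of residuals
#' — the expression unexplained by proliferation. Residuals sum to zero and
#' are orthogonal to the proliferation score.
#'
#' @param data A data frame.
#' @param expression,proliferation Columns (tidy-eval).
#' @return `data` with an `adjusted` column added.
#' @export
adjust_expression <- function(data, expression = rad18,
                              proliferation = proliferation) {
  y <- dplyr::pull(data, {{ expression }})
  x <- dplyr::pull(data, {{ proliferation }})
  if (length(y) < 3) abort("need at least 3 samples")
  if (sd(x) == 0) abort("proliferation score is constant")
  data$adjusted <- unname(residuals(lm(y ~ x)))
  data
}

#' Stratify values into low / medium / high tertiles
#'
#' Cut points are the empirical 1/3 and 2/3 quantiles (linear-interpolation
#' type 7). Values at or below the lower cut are `low`, above the upper cut
#' `high`, else `medium`; tied values always share a label. If all values
#' are equal everything is `medium`, with a warning.
#'
#' @param x Numeric vector, length >= 3.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
tertile_stratify <- function(x) {
  if (length(x) < 3) abort("need at least 3 values")
  if (length(unique(x)) == 1) {
    warn("all values equal; assigning medium to every sample")
    return(factor(rep("medium", length(x)), levels = c("low", "medium", "high")))
  }
  q <- quantile(x, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  factor(ifelse(x <= q[1], "low", ifelse(x > q[2], "high", "medium")),
         levels = c("low", "medium", "high"))
}

#' Logistic regression of hypermutation on adjusted expression and MGMT
#'
#' Maximum-likelihood fit of
#' `outcome ~ adjusted expression + MGMT` via iteratively reweighted least
#' squares (binomial family, logit link), with Wald standard errors and
#' two-sided normal p-values per coefficient. Exact or quasi separation is
#' reported as an error naming the offending covariate.
#'
#' @param data A data frame.
#' @param formula Model formula; default
#'   `hypermutant ~ adjusted + mgmt_low`.
#' @return A `hyperm_fit` object; use [tidy()] for the coefficient table
#'   and [glance()] for fit diagnostics.
#' @export
logistic_fit <- function(data, formula = hypermutant ~ adjusted + mgmt_low) {
  mf <- stats::model.frame(formula, data)
  yy <- stats::model.response(mf)
  if (length(unique(yy)) < 2) abort("outcome is constant")
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(link = "logit"),
        control = list(maxit = 100, epsilon = 1e-10)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- coef(fit)
  big <- abs(co[-1]) > 15
  if (any(big, na.rm = TRUE)) {
    abort(paste0("separation detected for covariate(s): ",
                 paste(names(co[-1])[big], collapse = ", ")))
  }
  if (!fit$converged) abort("IRLS did not converge")
  structure(list(fit = fit, formula = formula, n = nrow(mf)),
            class = "hyperm_fit")
}

#' @export
print.hyperm_fit <- function(x, ...) {
  cat("<hyperm_fit> logistic hypermutation model\n")
  print(tidy(x))
  invisible(x)
}

#' @method tidy hyperm_fit
#' @export
tidy.hyperm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std.error = unname(s[, 2]), statistic = unname(s[, 3]),
         p.value = unname(s[, 4]))
}

#' @method glance hyperm_fit
#' @export
glance.hyperm_fit <- function(x, ...) {
  f <- x$fit
  tibble(n = x$n, null.deviance = f$null.deviance, deviance = f$deviance,
         aic = f$aic, converged = f$converged, iterations = f$iter)
}

#' End-to-end cohort hypermutation analysis
#'
#' Excludes POLE-mutant samples (when flagged), adjusts expression for
#' proliferation, assigns tertiles, classifies hypermutation from
#' Signature-11 counts when no flag is present, and fits the logistic
#' model. MGMT enters as the binary low/high indicator by default, or as a
#' continuous covariate.
#'
#' @param cohort Cohort tibble (see [sim_cohort()] for the schema).
#' @param exclude_pole Drop rows with `pole_mutant == TRUE` (default
#'   `TRUE`).
#' @param mgmt_mode `"binary"` (default) or `"continuous"` (expects an
#'   `mgmt_expression` column).
#' @param hypermutation_threshold Strict Signature-11-count threshold used
#'   when `hypermutant` is absent (default 500).
#' @return List with the augmented `cohort` tibble and the `fit`
#'   (`hyperm_fit`).
#' @export
cohort_analysis <- function(cohort, exclude_pole = TRUE,
                            mgmt_mode = c("binary", "continuous"),
                            hypermutation_threshold = 500) {
  mgmt_mode <- match.arg(mgmt_mode)
  d <- as_tibble(cohort)
  if (exclude_pole && "pole_mutant" %in% names(d)) {
    d <- filter(d, !.data$pole_mutant)
  }
  if (!"hypermutant" %in% names(d)) {
    d$hypermutant <- d$sig11_count > hypermutation_threshold
  }
  d <- adjust_expression(d, .data$rad18, .data$proliferation)
  d$tertile <- tertile_stratify(d$adjusted)
  fml <- if (mgmt_mode == "binary") {
    hypermutant ~ adjusted + mgmt_low
  } else {
    hypermutant ~ adjusted + mgmt_expression
  }
  list(cohort = d, fit = logistic_fit(d, fml))
}
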