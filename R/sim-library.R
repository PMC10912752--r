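# Synthetic DDR-focused sgRNA library generation. The default composition
# mirrors a domain-focused dropout-screen library: 504 DNA-damage-response
# genes with 10 guides each plus 1000 non-targeting controls.

# Pathway labels used throughout: the major DDR pathways profiled in
# genotoxin dropout screens.
.DDR_PATHWAYS <- c(
  "MMR", "BER", "TLS", "FA", "HR", "NHEJ", "NER", "Checkpoint",
  "Mitosis/SAC", "PARP", "NucleotideMetabolism", "TemplateSwitch"
)

#' Default DDR gene-to-pathway map
#'
#' A many-to-one default map assigning each synthetic gene a DDR pathway.
#' The first entries carry recognizable DDR gene names (the MMR genes,
#' `RAD18`, `POLD3`, `CHEK2`, `PRKDC`) placed in their actual pathways;
#' remaining genes are synthetic (`DDR010`, ...) assigned round-robin.
#' The map may in general be many-to-many: downstream pathway statistics
#' accept genes contributing to several pathways.
#'
#' @param n_genes Number of genes (default 504).
#' @return A tibble with columns `gene` and `pathway`.
#' @export
default_pathway_map <- function(n_genes = 504) {
  stopifnot(n_genes >= 1)
  named <- tibble(
    gene = c("MLH1", "MSH2", "MSH6", "PMS1", "PMS2",
             "RAD18", "POLD3", "CHEK2", "PRKDC"),
    pathway = c("MMR", "MMR", "MMR", "MMR", "MMR",
                "TLS", "TLS", "Checkpoint", "NHEJ")
  )
  named <- named[seq_len(min(nrow(named), n_genes)), ]
  n_extra <- n_genes - nrow(named)
  if (n_extra > 0) {
    extra <- tibble(
      gene = sprintf("DDR%03d", nrow(named) + seq_len(n_extra)),
      pathway = rep_len(.DDR_PATHWAYS, n_extra)
    )
    named <- bind_rows(named, extra)
  }
  named
}

#' Generate a synthetic sgRNA library manifest
#'
#' Builds a guide manifest of `n_genes * guides_per_gene` targeting guides
#' plus `n_controls` non-targeting controls with unique random spacers.
#' Deterministic for a given seed.
#'
#' @param n_genes Number of targeted genes (default 504).
#' @param guides_per_gene Guides per gene (default 10).
#' @param n_controls Non-targeting control guides (default 1000).
#' @param pathway_map Tibble with columns `gene`, `pathway` assigning every
#'   gene at least one pathway; defaults to [default_pathway_map()]. May be
#'   many-to-many.
#' @param spacer_len Spacer length in nt (default 20, minimum 10).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `guide_id`, `spacer`, `gene`, `pathways`
#'   (semicolon-joined) and `is_control`. Control guides have `gene = NA`.
#' @export
#' @examples
#' lib <- sim_library(n_genes = 3, guides_per_gene = 2, n_controls = 4, seed = 1)
sim_library <- function(n_genes = 504, guides_per_gene = 10, n_controls = 1000,
                        pathway_map = NULL, spacer_len = 20, seed = NULL) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, n_controls >= 0,
            spacer_len >= 10)
  if (is.null(pathway_map)) pathway_map <- default_pathway_map(n_genes)
  genes <- unique(pathway_map$gene)
  if (length(genes) < n_genes) {
    abort("pathway_map supplies fewer genes than n_genes")
  }
  genes <- genes[seq_len(n_genes)]
  if (anyDuplicated(genes)) abort("duplicate gene names in pathway_map")
  run <- function() {
    n_total <- n_genes * guides_per_gene + n_controls
    spacers <- draw_unique_spacers(n_total, spacer_len)
    path_str <- vapply(split(pathway_map$pathway, pathway_map$gene), paste,
                       "", collapse = ";")[genes]
    if (anyNA(path_str)) abort("pathway_map missing a gene")
    targeting <- tibble(
      guide_id = paste0(rep(genes, each = guides_per_gene), "_g",
                        rep(seq_len(guides_per_gene), times = n_genes)),
      spacer = spacers[seq_len(n_genes * guides_per_gene)],
      gene = rep(genes, each = guides_per_gene),
      pathways = rep(unname(path_str), each = guides_per_gene),
      is_control = FALSE
    )
    controls <- tibble(
      guide_id = sprintf("NTC_%04d", seq_len(n_controls)),
      spacer = spacers[n_genes * guides_per_gene + seq_len(n_controls)],
      gene = NA_character_,
      pathways = NA_character_,
      is_control = TRUE
    )
    bind_rows(targeting, controls)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# draw n unique random spacers of the given length
draw_unique_spacers <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    new <- vapply(seq_len(need), function(i) {
      paste(sample(.BASES, len, replace = TRUE), collapse = "")
    }, "")
    out <- unique(c(out, new))
  }
  out
}
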