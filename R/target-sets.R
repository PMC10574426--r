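#' Construct a deduplicated target set
#'
#' A target set is a deduplicated, sorted collection of gene symbols with
#' optional provenance (which sources contributed each gene). Symbols are
#' compared case-insensitively after trimming; no alias resolution is
#' attempted.
#'
#' @param genes Character vector of gene symbols.
#' @param provenance Optional named list mapping gene symbol to a character
#'   vector of contributing sources.
#' @return A tibble of class `target_set` with columns `gene` and `sources`
#'   (list-column).
#' @export
target_set <- function(genes, provenance = NULL) {
  genes <- normalize_gene(genes)
  if (any(genes == "" | is.na(genes))) abort("empty gene symbol in target set")
  genes <- sort(unique(genes))
  sources <- map(genes, function(g) {
    src <- provenance[[g]] %||% character(0)
    sort(unique(src))
  })
  structure(tibble(gene = genes, sources = sources),
            class = c("target_set", class(tibble())))
}

set_members <- function(x) {
  if (inherits(x, "target_set")) x$gene
  else if (is.data.frame(x) && "gene" %in% names(x)) normalize_gene(x$gene)
  else normalize_gene(as.character(x))
}

#' Assemble the compound-target set from prediction hits
#'
#' Hits from target prediction (source `"SwissTargetPrediction"`) are kept
#' only when their probability is strictly greater than 0; hits from the
#' herbal database route (source `"TCMSP"`) are kept unconditionally. The
#' union is deduplicated by gene symbol and provenance records every
#' contributing source.
#'
#' @param hits Data frame with columns `gene_symbol`, `source` and
#'   `probability` (required for prediction hits).
#' @return A [target_set()].
#' @examples
#' collect_compound_targets(tibble::tibble(
#'   compound = "c1", gene_symbol = c("TNF", "IL6"),
#'   source = c("TCMSP", "SwissTargetPrediction"),
#'   probability = c(NA, 0.12)))
#' @export
collect_compound_targets <- function(hits) {
  check_columns(hits, c("gene_symbol", "source"), "target-hit table")
  hits <- as_tibble(hits)
  if (!"probability" %in% names(hits)) hits$probability <- NA_real_
  if (any(is.na(hits$gene_symbol) | trimws(hits$gene_symbol) == "")) {
    abort("empty gene symbol in target-hit table")
  }
  stp <- hits$source == "SwissTargetPrediction"
  if (any(stp & is.na(hits$probability))) {
    abort("prediction hits must carry a probability")
  }
  keep <- !stp | hits$probability > 0
  kept <- hits[keep, ]
  genes <- normalize_gene(kept$gene_symbol)
  prov <- split(kept$source, genes)
  target_set(genes, provenance = lapply(prov, unique))
}

#' Assemble the disease-target set with per-source score filters
#'
#' Applies the per-database filters: DisGeNet records are kept when their
#' score is at least `disgenet_min` (inclusive), GeneCards records when
#' their relevance score is strictly greater than `genecards_min`; OMIM and
#' TTD records are kept unfiltered.
#'
#' @param records Data frame with columns `gene_symbol`, `source` and
#'   `score` (required for DisGeNet and GeneCards rows).
#' @param disgenet_min Inclusive DisGeNet score cutoff (default 0.3).
#' @param genecards_min Strict GeneCards relevance cutoff (default 10).
#' @return A [target_set()].
#' @export
collect_disease_targets <- function(records, disgenet_min = 0.3,
                                    genecards_min = 10) {
  check_columns(records, c("gene_symbol", "source"), "disease-target table")
  records <- as_tibble(records)
  if (!"score" %in% names(records)) records$score <- NA_real_
  if (any(is.na(records$gene_symbol) | trimws(records$gene_symbol) == "")) {
    abort("empty gene symbol in disease-target table")
  }
  scored <- records$source %in% c("DisGeNet", "GeneCards")
  if (any(scored & is.na(records$score))) {
    abort("DisGeNet/GeneCards records must carry a score")
  }
  keep <- ifelse(records$source == "DisGeNet", records$score >= disgenet_min,
          ifelse(records$source == "GeneCards", records$score > genecards_min,
                 TRUE))
  kept <- records[keep, ]
  genes <- normalize_gene(kept$gene_symbol)
  prov <- split(kept$source, genes)
  target_set(genes, provenance = lapply(prov, unique))
}

#' Intersect two target sets with Venn bookkeeping
#'
#' @param a,b [target_set()]s (or character vectors).
#' @return An object of class `target_overlap`: list with `common` (a
#'   `target_set`), and `venn`, the counts `(a_only, common, b_only)`.
#'   [glance()] returns the counts as a one-row tibble; [tidy()] the common
#'   genes.
#' @examples
#' ov <- intersect_targets(c("a", "b", "c"), c("b", "c", "d"))
#' glance(ov)
#' @export
intersect_targets <- function(a, b) {
  ma <- set_members(a); mb <- set_members(b)
  common <- intersect(ma, mb)
  structure(
    list(
      common = target_set(if (length(common)) common else character(0)),
      venn = c(a_only = length(setdiff(ma, mb)), common = length(common),
               b_only = length(setdiff(mb, ma)))
    ),
    class = "target_overlap"
  )
}

#' @export
print.target_overlap <- function(x, ...) {
  cat("Target overlap:", x$venn["a_only"], "| common", x$venn["common"],
      "|", x$venn["b_only"], "\n")
  invisible(x)
}

#' @rdname intersect_targets
#' @param x A `target_overlap`.
#' @param ... Unused.
#' @export
glance.target_overlap <- function(x, ...) {
  tibble(a_only = unname(x$venn["a_only"]), common = unname(x$venn["common"]),
         b_only = unname(x$venn["b_only"]),
         a_total = unname(x$venn["a_only"] + x$venn["common"]),
         b_total = unname(x$venn["b_only"] + x$venn["common"]))
}

#' @rdname intersect_targets
#' @export
tidy.target_overlap <- function(x, ...) {
  tibble(gene = x$common$gene)
}
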