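#' Per-gene group mean expression
#'
#' Arithmetic means over the wild columns, the cultivated columns, and all
#' columns.
#'
#' @param expression an `expression_table` (list with `values` matrix and
#'   `groups` map) or a gene x sample matrix.
#' @param group_map named vector sample -> "wild"/"cultivated"; taken from
#'   the expression table when omitted.
#' @return data.frame with gene, mean_wild, mean_cultivated, mean_all.
#' @export
group_mean_expression <- function(expression, group_map = NULL) {
  if (inherits(expression, "expression_table")) {
    if (is.null(group_map)) group_map <- expression$groups
    values <- expression$values
  } else {
    values <- expression
  }
  samples <- colnames(values)
  missing <- setdiff(samples, names(group_map))
  if (length(missing) > 0) {
    stop("samples missing from group map: ", paste(missing, collapse = ", "))
  }
  w <- samples[group_map[samples] == "wild"]
  c_ <- samples[group_map[samples] == "cultivated"]
  data.frame(gene = rownames(values),
             mean_wild = rowMeans(values[, w, drop = FALSE]),
             mean_cultivated = rowMeans(values[, c_, drop = FALSE]),
             mean_all = rowMeans(values),
             row.names = NULL, stringsAsFactors = FALSE)
}

# gene -> is the gene's subfamily clade-specific
gene_specific_flag <- function(calls, assignment) {
  flag <- stats::setNames(calls$specific, calls$subfamily_id)
  stats::setNames(unname(flag[assignment$genes$subfamily_id]),
                  assignment$genes$gene)
}

#' Compare expression of clade-specific vs shared superfamily members
#'
#' Two-sided Wilcoxon rank-sum test on `log2(mean_all + 1)` between genes
#' of clade-specific and shared subfamilies: exact enumeration when both
#' classes have at most 20 genes, normal approximation with continuity/tie
#' correction otherwise.
#'
#' @param means output of [group_mean_expression()].
#' @param calls output of [call_clade_specific()].
#' @param assignment the matching [subfamily_assignment()].
#' @return list with `statistic` (rank-sum U), `p_value`, `n_specific`,
#'   `n_shared`, `method`.
#' @export
compare_specific_vs_nonspecific <- function(means, calls, assignment) {
  flag <- gene_specific_flag(calls, assignment)
  common <- intersect(means$gene, names(flag))
  x <- log2(means$mean_all[match(common, means$gene)] + 1)
  spec <- flag[common]
  xs <- x[spec]; xn <- x[!spec]
  if (length(xs) == 0 || length(xn) == 0) {
    stop("both classes must be non-empty (specific: ", length(xs),
         ", shared: ", length(xn), ")")
  }
  exact <- length(xs) <= 20 && length(xn) <= 20
  wt <- suppressWarnings(stats::wilcox.test(xs, xn, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_specific = length(xs), n_shared = length(xn),
       method = if (exact) "exact" else "normal approximation")
}

#' Rank clade-specific candidates by expression
#'
#' Restricts to genes in clade-specific subfamilies (optionally to a focal
#' species), sorts descending by mean expression over all samples with ties
#' broken lexicographically by gene id, and returns the top `top_k`. The
#' default shortlist size is 36, the published candidate count.
#'
#' @param calls output of [call_clade_specific()].
#' @param means output of [group_mean_expression()].
#' @param assignment the matching [subfamily_assignment()].
#' @param top_k shortlist size (>= 1).
#' @param focal_species optional species restriction.
#' @return data.frame of class `candidate_ranking` with gene, subfamily_id,
#'   mean_wild, mean_cultivated, mean_all, rank.
#' @export
rank_candidates <- function(calls, means, assignment, top_k = 36,
                            focal_species = NULL) {
  if (top_k < 1) stop("top_k must be >= 1")
  genes <- assignment$genes
  specific_sfs <- calls$subfamily_id[calls$specific]
  cand <- genes[genes$subfamily_id %in% specific_sfs, , drop = FALSE]
  if (!is.null(focal_species)) {
    cand <- cand[cand$species == focal_species, , drop = FALSE]
  }
  cand <- cand[cand$gene %in% means$gene, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no clade-specific candidate genes; returning empty ranking")
    out <- data.frame(gene = character(0), subfamily_id = character(0),
                      mean_wild = numeric(0), mean_cultivated = numeric(0),
                      mean_all = numeric(0), rank = integer(0))
    return(structure(out, class = c("candidate_ranking", "data.frame")))
  }
  m <- means[match(cand$gene, means$gene), ]
  out <- data.frame(gene = cand$gene, subfamily_id = cand$subfamily_id,
                    mean_wild = m$mean_wild, mean_cultivated = m$mean_cultivated,
                    mean_all = m$mean_all, stringsAsFactors = FALSE)
  out <- out[order(-out$mean_all, out$gene), , drop = FALSE]
  out <- head(out, top_k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("candidate_ranking", "data.frame"))
}
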