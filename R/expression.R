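#' Collapse a probe-level expression matrix to gene level (max mode)
#'
#' Each gene's value per sample is the maximum over its probes; probes
#' mapping to no gene, and genes with no probes, are absent from the output.
#'
#' @param expr probe x sample numeric matrix (probe ids as rownames).
#' @param probe_to_gene named character vector: probe id -> gene symbol
#'   (each probe maps to at most one gene).
#' @return gene x sample matrix.
#' @export
collapse_to_genes <- function(expr, probe_to_gene) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  gene <- probe_to_gene[rownames(expr)]
  keep <- !is.na(gene)
  expr <- expr[keep, , drop = FALSE]
  gene <- gene[keep]
  if (!nrow(expr)) stop("no probes map to any gene")
  out <- do.call(rbind, lapply(split(seq_len(nrow(expr)), gene), function(i)
    apply(expr[i, , drop = FALSE], 2, max)))
  out
}

#' Nearest-centroid classification by Pearson correlation
#'
#' Each sample is correlated with every class centroid over the genes shared
#' between the expression matrix and the centroid set; the sample is assigned
#' to the class with the maximal correlation. Ties are flagged, not silently
#' broken.
#'
#' @param expr gene x sample matrix.
#' @param centroids gene x class matrix (>= 2 classes).
#' @param min_shared minimum shared genes required (default 10).
#' @return data.frame: `sample`, `assigned`, `confidence` (top correlation
#'   minus runner-up), `tie`, plus one correlation column per class
#'   (`cor_<class>`).
#' @export
classify_by_centroids <- function(expr, centroids, min_shared = 10L) {
  stopifnot(is.matrix(expr), is.matrix(centroids), ncol(centroids) >= 2)
  shared <- intersect(rownames(expr), rownames(centroids))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " genes shared with the centroids (need ",
         min_shared, ")")
  cors <- stats::cor(expr[shared, , drop = FALSE],
                     centroids[shared, , drop = FALSE],
                     method = "pearson")
  top <- apply(cors, 1, function(r) {
    o <- order(r, decreasing = TRUE)
    c(best = o[1], conf = unname(r[o[1]] - r[o[2]]))
  })
  out <- data.frame(sample = colnames(expr),
                    assigned = colnames(centroids)[top["best", ]],
                    confidence = top["conf", ],
                    tie = top["conf", ] == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (cl in colnames(centroids)) out[[paste0("cor_", cl)]] <- cors[, cl]
  out
}

#' Order samples by hierarchical clustering of centroid correlations
#'
#' Agglomerative clustering (complete linkage, Euclidean distance) of the
#' samples on their per-class correlation vectors; samples are pre-sorted by
#' name so leaf order is deterministic under ties.
#'
#' @param cors sample x class correlation matrix (rownames = samples).
#' @param method linkage (default "complete").
#' @return character vector of sample names in dendrogram leaf order.
#' @export
correlation_cluster <- function(cors, method = "complete") {
  stopifnot(is.matrix(cors), !anyNA(cors))
  if (nrow(cors) == 1) return(rownames(cors))
  cors <- cors[order(rownames(cors)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(cors), method = method)
  rownames(cors)[hc$order]
}

#' Expression difference between copy-number groups
#'
#' Compares one gene's expression in samples whose copy-number status is in
#' `altered_status` against all other samples: linear-scale fold change of
#' group means plus a two-sided rank-sum p-value.
#'
#' @param expr_values numeric expression per sample (named).
#' @param status character copy-number status per sample, parallel.
#' @param altered_status statuses forming the altered group (e.g. c("loss",
#'   "HD", "LOH")).
#' @param log2_input exponentiate log2-scale input before computing fold
#'   change (default FALSE).
#' @return list: `fold_change` (altered / rest), `p_value`, group sizes.
#' @export
expression_by_cn_group <- function(expr_values, status, altered_status,
                                   log2_input = FALSE) {
  stopifnot(length(expr_values) == length(status))
  altered <- status %in% altered_status
  if (sum(altered) < 2 || sum(!altered) < 2)
    stop("both groups need at least 2 samples (altered: ", sum(altered),
         ", rest: ", sum(!altered), ")")
  v <- if (log2_input) 2^expr_values else expr_values
  ga <- group_association(v, factor(ifelse(altered, "altered", "rest"),
                                    levels = c("altered", "rest")))
  list(fold_change = mean(v[altered]) / mean(v[!altered]),
       p_value = ga$p_value,
       n_altered = sum(altered), n_rest = sum(!altered))
}
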