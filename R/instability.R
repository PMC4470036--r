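#' Genomic-instability metrics for one sample
#'
#' Three ways of measuring per-sample alteration burden: (1) total size of
#' the probed genome altered (Mb gained, lost, and their sum, from segment bp
#' extents of non-neutral calls); (2) fraction of probes altered; (3) number
#' of altered segments.
#'
#' @param segments the sample's tiled, called segments.
#' @param annotation probe annotation.
#' @return one-row data.frame: `sample`, `mb_gained`, `mb_lost`,
#'   `mb_altered`, `frac_probes_altered`, `n_altered_segments`.
#' @export
instability_metrics <- function(segments, annotation) {
  gained <- segments$call >= 1L
  lost <- segments$call <= -1L
  mb_g <- sum(segments$end_bp[gained] - segments$start_bp[gained]) / 1e6
  mb_l <- sum(segments$end_bp[lost] - segments$start_bp[lost]) / 1e6
  frac <- sum(segments$n_probes[gained | lost]) / nrow(annotation)
  data.frame(sample = segments$sample[1], mb_gained = mb_g, mb_lost = mb_l,
             mb_altered = mb_g + mb_l, frac_probes_altered = frac,
             n_altered_segments = sum(gained | lost),
             stringsAsFactors = FALSE)
}

#' Tertile classification of a cohort metric
#'
#' Cuts at the empirical 1/3 and 2/3 quantiles (type 1, i.e. at observed
#' values); ties at a boundary go to the lower category. When all values are
#' equal every sample is "low" and a warning is emitted.
#'
#' @param values numeric vector (>= 3 samples).
#' @return factor with levels low / intermediate / high, same order as
#'   input.
#' @export
tertile_classify <- function(values) {
  stopifnot(length(values) >= 3)
  q <- stats::quantile(values, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  if (q[1] == q[2] && all(values == values[1]))
    warning("all metric values equal: every sample classified low")
  out <- ifelse(values <= q[1], "low",
                ifelse(values <= q[2], "intermediate", "high"))
  factor(out, levels = c("low", "intermediate", "high"))
}

#' Rank-sum association between a metric and a binary grouping
#'
#' Two-sided Wilcoxon rank-sum test: exact when the combined sample size is
#' at most 20 and there are no ties, normal approximation with continuity
#' correction otherwise.
#'
#' @param values numeric metric values.
#' @param groups binary labels parallel to `values` (2 levels, both
#'   non-empty).
#' @return list: `p_value`, `group_means`, `group_sds`, `exact`.
#' @export
group_association <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(nlevels(droplevels(groups)) == 2)
  groups <- droplevels(groups)
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # fully tied data carries no evidence
  list(p_value = p,
       group_means = stats::setNames(c(mean(x), mean(y)), levels(groups)),
       group_sds = stats::setNames(c(stats::sd(x), stats::sd(y)),
                                   levels(groups)),
       exact = use_exact)
}

#' Chi-square comparison of two mutation frequencies
#'
#' 2x2 chi-square without continuity correction by default (a Yates flag is
#' provided). Degenerate tables (an empty margin) return statistic 0 and
#' p = 1 with a warning.
#'
#' @param mutants_a,n_a mutant count and total in group A.
#' @param mutants_b,n_b mutant count and total in group B.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list: `statistic`, `p_value`.
#' @export
frequency_chi2 <- function(mutants_a, n_a, mutants_b, n_b,
                           correct = FALSE) {
  stopifnot(n_a > 0, n_b > 0, mutants_a >= 0, mutants_b >= 0,
            mutants_a <= n_a, mutants_b <= n_b)
  tab <- matrix(c(mutants_a, n_a - mutants_a, mutants_b, n_b - mutants_b),
                2, 2, byrow = TRUE)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    warning("degenerate 2x2 table (empty margin): statistic 0")
    return(list(statistic = 0, p_value = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Replicate call concordance
#'
#' Absolute concordance rate between two call vectors on the same probes,
#' with the discordance breakdown by type.
#'
#' @param calls_a,calls_b integer call vectors in {-1, 0, 1, 2}, same length.
#' @return list: `concordance`, `breakdown` (named fractions of all probes:
#'   `gain_loss`, `gain_nochange`, `loss_nochange`, `within_gain`).
#' @export
replicate_concordance <- function(calls_a, calls_b) {
  stopifnot(length(calls_a) == length(calls_b))
  n <- length(calls_a)
  disc <- calls_a != calls_b
  a <- calls_a[disc]; b <- calls_b[disc]
  gain_loss <- sum((a > 0 & b < 0) | (a < 0 & b > 0))
  gain_no <- sum((a > 0 & b == 0) | (a == 0 & b > 0))
  loss_no <- sum((a < 0 & b == 0) | (a == 0 & b < 0))
  within_gain <- sum(a > 0 & b > 0 & a != b)
  breakdown <- c(gain_loss = gain_loss, gain_nochange = gain_no,
                 loss_nochange = loss_no, within_gain = within_gain) / n
  list(concordance = 1 - sum(disc) / n,
       breakdown = breakdown[breakdown > 0])
}
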