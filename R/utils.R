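#' Match detected events to truth by reciprocal overlap
#'
#' Pairs detected and truth intervals on the same sample and chromosome when
#' the overlap covers at least `min_ro` of both intervals, then reports
#' sensitivity (matched truth / truth) and precision (matched detected /
#' detected).
#'
#' @param detected data.frame with `sample`, `chromosome`, `start_bp`,
#'   `end_bp` (0-based half-open).
#' @param truth data.frame with `sample`, `chromosome`, `start`, `end`.
#' @param min_ro minimum reciprocal overlap (default 0.5).
#' @return list: `sensitivity`, `precision`, `n_truth`, `n_detected`,
#'   `n_matched_truth`, `n_matched_detected`.
#' @export
match_events <- function(detected, truth, min_ro = 0.5) {
  if (!nrow(truth))
    return(list(sensitivity = NA_real_,
                precision = if (nrow(detected)) 0 else NA_real_,
                n_truth = 0L, n_detected = nrow(detected),
                n_matched_truth = 0L, n_matched_detected = 0L))
  if (!nrow(detected))
    return(list(sensitivity = 0, precision = NA_real_,
                n_truth = nrow(truth), n_detected = 0L,
                n_matched_truth = 0L, n_matched_detected = 0L))
  gr_d <- GenomicRanges::GRanges(
    paste(detected$sample, detected$chromosome, sep = ":"),
    IRanges::IRanges(detected$start_bp + 1, detected$end_bp))
  gr_t <- GenomicRanges::GRanges(
    paste(truth$sample, truth$chromosome, sep = ":"),
    IRanges::IRanges(truth$start + 1, truth$end))
  hits <- GenomicRanges::findOverlaps(gr_d, gr_t)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_d)[qi],
                                           IRanges::ranges(gr_t)[si]))
  ok <- ov >= min_ro * IRanges::width(gr_d)[qi] &
    ov >= min_ro * IRanges::width(gr_t)[si]
  list(sensitivity = length(unique(si[ok])) / nrow(truth),
       precision = length(unique(qi[ok])) / nrow(detected),
       n_truth = nrow(truth), n_detected = nrow(detected),
       n_matched_truth = length(unique(si[ok])),
       n_matched_detected = length(unique(qi[ok])))
}

#' Fraction of annotation probes falling inside a set of regions
#'
#' @param regions data.frame with `chromosome`, `start_bp`, `end_bp`.
#' @param annotation probe annotation.
#' @return fraction of probes covered.
#' @export
probe_fraction_in_regions <- function(regions, annotation) {
  if (!nrow(regions)) return(0)
  covered <- logical(nrow(annotation))
  for (i in seq_len(nrow(regions))) {
    covered <- covered |
      (annotation$chromosome == regions$chromosome[i] &
         annotation$position - 1 >= regions$start_bp[i] &
         annotation$position - 1 < regions$end_bp[i])
  }
  mean(covered)
}
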