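#' Probe-level allelic state: normal, LOH or homozygous deletion
#'
#' LOH: homozygous genotype call (AA/BB), BAF on a rail
#' (min(baf, 1-baf) <= `baf_hom_tol`), and a decline in LogR at the segment
#' level (segment mean LogR <= -`logR_decline`). HD: no-call genotype,
#' "abnormal" BAF (farther than `abnormal_baf_dist` from each of 0, 0.5, 1 —
#' the no-allele signal is noise) and a strong LogR decline (segment mean
#' LogR <= `hd_logR`). Everything else is normal.
#'
#' @param signals per-sample signal table (`genotype`, `baf`, `logR`).
#' @param segment_mean_logR per-probe vector of the containing segment's mean
#'   LogR (see [probe_segment_means()]).
#' @param baf_hom_tol BAF rail tolerance (default 0.05).
#' @param logR_decline minimum segment LogR decline for LOH (default 0.1).
#' @param hd_logR segment LogR ceiling for HD (default -1).
#' @param abnormal_baf_dist distance from {0, 0.5, 1} defining abnormal BAF
#'   (default 0.1).
#' @return character vector in {normal, LOH, HD} per probe.
#' @export
call_allelic_state <- function(signals, segment_mean_logR,
                               baf_hom_tol = 0.05, logR_decline = 0.1,
                               hd_logR = -1.0, abnormal_baf_dist = 0.1) {
  stopifnot(length(segment_mean_logR) == nrow(signals))
  gt <- signals$genotype
  baf <- signals$baf
  rail <- !is.na(baf) & pmin(baf, 1 - baf) <= baf_hom_tol
  abnormal <- !is.na(baf) &
    pmin(abs(baf), abs(baf - 0.5), abs(baf - 1)) > abnormal_baf_dist
  state <- rep("normal", nrow(signals))
  state[gt %in% c("AA", "BB") & rail &
          !is.na(segment_mean_logR) & segment_mean_logR <= -logR_decline] <-
    "LOH"
  state[gt == "NC" & abnormal &
          !is.na(segment_mean_logR) & segment_mean_logR <= hd_logR] <- "HD"
  state
}

#' Per-probe segment mean LogR
#'
#' Expands tiled segments to a per-probe vector of containing-segment means.
#' @param segments tiled segments of one sample.
#' @param annotation probe annotation (probe order).
#' @return numeric vector parallel to `annotation`.
#' @export
probe_segment_means <- function(segments, annotation) {
  out <- rep(NA_real_, nrow(annotation))
  offset <- 0L
  for (chr in chrom_order(annotation$chromosome)) {
    n_chr <- sum(annotation$chromosome == chr)
    seg <- segments[segments$chromosome == chr, , drop = FALSE]
    for (i in seq_len(nrow(seg)))
      out[offset + (seg$start_idx[i]:(seg$end_idx[i] - 1L))] <-
        seg$mean_logR[i]
    offset <- offset + n_chr
  }
  out
}

#' Detect copy-neutral LOH (UPD) candidate regions
#'
#' Scans each chromosome for maximal runs of consecutive informative probes
#' (genotype called) without heterozygous calls — absorbing isolated AB calls
#' as genotyping error while the run's heterozygous fraction stays at or
#' below `het_max` — whose LogR is compatible with two or more copies: every
#' rolling mean of `window` probes within the run must be at least
#' -`logR_tol` (copy-neutral runs sit within the +/- `logR_tol` band around
#' 0; amplified UPD sits above it). Runs shorter than `min_size_mb` or with
#' fewer than `min_probes` probes are discarded: at typical heterozygosity a
#' short homozygous run arises by chance, so the probe guard is what keeps a
#' diploid genome from generating events.
#'
#' @param signals per-sample signal table ordered by (chromosome, position).
#' @param window rolling-mean window in probes (default 50; clamped with a
#'   warning when a chromosome is shorter).
#' @param het_max maximum heterozygous-call fraction within a run (default
#'   0.02).
#' @param logR_tol LogR tolerance band around 0 (default 0.15).
#' @param min_size_mb minimum event size in Mb (default 2).
#' @param min_probes minimum probes per event (default 50).
#' @param sample sample name attached to the output.
#' @return data.frame of UPD events: `sample`, `chromosome`, `start_bp`,
#'   `end_bp` (0-based half-open), `n_probes`, `mean_logR`.
#' @export
detect_upd <- function(signals, window = 50L, het_max = 0.02,
                       logR_tol = 0.15, min_size_mb = 2, min_probes = 50L,
                       sample = "sample") {
  out <- list()
  for (chr in chrom_order(signals$chromosome)) {
    sig <- signals[signals$chromosome == chr, , drop = FALSE]
    inf <- which(sig$genotype %in% c("AA", "AB", "BB"))
    if (length(inf) < min_probes) next
    w <- window
    if (w > length(inf)) {
      warning("window larger than informative probe count on chromosome ",
              chr, "; clamped")
      w <- length(inf)
    }
    is_het <- sig$genotype[inf] == "AB"
    runs <- het_runs(is_het, het_max, flank = max(2L, w %/% 2L))
    for (r in seq_len(nrow(runs))) {
      ridx <- inf[runs$start[r]:runs$end[r]]
      if (length(ridx) < min_probes) next
      start_bp <- sig$position[ridx[1]] - 1
      end_bp <- sig$position[ridx[length(ridx)]]
      if ((end_bp - start_bp) < min_size_mb * 1e6) next
      lr <- sig$logR[ridx]
      lr <- lr[!is.na(lr)]
      if (!length(lr)) next
      roll <- if (length(lr) >= w) zoo::rollmean(lr, w) else mean(lr)
      if (any(roll < -logR_tol)) next
      out[[length(out) + 1]] <- data.frame(
        sample = sample, chromosome = chr, start_bp = start_bp,
        end_bp = end_bp, n_probes = length(ridx),
        mean_logR = mean(lr), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), chromosome = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_probes = integer(0), mean_logR = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# maximal runs of non-heterozygous informative probes. Isolated het calls
# (genotyping error) are absorbed only when both flanking homozygous runs
# have at least `flank` probes — a chance homozygous stretch in diploid
# background is practically never that long — and while the merged run's
# het fraction stays <= het_max.
het_runs <- function(is_het, het_max, flank = 25L) {
  n <- length(is_het)
  if (!n) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(is_het)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts, end = ends, het = r$values,
                    n_het = ifelse(r$values, r$lengths, 0L))
  seg <- seg[!seg$het | seg$n_het == 1L, , drop = FALSE]  # singles mergeable
  res <- list()
  i <- 1
  while (i <= nrow(seg)) {
    if (seg$het[i]) { i <- i + 1; next }
    start <- seg$start[i]; end <- seg$end[i]; n_het <- 0L
    j <- i + 1
    while (j + 1 <= nrow(seg) && seg$het[j] && !seg$het[j + 1] &&
           seg$start[j + 1] == seg$end[j] + 1L && seg$end[j] == end + 1L) {
      left_len <- end - start + 1L
      right_len <- seg$end[j + 1] - seg$start[j + 1] + 1L
      if (left_len < flank || right_len < flank) break
      cand_end <- seg$end[j + 1]
      cand_het <- n_het + 1L
      if (cand_het / (cand_end - start + 1L) > het_max) break
      end <- cand_end; n_het <- cand_het; j <- j + 2
    }
    res[[length(res) + 1]] <- c(start, end)
    i <- j
  }
  if (!length(res)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Classify a UPD event into the six-category taxonomy
#'
#' Categories: 1 whole chromosome; 2 whole chromosome arm; 3 focal;
#' 4 focal with segmental duplication (overlaps a +1 segment); 5 with
#' segmental amplification (overlaps a +2 segment); 6 nearly whole chromosome
#' combined with a focal deletion elsewhere on the chromosome.
#'
#' @param events output of [detect_upd()].
#' @param annotation probe annotation.
#' @param segments the sample's called segments.
#' @param arm_fraction arm coverage defining "whole" (default 0.9).
#' @param near_whole chromosome coverage defining "almost entire" for
#'   category 6 (default 0.8).
#' @return `events` with integer `category` and label `category_label`.
#' @export
classify_upd <- function(events, annotation, segments, arm_fraction = 0.9,
                         near_whole = 0.8) {
  labels <- c("whole_chromosome", "whole_arm", "focal",
              "focal_with_segmental_duplication",
              "upd_with_segmental_amplification",
              "near_whole_chromosome_with_focal_deletion")
  cat_v <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    chr <- events$chromosome[i]
    ann <- annotation[annotation$chromosome == chr, , drop = FALSE]
    inside <- ann$position - 1 >= events$start_bp[i] &
      ann$position - 1 < events$end_bp[i]
    n_arm <- c(p = sum(ann$arm == "p"), q = sum(ann$arm == "q"))
    cov <- c(p = sum(inside & ann$arm == "p"),
             q = sum(inside & ann$arm == "q")) / pmax(n_arm, 1L)
    cov[n_arm == 0] <- 1  # a missing arm cannot block whole-chromosome
    seg <- segments[segments$chromosome == chr, , drop = FALSE]
    ovl <- seg$start_bp < events$end_bp[i] & seg$end_bp > events$start_bp[i]
    ovl_calls <- seg$call[ovl]
    chrom_deleted <- any(seg$call == -1L & seg$scope == "focal")
    # near-whole + focal deletion (6) takes precedence over the single-arm
    # rule: a 90%-of-chromosome run with the remainder deleted is the
    # combined-deletion signature, not an arm event
    cat_v[i] <-
      if (all(cov >= arm_fraction) && !any(ovl_calls == -1L)) 1L
      else if (mean(inside) >= near_whole && chrom_deleted) 6L
      else if (sum(cov >= arm_fraction) == 1) 2L
      else if (any(ovl_calls == 2L)) 5L
      else if (any(ovl_calls == 1L)) 4L
      else 3L
  }
  events$category <- cat_v
  events$category_label <- labels[cat_v]
  events
}

#' Gene-level copy/allelic status
#'
#' HD if at least `min_probe_support` of the gene's probes are called HD;
#' else LOH under the same support rule; otherwise the majority segment call
#' over the gene's probes (amplification / gain / loss), else neutral.
#'
#' @param gene_probes named list: gene -> character vector of probe ids.
#' @param annotation probe annotation.
#' @param allelic_states per-probe states from [call_allelic_state()],
#'   parallel to `annotation`.
#' @param calls per-probe calls from [probe_calls()], parallel to
#'   `annotation`.
#' @param min_probe_support concordant probes required for HD/LOH (default
#'   2).
#' @param sample sample name attached to the output.
#' @return data.frame: `gene`, `sample`, `status`, `n_probes_support`.
#' @export
gene_status <- function(gene_probes, annotation, allelic_states, calls,
                        min_probe_support = 2L, sample = "sample") {
  out <- lapply(names(gene_probes), function(g) {
    idx <- match(gene_probes[[g]], annotation$probe_id)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) {
      warning("gene ", g, " maps to no annotated probes; status missing")
      return(data.frame(gene = g, sample = sample, status = NA_character_,
                        n_probes_support = 0L, stringsAsFactors = FALSE))
    }
    n_hd <- sum(allelic_states[idx] == "HD")
    n_loh <- sum(allelic_states[idx] == "LOH")
    if (n_hd >= min_probe_support)
      return(data.frame(gene = g, sample = sample, status = "HD",
                        n_probes_support = n_hd, stringsAsFactors = FALSE))
    if (n_loh >= min_probe_support)
      return(data.frame(gene = g, sample = sample, status = "LOH",
                        n_probes_support = n_loh, stringsAsFactors = FALSE))
    maj <- sort(table(calls[idx]), decreasing = TRUE)
    call <- as.integer(names(maj)[1])
    status <- c(`-1` = "loss", `0` = "neutral", `1` = "gain",
                `2` = "amplification")[as.character(call)]
    data.frame(gene = g, sample = sample, status = unname(status),
               n_probes_support = as.integer(maj[1]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort UPD summary
#'
#' @param events classified (or raw) UPD events for a cohort.
#' @param samples character vector of all cohort sample names (so samples
#'   without events count as zero).
#' @return list with `per_sample` (data.frame: `sample`, `n_events`,
#'   `total_bp`) and `median_events` over samples.
#' @export
upd_summary <- function(events, samples) {
  n_ev <- vapply(samples, function(s) sum(events$sample == s), integer(1))
  bp <- vapply(samples, function(s)
    sum(events$end_bp[events$sample == s] -
          events$start_bp[events$sample == s]), numeric(1))
  list(per_sample = data.frame(sample = samples, n_events = n_ev,
                               total_bp = bp, row.names = NULL,
                               stringsAsFactors = FALSE),
       median_events = stats::median(n_ev))
}
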