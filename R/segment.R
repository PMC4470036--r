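#' Segment a LogR series by circular binary segmentation
#'
#' Recursively scans each segment for the arc (contiguous sub-run, including
#' prefixes and suffixes, i.e. plain splits) maximizing the standardized
#' mean-shift statistic |sum(arc) - (d/m) sum(segment)| / sqrt(d (m - d) / m)
#' and accepts the corresponding one or two cut points when the statistic's
#' permutation p-value falls below `alpha`; the resulting pieces are then
#' segmented recursively. Arc lengths are scanned on a geometric grid (every
#' length up to 50 probes, then 10% steps), which bounds the scan cost while
#' locating any arc boundary within a few percent; the recursion then
#' refines. Cut points closer than `min_probes` to a segment edge are
#' discarded, so emitted segments have at least `min_probes` probes. The
#' permutation loop (compiled, using R's RNG) stops early as soon as enough
#' exceedances have accumulated that significance is impossible.
#'
#' Missing values are dropped before segmentation; returned breakpoints are
#' expressed in the original index space (a breakpoint k means "split between
#' probe k and probe k+1").
#'
#' @param x numeric LogR series for one chromosome (NA allowed).
#' @param alpha split acceptance level (default 0.01).
#' @param min_probes minimum probes per segment (default 5).
#' @param n_perm permutations per split test (default 1000).
#' @param seed integer seed (mandatory: results are deterministic given the
#'   seed).
#' @return sorted integer vector of breakpoints (possibly empty).
#' @export
segment_logR <- function(x, alpha = 0.01, min_probes = 5L, n_perm = 1000L,
                         seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(alpha > 0, alpha < 1, min_probes >= 2, n_perm >= 10)
  min_probes <- as.integer(min_probes)
  idx_map <- which(!is.na(x))
  y <- x[idx_map]
  if (length(y) < 2 * min_probes) {
    warning("series shorter than 2 * min_probes: single segment")
    return(integer(0))
  }
  set.seed(as.integer(seed))
  limit <- as.integer(ceiling(alpha * (n_perm + 1)))

  lag_grid <- function(m) {
    dmax <- m - min_probes
    if (dmax < 1) return(integer(0))
    small <- seq.int(1L, min(50L, dmax))
    if (dmax <= 50L) return(small)
    d <- 50
    geo <- integer(0)
    while (d < dmax) {
      d <- min(ceiling(d * 1.1), dmax)
      geo <- c(geo, d)
    }
    unique(c(small, geo))
  }

  recurse <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2 * min_probes) return(integer(0))
    seg <- y[lo:hi]
    lags <- lag_grid(m)
    obs <- arc_max_stat(c(0, cumsum(seg)), lags)
    if (!is.finite(obs$stat) || obs$stat <= 0) return(integer(0))
    pc <- arc_perm_count(seg, lags, obs$stat, n_perm, limit)
    if (pc$exceed >= limit ||
        (1 + pc$exceed) / (n_perm + 1) >= alpha) return(integer(0))
    # refine the grid-quantized arc to the exact local optimum
    dmax <- m - min_probes
    ref <- seq.int(max(1L, floor(obs$d / 1.1) - 2L),
                   min(dmax, ceiling(obs$d * 1.1) + 2L))
    obs <- arc_max_stat(c(0, cumsum(seg)), ref)
    cuts <- unique(c(obs$i, obs$i + obs$d))
    cuts <- cuts[cuts >= min_probes & cuts <= m - min_probes]
    if (!length(cuts)) return(integer(0))
    cuts <- sort(cuts)
    bounds <- c(0L, cuts, m)
    out <- lo + cuts - 1L
    for (j in seq_len(length(bounds) - 1L))
      out <- c(out, recurse(lo + bounds[j], lo + bounds[j + 1L] - 1L))
    out
  }

  sort(idx_map[recurse(1L, length(y))])
}

#' Tile breakpoints into segments for one chromosome
#'
#' @param x LogR series (original index space, NA allowed).
#' @param breakpoints output of [segment_logR()].
#' @param positions probe bp positions parallel to `x`.
#' @param min_probes segments with fewer non-missing probes are merged into
#'   the neighbor with the closer mean (ties to the left).
#' @return data.frame: `start_idx`, `end_idx` (half-open probe indices),
#'   `start_bp`, `end_bp` (0-based half-open), `n_probes`, `mean_logR`.
#' @keywords internal
tile_segments <- function(x, breakpoints, positions, min_probes = 5L) {
  n <- length(x)
  bounds <- c(0L, as.integer(breakpoints), n)
  starts <- head(bounds, -1) + 1L
  ends <- tail(bounds, -1)
  seg <- data.frame(start_idx = starts, end_idx = ends + 1L)
  seg$n_probes <- ends - starts + 1L
  seg$mean_logR <- vapply(seq_len(nrow(seg)), function(i)
    mean(x[starts[i]:ends[i]], na.rm = TRUE), numeric(1))
  # merge undersized segments into the more similar neighbor (left on ties)
  repeat {
    small <- which(seg$n_probes < min_probes)
    if (!length(small) || nrow(seg) == 1) break
    i <- small[1]
    dl <- if (i > 1) abs(seg$mean_logR[i] - seg$mean_logR[i - 1]) else Inf
    dr <- if (i < nrow(seg)) abs(seg$mean_logR[i] - seg$mean_logR[i + 1])
    else Inf
    j <- if (dl <= dr) i - 1 else i + 1
    a <- min(i, j); b <- max(i, j)
    lo <- seg$start_idx[a]; hi <- seg$end_idx[b] - 1L
    seg$start_idx[a] <- lo
    seg$end_idx[a] <- hi + 1L
    seg$n_probes[a] <- hi - lo + 1L
    seg$mean_logR[a] <- mean(x[lo:hi], na.rm = TRUE)
    seg <- seg[-b, , drop = FALSE]
  }
  seg$start_bp <- positions[seg$start_idx] - 1
  seg$end_bp <- positions[seg$end_idx - 1L]
  rownames(seg) <- NULL
  seg[, c("start_idx", "end_idx", "start_bp", "end_bp", "n_probes",
          "mean_logR")]
}

#' Assign categorical copy-number calls to segments
#'
#' call = -1 (loss) if mean LogR <= `loss_t`; +2 (amplification, i.e. >= 5
#' copies) if mean LogR >= `amp_t`; +1 (gain) if >= `gain_t`; else 0.
#' The default amplification threshold is log2(5/2), the LogR of five copies
#' in a diploid-referenced near-pure sample; no ploidy correction is applied.
#'
#' @param segments data.frame with a `mean_logR` column.
#' @param loss_t,gain_t,amp_t thresholds with loss_t < 0 < gain_t < amp_t.
#' @return `segments` with an integer `call` column in {-1, 0, 1, 2}.
#' @export
call_segments <- function(segments, loss_t = -0.3, gain_t = 0.3,
                          amp_t = log2(5 / 2)) {
  stopifnot(loss_t < 0, gain_t > 0, gain_t < amp_t)
  m <- segments$mean_logR
  call <- integer(nrow(segments))
  call[m <= loss_t] <- -1L
  call[m >= gain_t] <- 1L
  call[m >= amp_t] <- 2L
  segments$call <- call
  segments
}

#' Classify segment scope: whole chromosome, whole arm, or focal
#'
#' A segment is whole-arm when it covers at least `arm_fraction` of one arm's
#' probes and less of the other, whole-chromosome when it covers at least
#' `arm_fraction` of both arms, focal otherwise.
#'
#' @param segments data.frame with `chromosome`, `start_idx`, `end_idx`
#'   (chromosome-local half-open probe indices).
#' @param annotation probe annotation.
#' @param arm_fraction coverage fraction defining "whole" (default 0.9).
#' @return `segments` with a `scope` column.
#' @export
classify_scope <- function(segments, annotation, arm_fraction = 0.9) {
  stopifnot(arm_fraction > 0.5, arm_fraction <= 1)
  scope <- character(nrow(segments))
  for (chr in unique(segments$chromosome)) {
    arms <- annotation$arm[annotation$chromosome == chr]
    idx <- which(segments$chromosome == chr)
    if (!length(arms)) {
      warning("chromosome ", chr, " lacks arm annotation; scope = focal")
      scope[idx] <- "focal"
      next
    }
    n_arm <- c(p = sum(arms == "p"), q = sum(arms == "q"))
    for (i in idx) {
      probes <- arms[segments$start_idx[i]:(segments$end_idx[i] - 1L)]
      cov <- c(p = sum(probes == "p"), q = sum(probes == "q")) /
        pmax(n_arm, 1L)
      cov[n_arm == 0] <- 0
      scope[i] <- if (all(cov >= arm_fraction)) "whole_chromosome"
      else if (any(cov >= arm_fraction)) "whole_arm"
      else "focal"
    }
  }
  segments$scope <- scope
  segments
}

#' Segment, call and scope one sample genome-wide
#'
#' Runs [segment_logR()] per chromosome, tiles the results, assigns calls and
#' scopes. Per-chromosome seeds are derived deterministically from the config
#' seed.
#'
#' @param signals per-sample signal table (`chromosome`, `position`, `logR`,
#'   ... ordered by chromosome and position).
#' @param annotation probe annotation covering the signal probes.
#' @param config a [run_config()].
#' @param sample sample name attached to the output.
#' @return data.frame of segments: `sample`, `chromosome`, `start_idx`,
#'   `end_idx`, `start_bp`, `end_bp`, `n_probes`, `mean_logR`, `call`,
#'   `scope`. Segments tile each chromosome's probe range.
#' @export
segment_sample <- function(signals, annotation, config = run_config(),
                           sample = "sample") {
  chroms <- chrom_order(signals$chromosome)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    sig <- signals[signals$chromosome == chr, , drop = FALSE]
    seed_c <- as.integer((as.numeric(config$seed) + 7919 * ci) %% (2^31 - 1))
    bps <- withCallingHandlers(
      segment_logR(sig$logR, alpha = config$seg_alpha,
                   min_probes = config$seg_min_probes,
                   n_perm = config$seg_n_perm, seed = seed_c),
      warning = function(w) invokeRestart("muffleWarning"))
    seg <- tile_segments(sig$logR, bps, sig$position,
                         min_probes = config$seg_min_probes)
    seg <- cbind(sample = sample, chromosome = chr, seg,
                 stringsAsFactors = FALSE)
    out[[ci]] <- seg
  }
  seg <- do.call(rbind, out)
  seg <- call_segments(seg, config$loss_t, config$gain_t, config$amp_t)
  seg <- classify_scope(seg, annotation, config$arm_fraction)
  rownames(seg) <- NULL
  seg
}

#' Per-probe call vector from tiled segments
#'
#' @param segments one sample's tiled, called segments.
#' @param annotation probe annotation (defines probe order).
#' @return integer vector of calls parallel to `annotation`.
#' @export
probe_calls <- function(segments, annotation) {
  calls <- integer(nrow(annotation))
  offset <- 0L
  for (chr in chrom_order(annotation$chromosome)) {
    n_chr <- sum(annotation$chromosome == chr)
    seg <- segments[segments$chromosome == chr, , drop = FALSE]
    for (i in seq_len(nrow(seg)))
      calls[offset + (seg$start_idx[i]:(seg$end_idx[i] - 1L))] <- seg$call[i]
    offset <- offset + n_chr
  }
  calls
}
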