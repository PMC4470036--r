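#' Per-probe alteration frequency across a cohort
#'
#' @param call_matrix probes x samples integer matrix of calls in
#'   {-1, 0, 1, 2}.
#' @param direction "gain" (calls +1 and +2) or "loss" (call -1).
#' @return numeric vector: fraction of samples altered per probe.
#' @export
probe_frequency <- function(call_matrix, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(call_matrix))
  hit <- if (direction == "gain") call_matrix >= 1L else call_matrix <= -1L
  rowMeans(hit)
}

#' Build a probes x samples call matrix from cohort segments
#'
#' @param cohort_segments data.frame of called segments with a `sample`
#'   column (rbind of [segment_sample()] outputs).
#' @param annotation probe annotation defining probe order.
#' @return integer matrix, probes x samples.
#' @export
cohort_call_matrix <- function(cohort_segments, annotation) {
  samples <- unique(cohort_segments$sample)
  m <- vapply(samples, function(s)
    probe_calls(cohort_segments[cohort_segments$sample == s, , drop = FALSE],
                annotation),
    integer(nrow(annotation)))
  dimnames(m) <- list(annotation$probe_id, samples)
  m
}

#' Minimal common regions by a segment-relocation permutation test
#'
#' Under the null that alterations are randomly located in the genome, each
#' permutation relocates every sample's altered segments (sizes in probes
#' preserved) to uniformly random positions — genome-wide by default, within
#' the original chromosome with `relocation = "chromosome"` — rejecting
#' within-sample overlaps. Per-probe p-values compare the observed altered
#' frequency against the permutation null; with `p_method = "pooled"` (the
#' default) the null distribution is pooled over permutations and probes
#' (probes are exchangeable under uniform relocation), which gives p-value
#' resolution 1 / (n_perm x n_probes); `"per_probe"` uses the probe's own
#' n_perm draws only, p = (1 + #exceedances) / (n_perm + 1). P-values are
#' Benjamini-Hochberg adjusted across all probes; maximal runs of consecutive
#' probes with adjusted p below `alpha` become MCRs.
#'
#' @param cohort_segments called cohort segments (with `sample`).
#' @param annotation probe annotation.
#' @param direction "gain" or "loss".
#' @param n_perm number of relocation permutations (default 1000; < 100
#'   gives a resolution warning).
#' @param alpha FDR level for MCR membership (default 0.05).
#' @param seed integer seed.
#' @param relocation "genome" or "chromosome".
#' @param p_method "pooled" or "per_probe".
#' @return data.frame of MCRs: `chromosome`, `start_bp`, `end_bp`,
#'   `direction`, `n_probes`, `frequency` (maximum per-probe cohort frequency
#'   in the region), `p_adjusted` (minimum adjusted p in the region).
#' @export
mcr_permutation_test <- function(cohort_segments, annotation,
                                 direction = c("gain", "loss"),
                                 n_perm = 1000L, alpha = 0.05, seed,
                                 relocation = c("genome", "chromosome"),
                                 p_method = c("pooled", "per_probe")) {
  direction <- match.arg(direction)
  relocation <- match.arg(relocation)
  p_method <- match.arg(p_method)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_perm < 100) warning("n_perm < 100 gives poor p-value resolution")
  calls <- cohort_call_matrix(cohort_segments, annotation)
  n_probes <- nrow(calls)
  n_samples <- ncol(calls)
  obs_freq <- probe_frequency(calls, direction)
  obs_count <- as.integer(round(obs_freq * n_samples))

  # altered segment lengths (in probes) per sample, with chromosome of origin
  want <- if (direction == "gain") c(1L, 2L) else -1L
  alt <- cohort_segments[cohort_segments$call %in% want, , drop = FALSE]
  if (!nrow(alt)) return(empty_mcr())

  chroms <- chrom_order(annotation$chromosome)
  chr_sizes <- vapply(chroms, function(ch)
    sum(annotation$chromosome == ch), integer(1))
  chr_offsets <- stats::setNames(cumsum(c(0L, head(chr_sizes, -1))), chroms)

  set.seed(as.integer(seed))
  exceed <- integer(n_probes)          # per-probe null exceedances
  null_counts <- integer(n_samples + 1L)  # pooled histogram of null counts
  samples <- unique(alt$sample)
  seg_by_sample <- split(alt, alt$sample)

  for (b in seq_len(n_perm)) {
    delta <- integer(n_probes + 1L)
    for (s in samples) {
      lens <- seg_by_sample[[s]]$n_probes
      seg_chr <- seg_by_sample[[s]]$chromosome
      placed <- matrix(0L, 0, 2)
      for (j in seq_along(lens)) {
        L <- lens[j]
        for (try in 1:100) {
          if (relocation == "genome") {
            if (L > n_probes) { st <- 1L; L <- n_probes }
            st <- sample.int(n_probes - L + 1L, 1L)
          } else {
            sz <- chr_sizes[[seg_chr[j]]]
            Lc <- min(L, sz)
            st <- chr_offsets[[seg_chr[j]]] +
              sample.int(sz - Lc + 1L, 1L)
            L <- Lc
          }
          en <- st + L - 1L
          if (!nrow(placed) ||
              !any(st <= placed[, 2] & en >= placed[, 1])) break
        }
        placed <- rbind(placed, c(st, en))
        delta[st] <- delta[st] + 1L
        delta[en + 1L] <- delta[en + 1L] - 1L
      }
    }
    cnt <- cumsum(delta[seq_len(n_probes)])
    cnt[cnt > n_samples] <- n_samples    # overlap fallback guard
    if (p_method == "pooled") {
      tb <- tabulate(cnt + 1L, nbins = n_samples + 1L)
      null_counts <- null_counts + tb
    } else {
      exceed <- exceed + (cnt >= obs_count)
    }
  }

  p <- if (p_method == "pooled") {
    tail_ge <- rev(cumsum(rev(null_counts)))   # #null draws with count >= k
    total <- sum(null_counts)
    (1 + tail_ge[obs_count + 1L]) / (total + 1)
  } else {
    (1 + exceed) / (n_perm + 1)
  }
  p[obs_count == 0L] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")

  sig <- p_adj < alpha
  if (!any(sig)) return(empty_mcr())
  out <- list()
  for (chr in chroms) {
    idx <- which(annotation$chromosome == chr)
    if (!any(sig[idx])) next
    r <- rle(sig[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      probes <- idx[starts[k]:ends[k]]
      out[[length(out) + 1]] <- data.frame(
        chromosome = chr,
        start_bp = annotation$position[probes[1]] - 1,
        end_bp = annotation$position[probes[length(probes)]],
        direction = direction, n_probes = length(probes),
        frequency = max(obs_freq[probes]),
        p_adjusted = min(p_adj[probes]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_mcr <- function() {
  data.frame(chromosome = character(0), start_bp = numeric(0),
             end_bp = numeric(0), direction = character(0),
             n_probes = integer(0), frequency = numeric(0),
             p_adjusted = numeric(0))
}

#' Regions recurrently amplified across samples
#'
#' Maximal probe runs where at least `min_samples` samples carry a +2 call.
#'
#' @param call_matrix probes x samples call matrix.
#' @param annotation probe annotation.
#' @param min_samples recurrence threshold (default 3).
#' @return data.frame: `chromosome`, `start_bp`, `end_bp`, `n_probes`,
#'   `n_samples`, `samples` (comma-joined names).
#' @export
recurrent_amplifications <- function(call_matrix, annotation,
                                     min_samples = 3L) {
  amp_count <- rowSums(call_matrix == 2L)
  hit <- amp_count >= min_samples
  out <- list()
  for (chr in chrom_order(annotation$chromosome)) {
    idx <- which(annotation$chromosome == chr)
    if (!any(hit[idx])) next
    r <- rle(hit[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      probes <- idx[starts[k]:ends[k]]
      in_reg <- colSums(call_matrix[probes, , drop = FALSE] == 2L) > 0
      out[[length(out) + 1]] <- data.frame(
        chromosome = chr,
        start_bp = annotation$position[probes[1]] - 1,
        end_bp = annotation$position[probes[length(probes)]],
        n_probes = length(probes),
        n_samples = max(amp_count[probes]),
        samples = paste(colnames(call_matrix)[in_reg], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_probes = integer(0),
                      n_samples = integer(0), samples = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Whole-chromosome / arm alteration count table
#'
#' Counts, per chromosome, the samples with a whole-chromosome gain or loss
#' and with p- or q-arm gains/losses. A whole-chromosome event is counted
#' once and never re-counted as two arm events.
#'
#' @param cohort_segments called, scope-classified cohort segments.
#' @param annotation probe annotation (defines the chromosome set).
#' @return data.frame, one row per chromosome: `whole_loss`, `p_loss`,
#'   `q_loss`, `whole_gain`, `p_gain`, `q_gain`.
#' @export
arm_alteration_table <- function(cohort_segments, annotation) {
  chroms <- chrom_order(annotation$chromosome)
  res <- data.frame(chromosome = chroms, whole_loss = 0L, p_loss = 0L,
                    q_loss = 0L, whole_gain = 0L, p_gain = 0L, q_gain = 0L,
                    stringsAsFactors = FALSE)
  alt <- cohort_segments[cohort_segments$call != 0L, , drop = FALSE]
  for (i in seq_len(nrow(alt))) {
    chr <- alt$chromosome[i]
    ri <- match(chr, chroms)
    dir <- if (alt$call[i] > 0L) "gain" else "loss"
    if (alt$scope[i] == "whole_chromosome") {
      col <- paste0("whole_", dir)
      res[ri, col] <- res[ri, col] + 1L
    } else if (alt$scope[i] == "whole_arm") {
      arms <- annotation$arm[annotation$chromosome == chr]
      probes <- arms[alt$start_idx[i]:(alt$end_idx[i] - 1L)]
      arm <- names(which.max(table(probes)))
      col <- paste0(arm, "_", dir)
      res[ri, col] <- res[ri, col] + 1L
    }
  }
  res
}
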