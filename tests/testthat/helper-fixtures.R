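# shared desk-scale fixtures built in code

# two equal 150 Mb chromosomes, ~37.5 kb spacing
small_annotation <- function(n_probes = 4000,
                             sizes = c("1" = 150e6, "2" = 150e6)) {
  make_probe_annotation(n_probes, chrom_sizes = sizes)
}

# diploid signal table with no events
diploid_sample <- function(annotation, seed, noise = noise_model()) {
  simulate_sample(event_plan("null"), annotation, noise, seed = seed)$signals
}

# manual segment row builder (chromosome-local half-open probe indices)
make_segment <- function(chromosome, start_idx, end_idx, annotation,
                         mean_logR, call, sample = "s1", scope = "focal") {
  pos <- annotation$position[annotation$chromosome == chromosome]
  data.frame(sample = sample, chromosome = chromosome,
             start_idx = start_idx, end_idx = end_idx,
             start_bp = pos[start_idx] - 1, end_bp = pos[end_idx - 1],
             n_probes = end_idx - start_idx, mean_logR = mean_logR,
             call = as.integer(call), scope = scope,
             stringsAsFactors = FALSE)
}

# independent oracle: exact two-sided rank-sum p by full enumeration of
# which ranks belong to group x
enumerate_ranksum_p <- function(x, y) {
  n <- length(x) + length(y)
  w_obs <- sum(rank(c(x, y))[seq_along(x)])
  combos <- utils::combn(n, length(x))
  w_all <- colSums(matrix(seq_len(n)[combos], nrow = length(x)))
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# independent oracle: 2x2 chi-square by the textbook formula
chi2_formula <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
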