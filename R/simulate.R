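#' Noise model for the allele-specific array simulator
#'
#' @param logR_sd per-probe LogR noise sd (default 0.15, typical for
#'   high-density SNP arrays).
#' @param baf_sd BAF noise sd at a balanced heterozygous locus (default
#'   0.03). Homozygous-state BAF noise is compressed toward the rails, as on
#'   real arrays, and is drawn at `baf_sd / 2`.
#' @param dropout per-probe missingness rate (default 0.005).
#' @param het_fraction fraction of loci heterozygous in the germline
#'   (default 0.3).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(logR_sd = 0.15, baf_sd = 0.03, dropout = 0.005,
                        het_fraction = 0.3) {
  stopifnot(is.finite(logR_sd), logR_sd >= 0, is.finite(baf_sd), baf_sd >= 0,
            dropout >= 0, dropout < 1, het_fraction > 0, het_fraction < 1)
  structure(list(logR_sd = logR_sd, baf_sd = baf_sd, dropout = dropout,
                 het_fraction = het_fraction), class = "noise_model")
}

#' Plan of copy-number / allelic events for one sample
#'
#' Events are encoded by total copy number and minor-allele copy number:
#' `total = 2, minor = 1` is normal; `total = 2, minor = 0` is copy-neutral
#' LOH (uniparental disomy); `total = 1` a hemizygous deletion; `total = 0` a
#' homozygous deletion; `total >= 5` an amplification.
#'
#' @param sample sample name.
#' @param chromosome,start,end,total,minor parallel event vectors; `start`,
#'   `end` are 0-based half-open bp.
#' @param scope optional scope hints ("focal", "whole_arm",
#'   "whole_chromosome").
#' @return data.frame of class `event_plan`.
#' @export
event_plan <- function(sample, chromosome = character(0),
                       start = numeric(0), end = numeric(0),
                       total = integer(0), minor = integer(0),
                       scope = NULL) {
  n <- length(chromosome)
  if (is.null(scope)) scope <- rep("focal", n)
  ev <- data.frame(sample = rep(sample, n),
                   chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   total = as.integer(total), minor = as.integer(minor),
                   scope = scope, stringsAsFactors = FALSE)
  if (n) {
    stopifnot(all(ev$end > ev$start), all(ev$total >= 0), all(ev$minor >= 0),
              all(ev$minor * 2 <= ev$total | ev$total == 0),
              all(ev$minor[ev$total == 0] == 0))
    for (chr in unique(ev$chromosome)) {
      e <- ev[ev$chromosome == chr, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
        stop("overlapping events on chromosome ", chr, " of sample ", sample)
    }
  }
  class(ev) <- c("event_plan", "data.frame")
  ev
}

#' Simulate one allele-specific SNP-array sample
#'
#' For a probe carried at `total` copies c > 0 the expected LogR is
#' log2(c/2); the expected BAF of a locus carrying b copies of the B allele
#' is b/c. Homozygous deletions (c = 0) give a strongly negative LogR (drawn
#' around -3: arrays saturate rather than reach -Inf) and a BAF that is
#' uniform noise on \[0,1\]. Germline genotypes are drawn per locus with the
#' model's heterozygous fraction, distorted by the planted events, and then
#' re-called from the noisy BAF with [call_genotypes()], so the emitted
#' genotype column behaves like a genotyping-software call.
#'
#' @param plan an [event_plan()] (may be empty: diploid genome).
#' @param annotation probe annotation.
#' @param noise a [noise_model()].
#' @param seed integer seed; mandatory, reproducibility is part of the
#'   contract.
#' @return list with `signals` (probe_id, chromosome, position, logR, baf,
#'   genotype) and `truth` (the planted events with the sample name,
#'   0-based half-open coordinates).
#' @export
simulate_sample <- function(plan, annotation, noise = noise_model(),
                            seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  validate_annotation(annotation)
  stopifnot(inherits(noise, "noise_model"))
  for (i in seq_len(nrow(plan))) {
    chr_ann <- annotation[annotation$chromosome == plan$chromosome[i], ]
    if (!nrow(chr_ann))
      stop("event on unannotated chromosome ", plan$chromosome[i])
    spacing <- stats::median(diff(chr_ann$position))
    if (plan$start[i] < 0 ||
        plan$end[i] > max(chr_ann$position) + spacing)
      stop("event beyond annotated extent of chromosome ", plan$chromosome[i])
    covered <- any(chr_ann$position - 1 >= plan$start[i] &
                     chr_ann$position - 1 < plan$end[i])
    if (!covered)
      stop("event on chromosome ", plan$chromosome[i], " covers no probes")
  }
  set.seed(as.integer(seed))
  n <- nrow(annotation)
  h <- noise$het_fraction
  gt0 <- sample(c("AA", "AB", "BB"), n, replace = TRUE,
                prob = c((1 - h) / 2, h, (1 - h) / 2))
  b0 <- c(AA = 0, AB = 1, BB = 2)[gt0]

  total <- rep(2L, n)
  minor <- rep(1L, n)
  for (i in seq_len(nrow(plan))) {
    idx <- which(annotation$chromosome == plan$chromosome[i] &
                   annotation$position - 1 >= plan$start[i] &
                   annotation$position - 1 < plan$end[i])
    total[idx] <- plan$total[i]
    minor[idx] <- plan$minor[i]
  }

  # B-allele copies after the event: homozygous loci keep a single allele;
  # heterozygous loci assign B to the major or minor haplotype at random
  b_is_major <- stats::runif(n) < 0.5
  b_cop <- ifelse(gt0 == "AB",
                  ifelse(b_is_major, total - minor, minor),
                  (b0 / 2) * total)
  exp_baf <- ifelse(total > 0, b_cop / total, NA_real_)
  hom_state <- !is.na(exp_baf) & (exp_baf <= 0 | exp_baf >= 1)
  baf_sd_vec <- ifelse(hom_state, noise$baf_sd / 2, noise$baf_sd)
  baf <- ifelse(total > 0,
                pmin(1, pmax(0, exp_baf + stats::rnorm(n, 0, baf_sd_vec))),
                stats::runif(n))
  logR <- ifelse(total > 0, log2(total / 2), -3) +
    stats::rnorm(n, 0, noise$logR_sd)
  genotype <- call_genotypes(baf)
  if (noise$dropout > 0) {
    drop <- stats::runif(n) < noise$dropout
    logR[drop] <- NA_real_
    baf[drop] <- NA_real_
    genotype[drop] <- "NC"
  }
  signals <- data.frame(probe_id = annotation$probe_id,
                        chromosome = annotation$chromosome,
                        position = annotation$position,
                        logR = logR, baf = baf, genotype = genotype,
                        stringsAsFactors = FALSE)
  truth <- as.data.frame(plan)
  list(signals = signals, truth = truth)
}

#' Simulate a cohort with an optional shared event plus random background
#'
#' The shared event template is planted in `round(penetrance * n_samples)`
#' samples (chosen at random but reproducibly). Background events are placed
#' uniformly on the genome with sizes drawn log-uniformly between 1 Mb and
#' the length of a chromosome arm, rejecting overlaps within a sample.
#'
#' @param n_samples number of samples (>= 2).
#' @param annotation probe annotation.
#' @param shared_event one-row [event_plan()]-like data.frame (chromosome,
#'   start, end, total, minor) or NULL.
#' @param penetrance fraction of samples carrying the shared event, in (0,1].
#' @param background_rate expected background events per sample (Poisson).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return list with `signals` (named list of per-sample signal tables) and
#'   `truth` (data.frame of all planted events, with a `shared` flag).
#' @export
simulate_cohort <- function(n_samples, annotation, shared_event = NULL,
                            penetrance = 1, background_rate = 0,
                            noise = noise_model(), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(n_samples >= 2)
  if (!is.null(shared_event) && (penetrance <= 0 || penetrance > 1))
    stop("penetrance must be in (0, 1]")
  set.seed(as.integer(seed))
  samples <- sprintf("S%02d", seq_len(n_samples))
  carriers <- if (!is.null(shared_event))
    sort(sample(n_samples, round(penetrance * n_samples)))
  else integer(0)

  chrom_len <- tapply(annotation$position, annotation$chromosome, max)
  chroms <- names(chrom_len)
  plans <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    ev <- if (i %in% carriers) {
      data.frame(chromosome = shared_event$chromosome,
                 start = shared_event$start, end = shared_event$end,
                 total = shared_event$total, minor = shared_event$minor,
                 scope = "focal", shared = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(chromosome = character(0), start = numeric(0),
                 end = numeric(0), total = integer(0), minor = integer(0),
                 scope = character(0), shared = logical(0))
    }
    n_bg <- stats::rpois(1, background_rate)
    tries <- 0
    while (n_bg > 0 && tries < 100 * n_bg) {
      tries <- tries + 1
      chr <- sample(chroms, 1, prob = as.numeric(chrom_len))
      arm_len <- chrom_len[[chr]] * 0.5
      size <- exp(stats::runif(1, log(1e6), log(max(arm_len, 2e6))))
      start <- floor(stats::runif(1, 0, max(1, chrom_len[[chr]] - size)))
      end <- start + size
      same <- ev[ev$chromosome == chr, , drop = FALSE]
      if (nrow(same) && any(start < same$end & end > same$start)) next
      dir_gain <- stats::runif(1) < 0.5
      ev <- rbind(ev, data.frame(chromosome = chr, start = start, end = end,
                                 total = if (dir_gain) 3L else 1L,
                                 minor = if (dir_gain) 1L else 0L,
                                 scope = "focal", shared = FALSE,
                                 stringsAsFactors = FALSE))
      n_bg <- n_bg - 1
    }
    plans[[i]] <- ev
  }
  sample_seeds <- as.integer((as.numeric(seed) + 104729 * seq_len(n_samples)) %%
                               (2^31 - 1))
  signals <- vector("list", n_samples)
  truth <- list()
  for (i in seq_len(n_samples)) {
    ev <- plans[[i]]
    plan <- event_plan(samples[i], ev$chromosome, ev$start, ev$end,
                       ev$total, ev$minor, ev$scope)
    sim <- simulate_sample(plan, annotation, noise, seed = sample_seeds[i])
    signals[[i]] <- sim$signals
    if (nrow(ev))
      truth[[length(truth) + 1]] <- cbind(sim$truth, shared = ev$shared)
  }
  truth <- if (length(truth)) do.call(rbind, truth)
  else data.frame(sample = character(0), chromosome = character(0),
                  start = numeric(0), end = numeric(0), total = integer(0),
                  minor = integer(0), scope = character(0),
                  shared = logical(0))
  rownames(truth) <- NULL
  list(signals = stats::setNames(signals, samples), truth = truth)
}

#' Simulate a gene x sample expression matrix from class centroids
#'
#' Each sample equals its class centroid plus independent Gaussian noise.
#'
#' @param centroids gene x class numeric matrix (>= 10 genes, >= 2 classes,
#'   named dimensions).
#' @param assignment named character vector mapping sample name -> class.
#' @param sd noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return gene x sample matrix.
#' @export
simulate_expression <- function(centroids, assignment, sd, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(is.matrix(centroids), nrow(centroids) >= 10,
            ncol(centroids) >= 2, !is.null(colnames(centroids)),
            sd >= 0)
  unknown <- setdiff(unique(assignment), colnames(centroids))
  if (length(unknown))
    stop("assignment references unknown class(es): ",
         paste(unknown, collapse = ", "))
  cc <- stats::cor(centroids)
  if (any(cc[upper.tri(cc)] > 1 - 1e-12))
    warning("two centroids are effectively identical; ",
            "classification between them is a tie")
  set.seed(as.integer(seed))
  samples <- if (!is.null(names(assignment))) names(assignment)
  else sprintf("S%02d", seq_along(assignment))
  m <- centroids[, assignment, drop = FALSE] +
    matrix(stats::rnorm(nrow(centroids) * length(assignment), 0, sd),
           nrow(centroids))
  dimnames(m) <- list(rownames(centroids), samples)
  m
}
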