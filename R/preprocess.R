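#' Normalize raw R intensities by multiplicative median scaling
#'
#' Scales a sample's R intensities so that its median autosomal intensity
#' equals the reference pool's median autosomal mean intensity. This is a
#' deliberately simple, documented normalization: downstream stages depend
#' only on the LogR ratio being centered at 0 for two copies.
#'
#' @param R named or plain numeric vector of raw intensities (> 0 where not
#'   missing), parallel to `annotation`.
#' @param annotation probe annotation (autosomes identified as "1".."22").
#' @param pool reference pool data.frame (`probe_id`, `mean_R`), parallel or
#'   matchable by probe id.
#' @return normalized intensity vector (missing values stay missing).
#' @export
normalize_R <- function(R, annotation, pool) {
  stopifnot(length(R) == nrow(annotation))
  if (all(is.na(R))) stop("all probe intensities missing")
  if (any(R[!is.na(R)] <= 0)) stop("non-positive intensity encountered")
  mean_R <- pool$mean_R[match(annotation$probe_id, pool$probe_id)]
  auto <- annotation$chromosome %in% as.character(1:22)
  scale <- stats::median(mean_R[auto], na.rm = TRUE) /
    stats::median(R[auto], na.rm = TRUE)
  R * scale
}

#' LogR ratio of normalized intensities against a reference pool
#'
#' logR = log2(R / mean_R). Probes with missing intensity or a non-positive
#' pool mean are flagged missing.
#'
#' @param R normalized intensity vector, parallel to `annotation`.
#' @param annotation probe annotation.
#' @param pool reference pool (`probe_id`, `mean_R`).
#' @return numeric LogR vector.
#' @export
compute_logR <- function(R, annotation, pool) {
  mean_R <- pool$mean_R[match(annotation$probe_id, pool$probe_id)]
  out <- ifelse(!is.na(R) & !is.na(mean_R) & mean_R > 0,
                log2(R / mean_R), NA_real_)
  out
}

#' Call genotypes from BAF
#'
#' AA if baf <= hom_window; BB if baf >= 1 - hom_window; AB if
#' |baf - 0.5| <= het_window; NC otherwise (including missing BAF).
#'
#' @param baf numeric vector in \[0,1\] (NA allowed).
#' @param hom_window half-width of the homozygous rails (default 0.05).
#' @param het_window half-width of the heterozygous band (default 0.15).
#' @return character vector in {AA, AB, BB, NC}.
#' @export
call_genotypes <- function(baf, hom_window = 0.05, het_window = 0.15) {
  stopifnot(hom_window > 0, hom_window < het_window,
            hom_window + het_window < 0.5 + 1e-12)
  out <- rep("NC", length(baf))
  out[!is.na(baf) & baf <= hom_window] <- "AA"
  out[!is.na(baf) & baf >= 1 - hom_window] <- "BB"
  out[!is.na(baf) & abs(baf - 0.5) <= het_window] <- "AB"
  out
}

#' Build a synthetic reference intensity pool
#'
#' Pool mean intensities on a unit scale where 1.0 corresponds to two copies.
#' The mixed pool averages male and female X/Y dosages (1.5 X copies, 0.5 Y
#' copies); sex-specific pools carry the true dosage; the female Y entry is a
#' small background level.
#'
#' @param annotation probe annotation.
#' @param sex "mixed", "male" or "female".
#' @return data.frame `probe_id`, `mean_R`, `sex`.
#' @export
make_reference_pool <- function(annotation, sex = c("mixed", "male",
                                                    "female")) {
  sex <- match.arg(sex)
  copies <- rep(2, nrow(annotation))
  x <- annotation$chromosome == "X"
  y <- annotation$chromosome == "Y"
  copies[x] <- switch(sex, mixed = 1.5, male = 1, female = 2)
  copies[y] <- switch(sex, mixed = 0.5, male = 1, female = 0.1)
  data.frame(probe_id = annotation$probe_id, mean_R = copies / 2,
             sex = sex, stringsAsFactors = FALSE)
}

#' Infer sample sex from Y-probe dosage and select the reference pool
#'
#' The mean LogR of Y probes against the mixed pool is the evidence: above
#' the threshold the sample is called male. Y evidence overrides conflicting
#' metadata (the presence of a Y chromosome is treated as reliable); the
#' conflict is reported. Without Y probes the metadata is used; failing that
#' the sex is unknown and X analysis should be skipped.
#'
#' Autosomal LogR is computed against the mixed pool and X-chromosome LogR
#' against the sex-matched pool; probes on neither list (e.g. pseudoautosomal
#' X/Y probes) keep the mixed pool.
#'
#' @param R normalized intensities, parallel to `annotation`.
#' @param annotation probe annotation (ideally with Y probes).
#' @param pools named list of reference pools: `mixed`, `male`, `female`.
#' @param metadata_sex optional declared sex ("male"/"female"/NA).
#' @param y_threshold mean Y LogR above which the sample is male
#'   (default -1).
#' @return list with `sex` (data.frame: sample fields `sex`, `y_evidence`)
#'   and `logR` (per-probe LogR with X against the sex-matched pool).
#' @export
infer_sex_and_select_pool <- function(R, annotation, pools,
                                      metadata_sex = NA,
                                      y_threshold = -1.0) {
  stopifnot(all(c("mixed", "male", "female") %in% names(pools)))
  logR_mixed <- compute_logR(R, annotation, pools$mixed)
  y_idx <- which(annotation$chromosome == "Y")
  y_evidence <- if (length(y_idx)) mean(logR_mixed[y_idx], na.rm = TRUE)
  else NA_real_
  sex <- if (!is.na(y_evidence)) {
    called <- if (y_evidence > y_threshold) "male" else "female"
    if (!is.na(metadata_sex) && metadata_sex != called)
      message("declared sex '", metadata_sex,
              "' conflicts with Y evidence; Y evidence wins ('",
              called, "')")
    called
  } else if (!is.na(metadata_sex)) {
    as.character(metadata_sex)
  } else {
    warning("no Y probes and no metadata: sex unknown, X analysis skipped")
    "unknown"
  }
  logR <- logR_mixed
  if (sex %in% c("male", "female")) {
    x_idx <- which(annotation$chromosome == "X")
    logR[x_idx] <- compute_logR(R, annotation, pools[[sex]])[x_idx]
  }
  list(sex = data.frame(sex = sex, y_evidence = y_evidence,
                        stringsAsFactors = FALSE),
       logR = logR)
}
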