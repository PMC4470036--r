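#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline with its documented
#' default. All thresholds are validated against their legal ranges. The
#' configuration (including the seed) is echoed into output headers by the
#' writers so that any result file records how it was produced.
#'
#' @param seed integer seed recorded and used for every stochastic step.
#' @param ... overrides for any default listed below.
#' @return a named list of class `cnupd_config`.
#' @details Defaults:
#' \itemize{
#'   \item noise model: `logR_sd` 0.15, `baf_sd` 0.03, `dropout` 0.005,
#'     `het_fraction` 0.3
#'   \item genotype caller: `hom_window` 0.05, `het_window` 0.15
#'   \item segmentation: `seg_alpha` 0.01, `seg_min_probes` 5, `seg_n_perm`
#'     1000
#'   \item calling: `loss_t` -0.3, `gain_t` 0.3, `amp_t` log2(5/2)
#'   \item scope: `arm_fraction` 0.9
#'   \item allelic state: `baf_hom_tol` 0.05, `logR_decline` 0.1, `hd_logR`
#'     -1.0, `abnormal_baf_dist` 0.1
#'   \item UPD: `upd_window` 50, `upd_het_max` 0.02, `upd_logR_tol` 0.15,
#'     `upd_min_size_mb` 2, `upd_min_probes` 50, `near_whole` 0.8
#'   \item MCR: `mcr_n_perm` 1000, `mcr_alpha` 0.05, `mcr_relocation`
#'     "genome", `mcr_p_method` "pooled"
#'   \item gene status: `min_probe_support` 2
#'   \item sexing: `y_logR_threshold` -1.0
#'   \item `build` genome build label (metadata only, never interpreted)
#' }
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    build = "unspecified",
    logR_sd = 0.15, baf_sd = 0.03, dropout = 0.005, het_fraction = 0.3,
    hom_window = 0.05, het_window = 0.15,
    seg_alpha = 0.01, seg_min_probes = 5L, seg_n_perm = 1000L,
    loss_t = -0.3, gain_t = 0.3, amp_t = log2(5 / 2),
    arm_fraction = 0.9,
    baf_hom_tol = 0.05, logR_decline = 0.1, hd_logR = -1.0,
    abnormal_baf_dist = 0.1,
    upd_window = 50L, upd_het_max = 0.02, upd_logR_tol = 0.15,
    upd_min_size_mb = 2, upd_min_probes = 50L, near_whole = 0.8,
    mcr_n_perm = 1000L, mcr_alpha = 0.05,
    mcr_relocation = "genome", mcr_p_method = "pooled",
    min_probe_support = 2L,
    y_logR_threshold = -1.0
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  class(cfg) <- "cnupd_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    is.finite(cfg$seed),
    cfg$logR_sd > 0, cfg$baf_sd >= 0,
    cfg$dropout >= 0, cfg$dropout < 1,
    cfg$het_fraction > 0, cfg$het_fraction < 1,
    cfg$hom_window > 0, cfg$hom_window < cfg$het_window,
    cfg$hom_window + cfg$het_window < 0.5 + 1e-12,
    cfg$seg_alpha > 0, cfg$seg_alpha < 1, cfg$seg_min_probes >= 2,
    cfg$seg_n_perm >= 10,
    cfg$loss_t < 0, cfg$gain_t > 0, cfg$gain_t < cfg$amp_t,
    cfg$arm_fraction > 0.5, cfg$arm_fraction <= 1,
    cfg$baf_hom_tol > 0, cfg$logR_decline >= 0, cfg$hd_logR < 0,
    cfg$upd_het_max >= 0, cfg$upd_het_max < cfg$het_fraction,
    cfg$upd_logR_tol > 0, cfg$upd_min_size_mb > 0, cfg$upd_min_probes >= 2,
    cfg$near_whole > 0.5, cfg$near_whole <= 1,
    cfg$mcr_alpha > 0, cfg$mcr_alpha < 1,
    cfg$mcr_relocation %in% c("genome", "chromosome"),
    cfg$mcr_p_method %in% c("pooled", "per_probe"),
    cfg$min_probe_support >= 1
  )
  invisible(cfg)
}

#' Write / read a run configuration (YAML)
#'
#' @param config a `cnupd_config`.
#' @param path file path.
#' @return `read_config` returns a validated `cnupd_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cnupd_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' One-line parameter echo for output headers
#' @keywords internal
config_header <- function(config) {
  if (is.null(config)) return("# cnupd")
  paste0("# cnupd seed=", config$seed, " build=", config$build)
}
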