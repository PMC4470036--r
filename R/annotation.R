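#' Build a synthetic probe annotation
#'
#' Generates a desk-scale stand-in for a high-density SNP-array manifest:
#' probes equally spaced along each chromosome, with a p/q arm boundary at a
#' fixed fraction of the chromosome length and a coarse synthetic cytoband
#' label. The default (20,000 probes over chromosomes 1-22 and X, sizes
#' loosely proportional to the human karyotype) is deliberately small; pass a
#' custom `chrom_sizes` for denser designs, e.g. when small (few-Mb) events
#' must be resolvable.
#'
#' Chromosome labels are "1".."22","X","Y" without a "chr" prefix; positions
#' are 1-based probe coordinates; a probe at position p occupies the 0-based
#' half-open interval [p-1, p).
#'
#' @param n_probes total number of probes to distribute (proportional to
#'   chromosome size).
#' @param chrom_sizes named numeric vector of chromosome sizes in bp. Default
#'   approximates the human autosomes + X.
#' @param p_fraction fraction of each chromosome length assigned to the p arm.
#' @param include_y add a Y chromosome (needed for sex inference).
#' @return data.frame with columns `probe_id`, `chromosome`, `position`,
#'   `arm`, `cytoband`, sorted by (chromosome, position).
#' @export
make_probe_annotation <- function(n_probes = 20000,
                                  chrom_sizes = default_chrom_sizes(),
                                  p_fraction = 0.4,
                                  include_y = FALSE) {
  stopifnot(n_probes >= length(chrom_sizes), all(chrom_sizes > 0))
  if (include_y && !"Y" %in% names(chrom_sizes))
    chrom_sizes <- c(chrom_sizes, Y = 57e6)
  n_per <- pmax(round(n_probes * chrom_sizes / sum(chrom_sizes)), 2L)
  out <- lapply(names(chrom_sizes), function(chr) {
    n <- n_per[[chr]]
    size <- chrom_sizes[[chr]]
    pos <- round(seq(size / (2 * n), size - size / (2 * n), length.out = n))
    arm <- ifelse(pos <= size * p_fraction, "p", "q")
    band_idx <- pmin(9L, floor(10 * pos / size) + 1L)
    data.frame(
      probe_id = sprintf("P_%s_%05d", chr, seq_len(n)),
      chromosome = chr,
      position = as.integer(pos),
      arm = arm,
      cytoband = paste0(chr, arm, band_idx),
      stringsAsFactors = FALSE
    )
  })
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  validate_annotation(ann)
  ann
}

#' Approximate human chromosome sizes (bp)
#'
#' Rounded autosome + X sizes used by the default synthetic annotation. The
#' pipeline never assumes a genome build; these are scale realism only.
#' @return named numeric vector.
#' @export
default_chrom_sizes <- function() {
  mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
          115, 107, 102, 90, 81, 78, 59, 63, 48, 51, 155)
  stats::setNames(mb * 1e6, c(as.character(1:22), "X"))
}

validate_annotation <- function(annotation) {
  req <- c("probe_id", "chromosome", "position", "arm")
  missing <- setdiff(req, names(annotation))
  if (length(missing))
    stop("annotation lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(annotation$probe_id))
    stop("duplicate probe ids in annotation: ",
         annotation$probe_id[duplicated(annotation$probe_id)][1])
  pos_ok <- vapply(split(annotation$position, annotation$chromosome),
                   function(p) !is.unsorted(p, strictly = TRUE), logical(1))
  if (!all(pos_ok))
    stop("probe positions not strictly increasing on chromosome(s): ",
         paste(names(pos_ok)[!pos_ok], collapse = ", "))
  invisible(annotation)
}

#' Order chromosomes naturally (1..22, X, Y)
#' @param chroms character vector of chromosome labels.
#' @return input levels in karyotype order.
#' @keywords internal
chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  known <- c(as.character(1:22), "X", "Y")
  c(intersect(known, u), setdiff(u, known))
}

#' Per-arm probe counts for one chromosome
#' @keywords internal
arm_probe_counts <- function(annotation, chrom) {
  ann <- annotation[annotation$chromosome == chrom, , drop = FALSE]
  c(p = sum(ann$arm == "p"), q = sum(ann$arm == "q"))
}
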