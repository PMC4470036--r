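#' Read a probe-level signal matrix
#'
#' Parses a tab-separated probe matrix: a `probe_id` column followed by one
#' triplet of columns per sample, named `<sample>.logR`, `<sample>.baf`,
#' `<sample>.gt`. Probes absent from the annotation are dropped (with a
#' message reporting the count); BAF values outside \[0,1\] and non-finite
#' LogR values are flagged missing (`NA`), never silently zeroed; genotype
#' strings outside {AA, AB, BB, NC} become `NC`.
#'
#' @param path file path to the TSV.
#' @param annotation probe annotation (see [make_probe_annotation()]).
#' @return named list with one signal `data.frame` per sample, each with
#'   columns `probe_id`, `chromosome`, `position`, `logR`, `baf`, `genotype`,
#'   ordered by (chromosome, position).
#' @export
read_probe_matrix <- function(path, annotation) {
  validate_annotation(annotation)
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!"probe_id" %in% names(tab)) stop("probe matrix lacks a probe_id column")
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe id in matrix: ",
         tab$probe_id[duplicated(tab$probe_id)][1])
  cols <- setdiff(names(tab), "probe_id")
  m <- regmatches(cols, regexec("^(.*)\\.(logR|baf|gt)$", cols))
  bad <- cols[vapply(m, length, integer(1)) == 0]
  if (length(bad))
    stop("unrecognized column(s), expected <sample>.{logR,baf,gt}: ",
         paste(bad, collapse = ", "))
  samples <- unique(vapply(m, `[`, character(1), 2))
  for (s in samples) {
    need <- paste0(s, ".", c("logR", "baf", "gt"))
    if (!all(need %in% cols))
      stop("incomplete column triplet for sample '", s, "': missing ",
           paste(setdiff(need, cols), collapse = ", "))
  }
  known <- tab$probe_id %in% annotation$probe_id
  if (any(!known)) {
    message(sum(!known), " probe(s) absent from annotation dropped")
    tab <- tab[known, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no annotated probes left in matrix")
  ann <- annotation[match(tab$probe_id, annotation$probe_id), ]
  ord <- order(match(ann$chromosome, chrom_order(ann$chromosome)),
               ann$position)
  tab <- tab[ord, , drop = FALSE]
  ann <- ann[ord, , drop = FALSE]
  out <- lapply(samples, function(s) {
    logR <- as.numeric(tab[[paste0(s, ".logR")]])
    baf <- as.numeric(tab[[paste0(s, ".baf")]])
    gt <- as.character(tab[[paste0(s, ".gt")]])
    logR[!is.finite(logR)] <- NA_real_
    baf[!is.na(baf) & (baf < 0 | baf > 1)] <- NA_real_
    gt[!gt %in% c("AA", "AB", "BB", "NC")] <- "NC"
    data.frame(probe_id = tab$probe_id, chromosome = ann$chromosome,
               position = ann$position, logR = logR, baf = baf,
               genotype = gt, stringsAsFactors = FALSE, row.names = NULL)
  })
  stats::setNames(out, samples)
}

#' Write a probe-level signal matrix
#'
#' Inverse of [read_probe_matrix()]; one `<sample>.{logR,baf,gt}` triplet per
#' sample.
#'
#' @param signals named list of per-sample signal data.frames (all on the
#'   same probe set, same order).
#' @param path output TSV path.
#' @param config optional `cnupd_config`, echoed into a header comment.
#' @export
write_probe_matrix <- function(signals, path, config = NULL) {
  stopifnot(length(signals) >= 1, !is.null(names(signals)))
  base <- signals[[1]]$probe_id
  tab <- data.frame(probe_id = base, stringsAsFactors = FALSE)
  for (s in names(signals)) {
    sig <- signals[[s]]
    if (!identical(sig$probe_id, base))
      stop("sample '", s, "' is not on the shared probe set/order")
    tab[[paste0(s, ".logR")]] <- sig$logR
    tab[[paste0(s, ".baf")]] <- sig$baf
    tab[[paste0(s, ".gt")]] <- sig$genotype
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genomic regions as BED
#'
#' Regions use the package's internal convention (0-based half-open
#' start/end, chromosome labels without prefix); the writer adds the "chr"
#' prefix. Attribute columns beyond chromosome/start/end are serialized from
#' column 4 on. Rows are ordered deterministically by (chromosome, start,
#' end).
#'
#' @param regions data.frame with columns `chromosome`, `start`, `end` plus
#'   arbitrary attribute columns.
#' @param path output path.
#' @param config optional `cnupd_config` echoed as a header comment.
#' @export
write_regions <- function(regions, path, config = NULL) {
  req <- c("chromosome", "start", "end")
  if (!all(req %in% names(regions)))
    stop("regions need columns: ", paste(req, collapse = ", "))
  bad <- which(regions$end <= regions$start)
  if (length(bad))
    stop("interval with end <= start: ", regions$chromosome[bad[1]], ":",
         regions$start[bad[1]], "-", regions$end[bad[1]])
  extra <- setdiff(names(regions), req)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  writeLines(paste0("# columns: chrom start end",
                    if (length(extra)) paste0(" ", paste(extra, collapse = " "))),
             con)
  if (nrow(regions)) {
    ord <- order(match(regions$chromosome, chrom_order(regions$chromosome)),
                 regions$start, regions$end)
    regions <- regions[ord, , drop = FALSE]
    out <- data.frame(chrom = paste0("chr", regions$chromosome),
                      start = format(regions$start, scientific = FALSE,
                                     trim = TRUE),
                      end = format(regions$end, scientific = FALSE,
                                   trim = TRUE),
                      stringsAsFactors = FALSE)
    for (col in extra) out[[col]] <- regions[[col]]
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read regions written by [write_regions()]
#'
#' @param path BED-like file produced by [write_regions()].
#' @return data.frame with `chromosome`, `start`, `end` and any attribute
#'   columns (named from the header comment).
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  header <- grep("^# columns:", lines, value = TRUE)
  cols <- if (length(header))
    strsplit(sub("^# columns: ", "", header[1]), " ")[[1]]
  else c("chrom", "start", "end")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    out$start <- numeric(0); out$end <- numeric(0)
    names(out)[1] <- "chromosome"
    return(out)
  }
  tab <- utils::read.delim(text = body, header = FALSE, col.names = cols,
                           stringsAsFactors = FALSE)
  names(tab)[1] <- "chromosome"
  tab$chromosome <- sub("^chr", "", tab$chromosome)
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  tab
}

#' Read a gene x sample expression matrix (TSV)
#'
#' First column gene identifiers, remaining columns one per sample.
#' @param path TSV path.
#' @return numeric matrix, genes as rownames.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  genes <- tab[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene id: ",
                                 genes[duplicated(genes)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}
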