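#' Load the curated cell-line status table
#'
#' A packaged transcription of the published mutation / copy-number status
#' table for 49 urothelial bladder cancer cell lines. Each status entry keeps
#' its source tag(s) verbatim (numeric superscripts in the original;
#' source "4" is the study's own assay, "." marks an entry printed without a
#' source). Conflicting multi-source reports (e.g. an external homozygous
#' deletion vs an own-data wild type for the same gene) are preserved, not
#' resolved; resolution policies belong to the counting functions
#' ([count_dual_mutants()], [count_gene_loss()]).
#'
#' @return object of class `curated_line_table`: a list with `lines`
#'   (data.frame: `line`, `sex`, `grade`, `instability_group`) and `status`
#'   (data.frame: `line`, `gene`, `field` in {mutation, cn}, `value`,
#'   `sources`).
#' @export
load_table1_fixture <- function() {
  dir <- system.file("extdata", package = "cnupd", mustWork = TRUE)
  lines <- utils::read.delim(file.path(dir, "table1_lines.tsv"),
                             stringsAsFactors = FALSE, fill = TRUE,
                             na.strings = c("NA", ""))
  status <- utils::read.delim(file.path(dir, "table1_status.tsv"),
                              stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(lines$line),
            all(status$line %in% lines$line),
            all(status$field %in% c("mutation", "cn")),
            all(nzchar(status$sources)))
  out <- list(lines = lines, status = status)
  class(out) <- "curated_line_table"
  out
}

#' @export
print.curated_line_table <- function(x, ...) {
  cat("curated_line_table:", nrow(x$lines), "cell lines,",
      nrow(x$status), "status entries,",
      length(unique(x$status$gene)), "genes\n")
  invisible(x)
}

#' Look up the recorded status entries for one line and gene
#'
#' @param table a `curated_line_table`.
#' @param line cell line name (exact match).
#' @param gene gene symbol.
#' @param field "mutation" or "cn"; NULL returns both.
#' @return data.frame of matching entries. Unknown line names are an error.
#' @export
line_gene_status <- function(table, line, gene, field = NULL) {
  stopifnot(inherits(table, "curated_line_table"))
  if (!line %in% table$lines$line)
    stop("unknown cell line: '", line, "'")
  hit <- table$status[table$status$line == line & table$status$gene == gene, ,
                      drop = FALSE]
  if (!is.null(field)) hit <- hit[hit$field == field, , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

# entries whose value denotes a point mutation (not WT/neutral, not an
# amplification or a gene fusion)
is_point_mutation <- function(values) {
  v <- trimws(values)
  !(v %in% c("WT", "N", "Amp")) & !grepl("fusion", v, ignore.case = TRUE)
}

has_own_source <- function(sources) {
  vapply(strsplit(sources, ","), function(s) "4" %in% trimws(s), logical(1))
}

# resolve one line/gene/field to the entries a policy considers
resolve_entries <- function(entries, policy) {
  if (!nrow(entries)) return(entries)
  if (policy == "own_data_precedence") {
    own <- has_own_source(entries$sources)
    if (any(own)) return(entries[own, , drop = FALSE])
  }
  entries
}

#' Count lines mutant in two genes
#'
#' A line counts as mutant in a gene when a considered report is a point
#' mutation; amplifications and gene fusions are excluded. Under
#' `any_source`, every recorded report is considered; under
#' `own_data_precedence`, the study's own assay (source tag 4) overrides
#' external databases when present.
#'
#' @param table a `curated_line_table`.
#' @param gene_a,gene_b gene symbols present in the table.
#' @param policy "any_source" or "own_data_precedence".
#' @return integer count of lines mutant in both genes.
#' @export
count_dual_mutants <- function(table, gene_a, gene_b,
                               policy = c("any_source",
                                          "own_data_precedence")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "curated_line_table"))
  for (g in c(gene_a, gene_b))
    if (!g %in% table$status$gene) stop("gene not in table: ", g)
  mutant_in <- function(gene) {
    st <- table$status[table$status$gene == gene &
                         table$status$field == "mutation", , drop = FALSE]
    hits <- vapply(split(st, st$line), function(e) {
      e <- resolve_entries(e, policy)
      any(is_point_mutation(e$value))
    }, logical(1))
    names(hits)[hits]
  }
  length(intersect(mutant_in(gene_a), mutant_in(gene_b)))
}

#' Count lines with a given copy-number loss status for a gene
#'
#' @param table a `curated_line_table`.
#' @param gene gene symbol.
#' @param status "LOH" or "HD".
#' @param policy as in [count_dual_mutants()]; under `own_data_precedence` an
#'   own-assay report (source 4) overrides external sources, so e.g. an
#'   external HD contradicted by an own-data WT is not counted.
#' @return integer count of lines whose resolved status includes `status`.
#' @export
count_gene_loss <- function(table, gene, status = c("LOH", "HD"),
                            policy = c("own_data_precedence", "any_source")) {
  status <- match.arg(status)
  policy <- match.arg(policy)
  stopifnot(inherits(table, "curated_line_table"))
  if (!gene %in% table$status$gene) stop("gene not in table: ", gene)
  st <- table$status[table$status$gene == gene & table$status$field == "cn", ,
                     drop = FALSE]
  if (!nrow(st)) return(0L)
  hits <- vapply(split(st, st$line), function(e) {
    e <- resolve_entries(e, policy)
    status %in% trimws(e$value)
  }, logical(1))
  sum(hits)
}
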