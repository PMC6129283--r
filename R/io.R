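# TSV / OBO input-output helpers shared by the pipeline and the CLI.

#' Read a sample-to-ontology-term mapping TSV
#'
#' Expects a header row and at least the columns `sample_id` and `term_id`;
#' optional columns `group` (biological sample type, e.g. tissue) and `batch`
#' (technical origin, e.g. consortium or study) are carried along.
#'
#' @param path Path to a tab-separated file, UTF-8.
#' @return A data frame with columns `sample_id`, `term_id` and, when present,
#'   `group` and `batch`.
#' @export
read_mapping_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("sample_id", "term_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("mapping file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  keep <- intersect(c("sample_id", "term_id", "group", "batch"), names(df))
  df[keep]
}

#' Validate a sample mapping against an ontology
#'
#' Checks that every sample appears exactly once and that every mapped term
#' exists in the ontology and is not obsolete. Mapping a sample to an obsolete
#' term is an error rather than a silent drop, so curation mistakes surface.
#'
#' @param mapping Data frame with columns `sample_id`, `term_id`.
#' @param graph Optional `ontology`; when supplied, term membership is checked.
#' @return The validated mapping (invisibly usable), with character columns.
#' @export
validate_mapping <- function(mapping, graph = NULL) {
  if (!is.data.frame(mapping) ||
      !all(c("sample_id", "term_id") %in% names(mapping))) {
    stop("mapping must be a data frame with columns sample_id and term_id")
  }
  mapping$sample_id <- as.character(mapping$sample_id)
  mapping$term_id <- as.character(mapping$term_id)
  if (anyDuplicated(mapping$sample_id)) {
    stop("duplicated sample_id in mapping: ",
         paste(unique(mapping$sample_id[duplicated(mapping$sample_id)]),
               collapse = ", "))
  }
  if (!is.null(graph)) {
    unknown <- setdiff(mapping$term_id, graph$terms)
    if (length(unknown) > 0L) {
      stop("mapping references terms absent from the ontology: ",
           paste(unique(unknown), collapse = ", "))
    }
    obs <- intersect(unique(mapping$term_id), graph$obsolete)
    if (length(obs) > 0L) {
      stop("mapping references obsolete terms: ", paste(obs, collapse = ", "))
    }
  }
  mapping
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column holds gene ids, header row holds sample ids, body is dense
#' numeric (TPM or normalized counts).
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes in rows, samples in columns, with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                          comment.char = "#", check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  validate_expression(m)
  m
}

#' @rdname read_expression_tsv
#' @param expr Numeric matrix to write.
#' @param ... Header metadata written as `# key=value` comment lines.
#' @export
write_expression_tsv <- function(expr, path, ...) {
  .write_tsv_matrix(expr, path, first_col = "gene_id", ...)
}

#' Write a square similarity/distance matrix as TSV
#'
#' First row and first column are sample ids; full square body with
#' deterministic float formatting (10 significant digits).
#'
#' @param m Square numeric matrix with dimnames.
#' @param path Output path.
#' @param ... Header metadata written as `# key=value` comment lines.
#' @export
write_matrix_tsv <- function(m, path, ...) {
  .write_tsv_matrix(m, path, first_col = "sample_id", ...)
}

.write_tsv_matrix <- function(m, path, first_col, ...) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  .write_provenance(con, ...)
  writeLines(paste(c(first_col, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(row) paste(.fmt_num(row), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Write a data frame as TSV with a provenance header
#'
#' Numeric columns are formatted with 10 significant digits so that repeated
#' runs with identical inputs produce byte-identical files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param ... Header metadata written as `# key=value` comment lines.
#' @export
write_table_tsv <- function(df, path, ...) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  .write_provenance(con, ...)
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

.write_provenance <- function(con, ...) {
  meta <- list(...)
  writeLines(sprintf("# ontoscore_version=%s",
                     as.character(utils::packageVersion("ontoscore"))), con)
  for (k in names(meta)) {
    writeLines(sprintf("# %s=%s", k, paste(meta[[k]], collapse = ",")), con)
  }
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.10g", v)
  }, character(1))
  out
}

#' Write an ontology graph as a minimal OBO file
#'
#' Emits one `[Term]` stanza per term with `id`, `name` and `is_a` lines; the
#' output round-trips through [parse_obo()]. Used by the synthetic data
#' generator so fixtures exercise the same format path as real ontologies.
#'
#' @param graph An `ontology` object.
#' @param path Output path.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in graph$terms) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    nm <- graph$names[t]
    if (!is.na(nm)) writeLines(paste0("name: ", nm), con)
    for (p in graph$parents[[t]]) writeLines(paste0("is_a: ", p), con)
    if (t %in% graph$obsolete) writeLines("is_obsolete: true", con)
  }
  invisible(path)
}
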