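# Readers and writers for the plain-text formats the pipeline exchanges:
# TSV matrices (genes/probes as rows, first column the row id), TSV
# annotation and survival tables, and GCT-style profile matrices.

#' Read / write a gene (or probe) by sample TSV matrix
#'
#' First column holds row identifiers, remaining columns one sample each.
#'
#' @param path file path.
#' @return numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("matrix contains missing values: ", path)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate row or column identifiers: ", path)
  m
}

#' @rdname read_matrix_tsv
#' @param m matrix to write.
#' @param id_name header for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a GCT-style profile matrix
#'
#' The two header lines ("#1.2" and the row/column counts) are followed by a
#' table whose first two columns are Name and Description.
#'
#' @param path file path.
#' @return numeric matrix (rows = genes, columns = profiles).
#' @export
read_gct <- function(path) {
  lines <- readLines(path, n = 2)
  if (!startsWith(lines[1], "#1.2"))
    stop("not a GCT 1.2 file: ", path)
  dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
  df <- utils::read.delim(path, skip = 2, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (nrow(m) != dims[1] || ncol(m) != dims[2])
    stop("GCT dimension line disagrees with the table: ", path)
  m
}

#' @rdname read_gct
#' @param m matrix to write.
#' @export
write_gct <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(Name = rownames(m), Description = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table (sample_id, subtype[, barcode_prefix])
#' @param path file path.
#' @return data frame.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "subtype") %in% names(df)))
  df
}

#' Read a survival table (sample_id, OS_days, vital_status)
#'
#' \code{vital_status} may be LIVING/DECEASED strings or 0/1.
#'
#' @param path file path.
#' @return data frame with sample_id, time, event.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "OS_days", "vital_status") %in% names(df)))
  event <- if (is.character(df$vital_status)) {
    as.integer(toupper(df$vital_status) == "DECEASED")
  } else as.integer(df$vital_status)
  data.frame(sample_id = df$sample_id, time = df$OS_days, event = event,
             stringsAsFactors = FALSE)
}

#' @rdname read_survival_tsv
#' @param surv data frame with sample_id, time, event.
#' @export
write_survival_tsv <- function(surv, path) {
  utils::write.table(
    data.frame(sample_id = surv$sample_id, OS_days = surv$time,
               vital_status = ifelse(surv$event == 1, "DECEASED", "LIVING")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table (probe_id, gene_symbols)
#'
#' Multiple gene symbols per probe may be semicolon-separated; the table is
#' expanded to one row per (probe, gene) pair.
#'
#' @param path file path.
#' @return data frame with probe_id, gene.
#' @export
read_probe_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "gene_symbols") %in% names(df)))
  genes <- strsplit(df$gene_symbols, ";", fixed = TRUE)
  data.frame(probe_id = rep(df$probe_id, lengths(genes)),
             gene = unlist(genes), stringsAsFactors = FALSE)
}
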