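#' Amplicon count tables
#'
#' An `asv_table` bundles a taxa-by-samples matrix of non-negative integer
#' counts with a sample metadata tibble mapping each sample to a group label
#' (e.g. control / down / mid in a three-arm field design). It is the object
#' every downstream stage of the pipeline consumes.
#'
#' @param counts Numeric matrix, taxa as rows and samples as columns, with
#'   unique row and column names and non-negative integer entries.
#' @param metadata Data frame with columns `sample_id` and `group`, one row
#'   per sample of `counts`.
#'
#' @return An object of class `asv_table` with elements `counts` (integer
#'   matrix) and `metadata` (tibble with columns `sample_id`, `group`).
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 4L, 1L), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' asv_table(m, data.frame(sample_id = c("s1", "s2"), group = "control"))
asv_table <- function(counts, metadata) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort_invalid("`counts` must be a numeric matrix (taxa x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_invalid("`counts` must have taxon row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    abort_format(sprintf("duplicate taxon id: '%s'", dup))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    abort_format(sprintf("duplicate sample id: '%s'", dup))
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort_format("counts must be finite and non-negative")
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    abort_format(sprintf("non-integer count at taxon '%s', sample '%s'",
                         rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  metadata <- tibble::as_tibble(metadata)
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    abort_invalid("`metadata` needs columns `sample_id` and `group`")
  }
  missing <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing)) {
    abort_invalid(sprintf("samples without metadata: %s",
                          paste(missing, collapse = ", ")))
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, metadata = metadata), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  grp <- table(x$metadata$group)
  cat("groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n")
  cat(sprintf("depth: %d-%d reads per sample\n",
              min(colSums(x$counts)), max(colSums(x$counts))))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

taxa_names <- function(table) rownames(table$counts)
sample_names <- function(table) colnames(table$counts)

group_samples <- function(table, group) {
  groups <- unique(table$metadata$group)
  if (!group %in% groups) {
    abort_invalid(sprintf("unknown group '%s' (available: %s)",
                          group, paste(groups, collapse = ", ")))
  }
  table$metadata$sample_id[table$metadata$group == group]
}

subset_samples_tab <- function(table, samples) {
  asv_table(table$counts[, samples, drop = FALSE],
            table$metadata[table$metadata$sample_id %in% samples, ])
}

#' Read and write count tables
#'
#' Count tables are exchanged as TSV with taxa as rows, a header row of
#' sample ids, and the taxon id in the first column. `write_count_table()`
#' followed by `read_count_table()` reproduces the table exactly.
#'
#' @param path Path to a tab-separated count table.
#' @param metadata Optional metadata data frame (`sample_id`, `group`); when
#'   omitted, all samples are assigned group `"all"` so that purely tabular
#'   work is possible before metadata is attached.
#' @return `read_count_table()` returns an [asv_table()];
#'   `write_count_table()` invisibly returns `path`.
#' @export
read_count_table <- function(path, metadata = NULL) {
  if (!file.exists(path)) abort_invalid(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1]
    abort_format(sprintf("duplicate sample id in header: '%s'", dup))
  }
  raw <- read.delim(path, sep = "\t", row.names = NULL, check.names = FALSE,
                    colClasses = "character")
  if (anyDuplicated(raw[[1]])) {
    dup <- raw[[1]][duplicated(raw[[1]])][1]
    abort_format(sprintf("duplicate taxon id: '%s'", dup))
  }
  body <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  body <- matrix(body, nrow = nrow(raw),
                 dimnames = list(raw[[1]], sample_ids))
  if (anyNA(body)) {
    bad <- which(is.na(body), arr.ind = TRUE)[1, ]
    abort_format(sprintf("non-numeric entry at taxon '%s', sample '%s'",
                         rownames(body)[bad[1]], colnames(body)[bad[2]]))
  }
  if (is.null(metadata)) {
    metadata <- tibble::tibble(sample_id = sample_ids, group = "all")
  }
  asv_table(body, metadata)
}

#' @rdname read_count_table
#' @param table An [asv_table()].
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(taxon_id = taxa_names(table), table$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' @param path Path to a TSV with columns `sample_id` and `group`.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
read_sample_metadata <- function(path) {
  df <- tibble::as_tibble(read.delim(path, sep = "\t",
                                     colClasses = "character"))
  if (!all(c("sample_id", "group") %in% names(df))) {
    abort_format("metadata must have columns `sample_id` and `group`")
  }
  df
}

#' @rdname read_sample_metadata
#' @param metadata A data frame with `sample_id` and `group` columns.
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
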