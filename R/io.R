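#' Controlled vocabularies
#'
#' Dose levels (control plus three treated levels) and the default sampling
#' times of the two experimental systems: primary hepatocytes are profiled at
#' 2, 8 and 24 h, single-dose animal studies at 3, 6, 9 and 24 h.
#'
#' @name vocabularies
#' @export
DOSE_LEVELS <- c("control", "low", "middle", "high")

#' @rdname vocabularies
#' @export
SYSTEMS <- c("in_vitro", "in_vivo")

#' @rdname vocabularies
#' @export
default_time_vocab <- function() {
  list(in_vitro = c(2, 8, 24), in_vivo = c(3, 6, 9, 24))
}

#' Read a gene expression matrix from delimited text
#'
#' The format is TSV with genes in rows and samples in columns: the first
#' column holds gene/probe identifiers and the header row sample identifiers.
#' Values are log2-scale intensities.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cells in expression matrix")
  rownames(mat) <- genes
  validate_expression(mat)
  mat
}

#' @rdname read_expression
#' @param mat Matrix as returned by [read_expression()].
#' @export
write_expression <- function(mat, path) {
  validate_expression(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the container invariants: unique gene and sample identifiers,
#' dimnames present, all values finite.
#'
#' @param mat Numeric matrix, genes x samples.
#' @return The matrix, invisibly.
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers")
  if (!all(is.finite(mat))) stop("non-finite values in expression matrix")
  invisible(mat)
}

#' Read and validate a sample metadata table
#'
#' TSV with columns `sample_id, compound, system, dose, time_h, replicate`.
#' `system` must be `in_vitro` or `in_vivo`, `dose` one of
#' `control/low/middle/high`, `time_h` a positive number and `replicate` a
#' positive integer. `(compound, system, dose, time_h, replicate)` must be
#' unique.
#'
#' @param path File path.
#' @param expression Optional expression matrix; when given, every
#'   `sample_id` must be one of its columns.
#' @return A data.frame of sample metadata.
#' @export
read_meta <- function(path, expression = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_meta(df, expression)
}

#' @rdname read_meta
#' @param meta Metadata data.frame.
#' @export
write_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_meta
#' @export
validate_meta <- function(meta, expression = NULL) {
  need <- c("sample_id", "compound", "system", "dose", "time_h", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$compound <- as.character(meta$compound)
  meta$system <- as.character(meta$system)
  meta$dose <- as.character(meta$dose)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(meta$system %in% SYSTEMS)) stop("system must be in_vitro or in_vivo")
  if (!all(meta$dose %in% DOSE_LEVELS)) stop("dose outside vocabulary")
  if (!is.numeric(meta$time_h) || any(meta$time_h <= 0)) stop("time_h must be positive")
  if (any(meta$replicate < 1) || any(meta$replicate != round(meta$replicate)))
    stop("replicate must be a positive integer")
  key <- paste(meta$compound, meta$system, meta$dose, meta$time_h, meta$replicate)
  if (anyDuplicated(key)) stop("duplicate (compound, system, dose, time_h, replicate)")
  if (!is.null(expression)) {
    unknown <- setdiff(meta$sample_id, colnames(expression))
    if (length(unknown))
      stop("metadata references unknown samples: ", paste(unknown, collapse = ", "))
  }
  meta[need]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#' Used both for co-expression modules (named after their hub gene) and for
#' pathway gene sets.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 60))
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set in GMT: ", parts[1])
    sets[[parts[1]]] <- genes
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pathology findings table
#'
#' TSV with columns `sample_id, finding`. Samples with no pathological
#' finding may either be absent or carry an empty/`none` finding.
#'
#' @param path File path.
#' @return data.frame with `sample_id`, `finding`.
#' @export
read_pathology <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "finding") %in% names(df)))
    stop("pathology table needs columns sample_id, finding")
  df$sample_id <- as.character(df$sample_id)
  df$finding <- as.character(df$finding)
  df
}

#' @rdname read_pathology
#' @param pathology data.frame with `sample_id`, `finding`.
#' @export
write_pathology <- function(pathology, path) {
  write.table(pathology[, c("sample_id", "finding")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
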