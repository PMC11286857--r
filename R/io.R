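#' Read gene sets in GMT format
#'
#' One set per line: `name <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (recycled).
#' @export
write_gmt <- function(sets, path, descriptions = "") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression signature from a two-column TSV
#'
#' Expected columns: gene identifier and a signed value (log fold change or
#' characteristic score). A header row is detected and skipped when the value
#' column is non-numeric.
#'
#' @param path Path to the TSV.
#' @param id Entity identifier; defaults to the file name without extension.
#' @param kind `"disease"` or `"drug"`.
#' @return An `expr_signature` (see [expression_signature()]).
#' @export
read_signature <- function(path, id = NULL,
                           kind = c("disease", "drug")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("signature file needs columns gene, value", call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(df[[2L]][1L])))) df <- df[-1L, , drop = FALSE]
  vals <- as.numeric(df[[2L]])
  names(vals) <- as.character(df[[1L]])
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  expression_signature(id, vals, kind)
}

#' Read chemical fingerprints from a long-format TSV
#'
#' Columns: drug, feature, count. Fingerprints are always consumed from file,
#' never computed; any sparse count fingerprint family works.
#'
#' @param path Path to the TSV (header optional).
#' @return Named list of named non-negative numeric count vectors, one per
#'   drug.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("fingerprint file needs columns drug, feature, count",
                          call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(df[[3L]][1L])))) df <- df[-1L, , drop = FALSE]
  split_idx <- split(seq_len(nrow(df)), df[[1L]])
  lapply(split_idx, function(ix) {
    v <- as.numeric(df[[3L]][ix])
    names(v) <- as.character(df[[2L]][ix])
    v
  })
}

#' Published CML validation table
#'
#' The top 20 predicted drug combinations for chronic myeloid leukemia with
#' their published in-silico components (proximity z-scores, separation,
#' transcriptional correlations, prediction score) and in-vitro validation
#' measurements on K562 cells (percent survival, Loewe CA score, Bliss IA
#' score). Three pairs were excluded from wet-lab validation and carry `NA`
#' measurements. Ships as a plain TSV in `extdata`.
#'
#' @return A `data.frame` with one row per predicted pair.
#' @export
cml_validation_table <- function() {
  path <- system.file("extdata", "cml_predicted_pairs_validation.tsv",
                      package = "netsynergy", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
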