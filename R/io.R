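# Plain-text readers and writers for the pipeline's interchange formats:
# tidy feature TSV, metadata TSV, parcellation TSV, expression matrix TSV,
# DGE tables, and GMT gene sets.

#' Write / read a parcellation table
#' @param p parcellation.
#' @param path file path (TSV).
#' @export
write_parcellation <- function(p, path) {
  utils::write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(p) <- c("parcellation", "data.frame")
  validate_parcellation(p)
  p
}

#' Write / read cohort features as tidy TSV
#'
#' Long format: `subject_id`, `region_id`, `feature`, `value`.
#'
#' @param features named list of region x feature matrices.
#' @param path file path (TSV).
#' @export
write_features <- function(features, path) {
  rows <- lapply(names(features), function(s) {
    m <- features[[s]]
    data.frame(subject_id = s,
               region_id = rep(rownames(m), ncol(m)),
               feature = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "region_id", "feature", "value")
  if (!all(need %in% names(df))) stop("features TSV needs columns: ",
                                      paste(need, collapse = ", "))
  split_df <- split(df, df$subject_id)
  lapply(split_df, function(d) {
    regions <- unique(d$region_id)
    feats <- unique(d$feature)
    m <- matrix(NA_real_, length(regions), length(feats),
                dimnames = list(regions, feats))
    m[cbind(match(d$region_id, regions), match(d$feature, feats))] <- d$value
    if (anyNA(m)) stop("incomplete feature table for subject ", d$subject_id[1])
    m
  })
}

#' Write / read a numeric matrix with row names as first column
#' @param m matrix.
#' @param path file path (TSV).
#' @param rowname_col name of the first column.
#' @export
write_matrix_tsv <- function(m, path, rowname_col = "id") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- rowname_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}
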