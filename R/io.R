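# Delimited-text I/O for view matrices: CSV with a leading sample-ID column
# and a header row of feature names. Views are joined on identical sample-ID
# sets; a mismatch is a hard error naming the offending files.

#' Read aligned view matrices from CSV files
#'
#' Each file is a CSV whose first column holds sample IDs and whose
#' remaining columns are numeric features. All files must contain exactly
#' the same sample IDs; rows are reordered to the first file's order.
#'
#' @param paths named character vector of file paths; names become view
#'   names (defaults to file names without extension).
#' @return named list of numeric matrices with rownames = sample IDs.
#' @export
read_views <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  views <- lapply(paths, function(p) {
    df <- utils::read.csv(p, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    m
  })
  ids <- rownames(views[[1]])
  for (v in seq_along(views)[-1]) {
    if (!setequal(rownames(views[[v]]), ids)) {
      stop("sample IDs in '", paths[v], "' do not match '", paths[1], "'.")
    }
    views[[v]] <- views[[v]][ids, , drop = FALSE]
  }
  views
}

#' Write a view matrix to CSV
#'
#' @param x numeric matrix (samples x features); rownames used as sample
#'   IDs (generated as `s1, s2, ...` if absent).
#' @param path output file.
#' @param id_col name of the sample-ID column.
#' @return `path`, invisibly.
#' @export
write_view <- function(x, path, id_col = "sample_id") {
  x <- as.matrix(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(ids, x, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
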