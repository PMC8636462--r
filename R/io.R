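#' Read a numeric data matrix from CSV, TSV, or MatrixMarket
#'
#' Delimited files must carry a header row of variable names; an optional
#' first column of row identifiers is detected when its entries are
#' non-numeric.  MatrixMarket (\code{.mtx}) input is read with
#' \code{Matrix::readMM} and densified.
#'
#' @param path Path to a \code{.csv}, \code{.tsv}/\code{.txt}, or \code{.mtx}
#'   file.
#' @param format Override the format inferred from the file extension.
#' @return A numeric matrix with any row/column identifiers attached as
#'   dimnames.
#' @export
read_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension: ", ext))
  }
  if (format == "mtx") {
    return(as.matrix(Matrix::readMM(path)))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) > 1L && !is.numeric(df[[1L]])) {
    rn <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
    m <- as.matrix(df)
    rownames(m) <- rn
  } else {
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("matrix contains missing values: ", path)
  m
}
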