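# 10x-style Matrix Market triplet I/O (matrix.mtx + features.tsv +
# barcodes.tsv), gzip-transparent.

find_part <- function(dir, base) {
  for (cand in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  stop(sprintf("missing %s(.gz) in %s", base, dir), call. = FALSE)
}

read_lines_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  readLines(con)
}

#' Read a 10x-style sparse count matrix
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate format, 1-based indices),
#' `features.tsv` and `barcodes.tsv` in `dir` (optionally gzipped), with
#' features as rows and barcodes as columns.
#'
#' @param dir Directory containing the triplet.
#' @return dgCMatrix with gene ids as row names and barcodes as column
#'   names.
#' @export
read_matrix_10x <- function(dir) {
  mtx_path <- find_part(dir, "matrix.mtx")
  feats <- read_lines_maybe_gz(find_part(dir, "features.tsv"))
  feats <- vapply(strsplit(feats, "\t"), `[`, character(1), 1)
  bcs <- read_lines_maybe_gz(find_part(dir, "barcodes.tsv"))
  if (!length(bcs)) stop("empty barcode file", call. = FALSE)
  if (!length(feats)) stop("empty features file", call. = FALSE)
  lines <- read_lines_maybe_gz(mtx_path)
  if (!grepl("^%%MatrixMarket +matrix +coordinate", lines[1])) {
    stop("matrix.mtx: not a MatrixMarket coordinate file (line 1)",
         call. = FALSE)
  }
  body <- which(!startsWith(lines, "%"))
  hdr <- as.numeric(strsplit(trimws(lines[body[1]]), "[[:space:]]+")[[1]])
  if (length(hdr) != 3) {
    stop(sprintf("matrix.mtx: malformed size header at line %d", body[1]),
         call. = FALSE)
  }
  entries <- body[-1]
  if (length(entries) != hdr[3]) {
    stop(sprintf("matrix.mtx: %d entries declared but %d found (line %d)",
                 hdr[3], length(entries), body[1]), call. = FALSE)
  }
  trip <- matrix(0, length(entries), 3)
  if (length(entries)) {
    sp <- strsplit(trimws(lines[entries]), "[[:space:]]+")
    trip <- do.call(rbind, lapply(sp, as.numeric))
  }
  if (length(entries) && min(trip[, 1:2]) < 1) {
    bad <- entries[which(trip[, 1] < 1 | trip[, 2] < 1)[1]]
    stop(sprintf(
      "matrix.mtx: 0-based index at line %d; this reader requires 1-based MatrixMarket indices",
      bad), call. = FALSE)
  }
  if (hdr[1] != length(feats) || hdr[2] != length(bcs)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but features.tsv has %d rows and barcodes.tsv %d (line %d)",
      hdr[1], hdr[2], length(feats), length(bcs), body[1]), call. = FALSE)
  }
  m <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(hdr[1], hdr[2]),
                            dimnames = list(feats, bcs))
  as_dgc(m)
}

#' Write a sparse count matrix in the 10x triplet dialect
#'
#' @param counts Gene x cell matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrix_10x <- function(counts, dir) {
  x <- as_dgc(counts)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("`counts` needs gene and barcode dimnames", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "features.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
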