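# Readers and writers for the plain-text interchange formats used by the
# pipeline: counts as dense TSV or MatrixMarket (+ sidecar name files),
# metadata/traits as CSV, matrices as TSV, run metadata as JSON.

#' Read a gene x sample count matrix
#'
#' @param path A dense TSV (first column gene ids, header sample ids) or a
#'   MatrixMarket `.mtx` file with sidecar `<stem>_genes.txt` /
#'   `<stem>_samples.txt` (or `genes.txt`/`samples.txt` in the same
#'   directory) holding one identifier per line.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    gf <- if (file.exists(paste0(stem, "_genes.txt"))) paste0(stem, "_genes.txt")
          else file.path(dirname(path), "genes.txt")
    sf <- if (file.exists(paste0(stem, "_samples.txt"))) paste0(stem, "_samples.txt")
          else file.path(dirname(path), "samples.txt")
    if (!file.exists(gf) || !file.exists(sf))
      stop("MatrixMarket counts need sidecar gene/sample name files", call. = FALSE)
    dimnames(m) <- list(readLines(gf), readLines(sf))
  } else {
    dt <- data.table::fread(path, header = TRUE)
    m <- as.matrix(dt[, -1])
    rownames(m) <- as.character(dt[[1]])
  }
  storage.mode(m) <- "integer"
  check_counts(m)
  m
}

#' @rdname read_counts
#' @param counts Integer gene x sample matrix.
#' @param path Output file.
#' @export
write_counts_tsv <- function(counts, path) {
  dt <- data.table::data.table(gene_id = rownames(counts))
  dt <- cbind(dt, data.table::as.data.table(counts))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname read_counts
#' @export
write_counts_mtx <- function(counts, path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  stem <- sub("\\.mtx$", "", path)
  writeLines(rownames(counts), paste0(stem, "_genes.txt"))
  writeLines(colnames(counts), paste0(stem, "_samples.txt"))
  invisible(path)
}

#' Read sample metadata
#'
#' @param path CSV/TSV with at least `sample_id`, `population`, `treatment`;
#'   optional `read_mapping_pct`.
#' @param populations,treatments Optional declared level sets; values outside
#'   them are an error.
#' @return A data.frame with factor population/treatment columns.
#' @export
read_samples <- function(path, populations = NULL, treatments = NULL) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  check_samples(df)
  lev_p <- populations %||% unique(df$population)
  lev_t <- treatments %||% unique(df$treatment)
  if (!all(df$population %in% lev_p))
    stop("population levels outside declared set", call. = FALSE)
  if (!all(df$treatment %in% lev_t))
    stop("treatment levels outside declared set", call. = FALSE)
  df$population <- factor(df$population, levels = lev_p)
  df$treatment <- factor(df$treatment, levels = lev_t)
  df
}

#' Read a per-trial trait table
#'
#' @param path CSV/TSV with `sample_id` plus numeric trait columns named
#'   `<block>_<k>` for blocks Fbehav, Mbehav, Mmorph.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE))
}

# Generic numeric matrix round-trip (VST values, eigengenes, scores).
write_matrix_tsv <- function(m, path, id_col = "id") {
  dt <- data.table::data.table(V1 = rownames(m))
  data.table::setnames(dt, "V1", id_col)
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
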