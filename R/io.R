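#' Write a dataset to disk
#'
#' Writes one technology as a directory containing `matrix.mtx`
#' (cells x features, MatrixMarket), `features.tsv` (feature ids),
#' `cells.tsv` (cell id plus any annotation columns) and `dataset.json`
#' (technology tag).
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeDataset <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- .datasetMatrix(sce)
  Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  data.table::fwrite(data.frame(feature_id = rownames(counts)),
                     file.path(dir, "features.tsv"), sep = "\t")
  cells <- data.frame(cell_id = colnames(counts))
  if (is(sce, "SummarizedExperiment"))
    for (col in names(colData(sce)))
      cells[[col]] <- colData(sce)[[col]]
  data.table::fwrite(cells, file.path(dir, "cells.tsv"), sep = "\t")
  tech <- if (is(sce, "SummarizedExperiment"))
    metadata(sce)$technology %||% "unknown" else "unknown"
  jsonlite::write_json(list(technology = tech), file.path(dir, "dataset.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset from disk
#'
#' Reads a cells-by-features expression dataset either from a directory in
#' the layout written by [writeDataset()] (`mtx` format) or from a dense CSV
#' with a `cell_id` column and one column per feature (`csv` format, with an
#' optional `cells.tsv`-style annotation file alongside). Cell ids and any
#' `branch`, `pseudotime`, `label` annotations are preserved.
#'
#' @param path directory (mtx) or file (csv).
#' @param format `"auto"` (by path type/extension), `"mtx"` or `"csv"`.
#' @param annotations optional annotation file for csv input.
#' @return a `SingleCellExperiment` (counts stored features x cells).
#' @export
readDataset <- function(path, format = c("auto", "mtx", "csv"),
                        annotations = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "mtx"
              else if (grepl("\\.csv$", path)) "csv"
              else stop("cannot auto-detect format of ", path)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx under ", path)
    counts <- t(as.matrix(Matrix::readMM(mtx)))
    feats <- data.table::fread(file.path(path, "features.tsv"),
                               data.table = FALSE)
    cells <- data.table::fread(file.path(path, "cells.tsv"),
                               data.table = FALSE)
    if (nrow(feats) != nrow(counts))
      stop("dimension mismatch: matrix has ", nrow(counts),
           " features but features.tsv has ", nrow(feats), " rows")
    if (nrow(cells) != ncol(counts))
      stop("dimension mismatch: matrix has ", ncol(counts),
           " cells but cells.tsv has ", nrow(cells), " rows")
    rownames(counts) <- feats[[1]]
    colnames(counts) <- cells$cell_id
    tech <- "unknown"
    dj <- file.path(path, "dataset.json")
    if (file.exists(dj)) tech <- jsonlite::read_json(dj)$technology
    ann <- cells[, setdiff(names(cells), "cell_id"), drop = FALSE]
  } else {
    df <- data.table::fread(path, data.table = FALSE)
    if (!"cell_id" %in% names(df))
      stop("csv input must contain a cell_id column")
    counts <- t(as.matrix(df[, setdiff(names(df), "cell_id"),
                             drop = FALSE]))
    colnames(counts) <- df$cell_id
    tech <- "unknown"
    ann <- NULL
    if (!is.null(annotations)) {
      cells <- data.table::fread(annotations, data.table = FALSE)
      if (nrow(cells) != ncol(counts))
        stop("dimension mismatch: matrix has ", ncol(counts),
             " cells but annotations have ", nrow(cells), " rows")
      ord <- match(colnames(counts), cells$cell_id)
      if (any(is.na(ord))) stop("annotation cell ids do not match matrix")
      ann <- cells[ord, setdiff(names(cells), "cell_id"), drop = FALSE]
    }
  }
  cd <- if (is.null(ann) || ncol(ann) == 0)
    DataFrame(row.names = colnames(counts))
  else DataFrame(ann, row.names = colnames(counts))
  sce <- SingleCellExperiment(assays = list(counts = counts), colData = cd)
  metadata(sce)$technology <- tech
  sce
}

#' Write latent codes as TSV
#'
#' @param codes a [LatentCodes-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCodes <- function(codes, path) {
  M <- codeMatrix(codes)
  df <- data.frame(cell_id = rownames(M), M)
  names(df)[-1] <- sprintf("z%d", seq_len(ncol(M)))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read latent codes from TSV
#'
#' @param path TSV written by [writeCodes()].
#' @param technology tag attached to the codes.
#' @return a [LatentCodes-class].
#' @export
readCodes <- function(path, technology = "unknown") {
  df <- data.table::fread(path, data.table = FALSE)
  M <- as.matrix(df[, setdiff(names(df), "cell_id"), drop = FALSE])
  rownames(M) <- df$cell_id
  new("LatentCodes", codes = M, technology = technology)
}

#' Write a matching as TSV
#'
#' Emits one row per matched pair plus one row per null-assigned cell with
#' target `NULL`.
#'
#' @param matches a [MatchResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMatches <- function(matches, path) {
  p <- matchedPairs(matches)
  nn <- nullAssigned(matches)
  nullRows <- NULL
  if (length(nn)) {
    # null-assigned cells always come from the bigger side
    nullRows <- if (matches@nSource >= matches@nTarget)
      data.frame(source_id = nn, target_id = "NULL", cost = "")
    else data.frame(source_id = "NULL", target_id = nn, cost = "")
  }
  df <- rbind(data.frame(source_id = p$source, target_id = p$target,
                         cost = sprintf("%.6f", p$cost)),
              nullRows)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
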