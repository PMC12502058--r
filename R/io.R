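# Readers and writers for the expression-matrix formats the toolkit
# accepts: dense CSV/TSV, MatrixMarket triplets with gene/cell sidecar
# files, and a minimal AnnData-compatible HDF5 (.h5ad) layout.

#' Read an expression matrix
#'
#' @param path input file. Format is inferred from the extension
#'   (`.csv`, `.tsv`/`.txt`, `.mtx`, `.h5ad`) unless `format` is given.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`, `"h5ad"` or `"auto"`.
#' @param orientation for dense files: `"genes_by_cells"` (default) or
#'   `"cells_by_genes"`; the first column must hold the row names.
#' @param assayName `"counts"` or `"lognorm"`.
#' @param genesFile,cellsFile sidecar paths for `"mtx"`; default to
#'   `<stem>-genes.tsv` / `<stem>-cells.tsv` next to the matrix.
#' @return SingleCellExperiment (genes x cells). For `.h5ad`, obs columns
#'   become colData.
#' @export
readExpression <- function(path, format = "auto",
    orientation = c("genes_by_cells", "cells_by_genes"),
    assayName = "counts", genesFile = NULL, cellsFile = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx", h5ad = "h5ad",
      stop("cannot infer format from extension of ", path))
  mat <- switch(format,
    csv = .readDense(path, ",", orientation),
    tsv = .readDense(path, "\t", orientation),
    mtx = .readMtx(path, genesFile, cellsFile),
    h5ad = return(.readH5ad(path, assayName)),
    stop("unknown format: ", format))
  makeSCE(mat, assayName)
}

.readDense <- function(path, sep, orientation) {
  dt <- data.table::fread(path, sep = sep, header = TRUE,
    data.table = FALSE)
  rn <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- rn
  if (orientation == "cells_by_genes") m <- t(m)
  m
}

.mtxSidecars <- function(path, genesFile, cellsFile) {
  stem <- sub("\\.mtx$", "", path)
  list(genes = if (is.null(genesFile)) paste0(stem, "-genes.tsv")
      else genesFile,
    cells = if (is.null(cellsFile)) paste0(stem, "-cells.tsv")
      else cellsFile)
}

.readMtx <- function(path, genesFile, cellsFile) {
  sc <- .mtxSidecars(path, genesFile, cellsFile)
  if (!file.exists(sc$genes) || !file.exists(sc$cells))
    stop("MTX sidecar file(s) missing: expected ", sc$genes, " and ",
      sc$cells)
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(sc$genes)
  colnames(m) <- readLines(sc$cells)
  m
}

#' Write an expression matrix
#'
#' @param sce SingleCellExperiment.
#' @param path output file; format inferred from extension unless given.
#' @inheritParams readExpression
#' @export
writeExpression <- function(sce, path, format = "auto",
    orientation = c("genes_by_cells", "cells_by_genes"),
    assayName = assayNames(sce)[1L]) {
  orientation <- match.arg(orientation)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx", h5ad = "h5ad",
      stop("cannot infer format from extension of ", path))
  m <- as.matrix(assay(sce, assayName))
  switch(format,
    csv = .writeDense(m, path, ",", orientation),
    tsv = .writeDense(m, path, "\t", orientation),
    mtx = .writeMtx(m, path),
    h5ad = .writeH5ad(sce, path, assayName),
    stop("unknown format: ", format))
  invisible(path)
}

.writeDense <- function(m, path, sep, orientation) {
  if (orientation == "cells_by_genes") m <- t(m)
  df <- data.frame(name = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- if (orientation == "cells_by_genes") "cell" else "gene"
  data.table::fwrite(df, path, sep = sep)
}

.writeMtx <- function(m, path) {
  sc <- .mtxSidecars(path, NULL, NULL)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  writeLines(rownames(m), sc$genes)
  writeLines(colnames(m), sc$cells)
}

# ---- minimal AnnData-compatible HDF5 ----
# Layout written: X dense (obs x var from the HDF5/Python viewpoint),
# obs/_index, var/_index, plus any character/numeric/logical colData
# columns under obs/. Reading also handles CSR/CSC sparse X groups and
# categorical obs columns, which covers files exported by common Python
# tooling.

.writeH5ad <- function(sce, path, assayName) {
  if (file.exists(path)) unlink(path)
  m <- as.matrix(assay(sce, assayName))
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  wattr <- function(obj, name, val)
    rhdf5::h5writeAttribute(val, obj, name, variableLengthString = TRUE,
      asScalar = length(val) == 1L)
  # R matrix genes x cells -> HDF5 dims reversed -> Python sees obs x var
  rhdf5::h5write(m, fid, "X")
  oX <- rhdf5::H5Dopen(fid, "X")
  wattr(oX, "encoding-type", "array")
  wattr(oX, "encoding-version", "0.2.0")
  rhdf5::H5Dclose(oX)
  writeFrame <- function(group, index, df) {
    rhdf5::h5createGroup(fid, group)
    rhdf5::h5write(index, fid, paste0(group, "/_index"))
    cols <- character(0)
    if (!is.null(df)) for (nm in names(df)) {
      v <- df[[nm]]
      if (is.factor(v)) v <- as.character(v)
      if (is.character(v)) v[is.na(v)] <- ""
      if (!(is.character(v) || is.numeric(v) || is.logical(v))) next
      rhdf5::h5write(v, fid, paste0(group, "/", nm))
      cols <- c(cols, nm)
      od <- rhdf5::H5Dopen(fid, paste0(group, "/", nm))
      wattr(od, "encoding-type",
        if (is.character(v)) "string-array" else "array")
      wattr(od, "encoding-version", "0.2.0")
      rhdf5::H5Dclose(od)
    }
    og <- rhdf5::H5Gopen(fid, group)
    wattr(og, "encoding-type", "dataframe")
    wattr(og, "encoding-version", "0.2.0")
    wattr(og, "_index", "_index")
    if (length(cols))
      rhdf5::h5writeAttribute(cols, og, "column-order",
        variableLengthString = TRUE)
    else
      rhdf5::h5createAttribute(og, "column-order", dims = 0,
        storage.mode = "character", size = 8)
    oi <- rhdf5::H5Dopen(fid, paste0(group, "/_index"))
    wattr(oi, "encoding-type", "string-array")
    wattr(oi, "encoding-version", "0.2.0")
    rhdf5::H5Dclose(oi)
    rhdf5::H5Gclose(og)
  }
  cdFull0 <- colData(sce)
  keep <- vapply(cdFull0, function(v) is.atomic(v) && !is.matrix(v),
    logical(1))
  cd <- as.data.frame(cdFull0[, keep, drop = FALSE])
  writeFrame("obs", colnames(m), if (ncol(cd)) cd else NULL)
  writeFrame("var", rownames(m), NULL)
  # matrix colData columns (e.g. probability matrices) become obsm arrays
  cdFull <- colData(sce)
  matCols <- names(cdFull)[vapply(cdFull, is.matrix, logical(1))]
  if (length(matCols)) {
    rhdf5::h5createGroup(fid, "obsm")
    for (nm in matCols) {
      rhdf5::h5write(t(cdFull[[nm]]), fid, paste0("obsm/", nm))
      od <- rhdf5::H5Dopen(fid, paste0("obsm/", nm))
      wattr(od, "encoding-type", "array")
      wattr(od, "encoding-version", "0.2.0")
      rhdf5::H5Dclose(od)
    }
  }
}

.readH5ad <- function(path, assayName) {
  ls <- rhdf5::h5ls(path)
  readIndex <- function(group) {
    as.character(rhdf5::h5read(path, paste0(group, "/_index")))
  }
  cells <- readIndex("obs")
  genes <- readIndex("var")
  xInfo <- ls[ls$group == "/" & ls$name == "X", ]
  if (nrow(xInfo) && xInfo$otype == "H5I_GROUP") {
    g <- rhdf5::h5read(path, "X", read.attributes = TRUE)
    enc <- attr(g, "encoding-type")
    i <- as.integer(g$indices); p <- as.integer(g$indptr)
    x <- as.numeric(g$data)
    nObs <- length(cells); nVar <- length(genes)
    sm <- if (identical(enc, "csc_matrix"))
      # CSC over obs x var: columns are vars
      Matrix::sparseMatrix(i = i + 1L, p = p, x = x, dims = c(nObs, nVar))
    else
      # CSR over obs x var == CSC over var x obs
      Matrix::t(Matrix::sparseMatrix(i = i + 1L, p = p, x = x,
        dims = c(nVar, nObs)))
    m <- t(as.matrix(sm))                       # genes x cells
  } else {
    m <- rhdf5::h5read(path, "X")               # genes x cells in R
  }
  dimnames(m) <- list(genes, cells)
  sce <- makeSCE(m, assayName)
  # plain obs columns -> colData
  obsLs <- ls[ls$group == "/obs" & ls$name != "_index", ]
  for (nm in obsLs$name[obsLs$otype == "H5I_DATASET"]) {
    v <- rhdf5::h5read(path, paste0("obs/", nm))
    if (length(v) == length(cells))
      colData(sce)[[nm]] <- as.vector(v)
  }
  for (nm in obsLs$name[obsLs$otype == "H5I_GROUP"]) {
    g <- rhdf5::h5read(path, paste0("obs/", nm))
    if (all(c("categories", "codes") %in% names(g))) {
      codes <- as.integer(g$codes)
      v <- ifelse(codes < 0L, NA_character_,
        as.character(g$categories)[codes + 1L])
      colData(sce)[[nm]] <- v
    }
  }
  rhdf5::h5closeAll()
  sce
}

#' Write a gene panel / coverage report
#'
#' @param panel character vector of gene names.
#' @param path output path (one gene per line).
#' @export
writePanel <- function(panel, path) {
  writeLines(panel, path)
  invisible(path)
}

#' @rdname writePanel
#' @param sce an aligned SingleCellExperiment (from [alignToPanel()]).
#' @export
writeCoverageReport <- function(sce, path) {
  jsonlite::write_json(list(coveragePercent = metadata(sce)$coverage,
    nPanelGenes = nrow(sce), nCells = ncol(sce)), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
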