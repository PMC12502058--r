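#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<- rowData
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Build a SingleCellExperiment from an expression matrix
#'
#' Convenience constructor used by the readers and the synthetic generator.
#' Rows are genes, columns are cells (Bioconductor orientation).
#'
#' @param mat numeric matrix, genes x cells, non-negative.
#' @param assayName `"counts"` for raw counts or `"lognorm"` for
#'   log-normalized values.
#' @return a [SingleCellExperiment::SingleCellExperiment] object.
#' @export
makeSCE <- function(mat, assayName = c("counts", "lognorm")) {
  assayName <- match.arg(assayName)
  if (is.null(rownames(mat)) || (ncol(mat) > 0L && is.null(colnames(mat))))
    stop("matrix must carry gene (row) and cell (column) names")
  if (is.null(colnames(mat))) colnames(mat) <- character(0)
  if (anyDuplicated(rownames(mat)))
    stop("gene names must be unique")
  if (length(mat) && min(mat) < 0)
    stop("expression values must be non-negative")
  a <- list(mat); names(a) <- assayName
  SingleCellExperiment(assays = a)
}

#' Library-size normalization with log1p transform
#'
#' Scales every cell to `scaleTotal` total counts, then applies
#' `log1p` (natural log). Cells with zero total counts cannot be scaled and
#' must be filtered upstream; they raise an error naming the cells.
#'
#' @param sce SingleCellExperiment with a `"counts"` assay.
#' @param scaleTotal target total per cell (default 10000).
#' @return the input with a `"lognorm"` assay added.
#' @export
logNormalize <- function(sce, scaleTotal = 1e4) {
  if (!"counts" %in% assayNames(sce)) stop("no 'counts' assay")
  if (scaleTotal <= 0) stop("scaleTotal must be positive")
  x <- assay(sce, "counts")
  tot <- Matrix::colSums(x)
  if (any(tot == 0))
    stop("cell(s) with zero total counts: ",
      paste(head(colnames(sce)[tot == 0], 5L), collapse = ", "),
      "; filter them before normalizing")
  norm <- log1p(t(t(x) * (scaleTotal / tot)))
  assay(sce, "lognorm") <- norm
  sce
}

#' Select highly variable genes
#'
#' Ranks genes by a dispersion statistic (variance over mean of the
#' log-normalized values; genes with zero mean get dispersion 0) and returns
#' the top `nTop` gene names. The ranking is deterministic: ties are broken
#' by lexicographic gene name. Invariant to cell order.
#'
#' @param sce SingleCellExperiment with a `"lognorm"` assay.
#' @param nTop number of genes to keep (default 5000, capped at the panel
#'   the reference offers).
#' @return character vector of `nTop` gene names, most variable first.
#' @export
selectHVGs <- function(sce, nTop = 5000) {
  if (!"lognorm" %in% assayNames(sce)) stop("no 'lognorm' assay; ",
    "run logNormalize() first")
  if (nTop > nrow(sce))
    stop("nTop (", nTop, ") exceeds gene count (", nrow(sce), ")")
  x <- as.matrix(assay(sce, "lognorm"))
  m <- rowMeans(x)
  v <- matrixStats::rowVars(x)
  disp <- ifelse(m > 0, v / m, 0)
  ord <- order(-disp, rownames(sce), method = "radix")
  rownames(sce)[ord[seq_len(nTop)]]
}

#' Align a query matrix to a gene panel
#'
#' Reorders the query to exactly the panel's genes in panel order. Genes the
#' query lacks are filled with 0 (the log-normalized value of an unobserved
#' gene); extra query genes are dropped. The percentage of panel genes the
#' query covers is recorded in `metadata(sce)$coverage` — the robustness of
#' the classifier to the zero-filled remainder is what training-time random
#' masking targets.
#'
#' Idempotent: aligning an aligned matrix changes nothing.
#'
#' @param sce SingleCellExperiment (any assays).
#' @param panel ordered character vector of gene names.
#' @return SingleCellExperiment over exactly `panel`, with
#'   `metadata(sce)$coverage` set (percent).
#' @export
alignToPanel <- function(sce, panel) {
  shared <- intersect(panel, rownames(sce))
  coverage <- 100 * length(shared) / length(panel)
  if (length(shared) == 0L)
    stop("no genes shared between query and panel (coverage 0%); ",
      "check the gene naming scheme")
  idx <- match(panel, rownames(sce))
  alignOne <- function(a) {
    out <- a[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    out[is.na(idx), ] <- 0
    rownames(out) <- panel
    out
  }
  assays <- lapply(assayNames(sce), function(nm) alignOne(assay(sce, nm)))
  names(assays) <- assayNames(sce)
  out <- SingleCellExperiment(assays = assays, colData = colData(sce))
  metadata(out) <- metadata(sce)
  metadata(out)$coverage <- coverage
  out
}

#' Identity batch-correction hook
#'
#' Batch correction is delegated to upstream tooling: any function mapping a
#' SingleCellExperiment to a corrected SingleCellExperiment can be supplied
#' wherever a `correction` argument appears. The default hook is the
#' identity.
#'
#' @param sce SingleCellExperiment.
#' @return `sce`, unchanged.
#' @export
identityCorrection <- function(sce) sce
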