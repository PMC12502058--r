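#' Embed genes in two dimensions
#'
#' Lays out the reference panel's genes in the plane so that genes with
#' similar expression patterns across the reference cells sit close
#' together, using t-SNE (default) or UMAP on the gene x cell log-normalized
#' matrix. When a grid of candidate t-SNE perplexities is supplied, each is
#' tried and the layout that occupies the largest number of distinct
#' nearest-pixel cells on the target grid is kept (a spread/de-collision
#' proxy); ties go to the smallest perplexity. Deterministic given `seed`.
#'
#' Layouts for very small panels (< 6 genes) are computed directly from the
#' first two principal components — manifold methods need more points than
#' that to be defined.
#'
#' @param sce reference SingleCellExperiment with a `"lognorm"` assay.
#' @param method `"tsne"` or `"umap"`.
#' @param perplexityGrid candidate t-SNE perplexities (ignored for UMAP).
#'   Each must satisfy `3 * perplexity < nGenes - 1`.
#' @param seed integer seed.
#' @param gridDim integer(2) target grid (used only by the perplexity
#'   selection criterion).
#' @return list with `coords` (genes x 2 matrix, rownames = genes),
#'   `perplexity` (chosen value, `NA` for UMAP/PCA) and `method`.
#' @export
embedGenes <- function(sce, method = c("tsne", "umap"),
    perplexityGrid = c(5, 15, 30), seed = 1L, gridDim = c(224L, 224L)) {
  method <- match.arg(method)
  x <- as.matrix(assay(sce, "lognorm"))  # genes x cells
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 genes to embed")

  if (n < 6L) {
    co <- .pcaCoords(x)
    rownames(co) <- rownames(x)
    return(list(coords = co, perplexity = NA_real_, method = "pca"))
  }

  runOne <- function(perp) {
    set.seed(seed)
    if (method == "tsne") {
      fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perp,
        pca = TRUE, initial_dims = min(50L, ncol(x)),
        check_duplicates = FALSE, max_iter = 500, verbose = FALSE,
        num_threads = 1)
      fit$Y
    } else {
      uwot::umap(x, n_neighbors = min(15L, n - 2L), n_components = 2,
        n_threads = 1, n_sgd_threads = 0, seed = seed)
    }
  }

  if (method == "tsne") {
    bound <- (n - 1) / 3
    ok <- perplexityGrid < bound
    if (!any(ok))
      stop("every candidate perplexity exceeds the t-SNE bound ",
        "(must be < (nGenes - 1)/3 = ", signif(bound, 4), ")")
    grid <- sort(perplexityGrid[ok])
    if (length(grid) == 1L) {
      co <- runOne(grid)
      rownames(co) <- rownames(x)
      return(list(coords = co, perplexity = grid, method = method))
    }
    fits <- lapply(grid, runOne)
    occ <- vapply(fits, function(co)
      .nearestPixelOccupancy(co, gridDim), numeric(1))
    best <- which(occ == max(occ))[1L]   # grid sorted: tie -> smallest
    co <- fits[[best]]
    rownames(co) <- rownames(x)
    list(coords = co, perplexity = grid[best], method = method)
  } else {
    co <- runOne(NA)
    rownames(co) <- rownames(x)
    list(coords = co, perplexity = NA_real_, method = method)
  }
}

.pcaCoords <- function(x) {
  co <- tryCatch({
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    cbind(p$x[, 1], if (ncol(p$x) >= 2) p$x[, 2] else 0)
  }, error = function(e) cbind(rowMeans(x), 0))
  # enforce distinct points for downstream assignment
  dup <- duplicated(round(co, 12))
  if (any(dup))
    co[dup, ] <- co[dup, ] + 1e-6 * seq_len(sum(dup))
  co
}

# distinct nearest-pixel cells occupied by min-max-scaled coordinates
.nearestPixelOccupancy <- function(coords, gridDim) {
  sc <- .scaleToGrid(coords, gridDim)
  length(unique(paste(round(sc[, 1]), round(sc[, 2]))))
}

# min-max scale embedding coords to [0, W-1] x [0, H-1] pixel-center units;
# column 1 -> grid column (x), column 2 -> grid row (y)
.scaleToGrid <- function(coords, gridDim) {
  h <- gridDim[1L]; w <- gridDim[2L]
  scale1 <- function(v, hi) {
    r <- range(v)
    if (r[1] == r[2]) rep((hi - 1) / 2, length(v))
    else (v - r[1]) / (r[2] - r[1]) * (hi - 1)
  }
  cbind(scale1(coords[, 1], w), scale1(coords[, 2], h))
}

#' Assign genes to pixels by linear sum assignment
#'
#' Scales the embedding coordinates to the grid extent and solves the
#' rectangular assignment problem that places each gene on its own pixel:
#' the cost of pixel (r, c) for a gene is the squared Euclidean distance
#' between the gene's scaled coordinate and that pixel's center, and the
#' returned assignment minimizes the total cost over all injective
#' gene-to-pixel assignments. This removes the collisions a plain
#' nearest-pixel quantization would produce.
#'
#' @param coords genes x 2 coordinate matrix with rownames.
#' @param gridDim integer(2), grid height and width; needs
#'   `nGenes <= prod(gridDim)`.
#' @return data.frame with columns `gene`, `row`, `col` (1-based).
#' @export
assignPixels <- function(coords, gridDim) {
  h <- as.integer(gridDim[1L]); w <- as.integer(gridDim[2L])
  n <- nrow(coords)
  if (n > h * w)
    stop("more genes (", n, ") than pixels (", h * w, ")")
  sc <- .scaleToGrid(coords, c(h, w))
  centers <- cbind(col = rep(0:(w - 1), each = h), row = rep(0:(h - 1), w))
  # pixels enumerated column-major: pixel p -> row (p-1) %% h + 1, col (p-1) %/% h + 1
  cost <- outer(sc[, 1], centers[, 1], "-")^2 +
          outer(sc[, 2], centers[, 2], "-")^2
  sol <- clue::solve_LSAP(cost)
  p <- as.integer(sol)
  data.frame(gene = rownames(coords),
    row = (p - 1L) %% h + 1L, col = (p - 1L) %/% h + 1L,
    stringsAsFactors = FALSE)
}

#' Fit a gene-to-pixel map from reference data
#'
#' Composition of [embedGenes()] and [assignPixels()], plus per-gene min/max
#' normalization statistics over the reference cells. The resulting
#' [PixelMap-class] fully determines how any expression vector over the same
#' panel renders as an image.
#'
#' @inheritParams embedGenes
#' @param gridDim integer(2) image dimensions (default 224 x 224).
#' @param nChannels channels rendered images carry (identical copies of the
#'   intensity plane; default 3).
#' @return a [PixelMap-class].
#' @export
fitPixelMap <- function(sce, gridDim = c(224L, 224L),
    method = c("tsne", "umap"), perplexityGrid = c(5, 15, 30), seed = 1L,
    nChannels = 3L) {
  method <- match.arg(method)
  emb <- embedGenes(sce, method, perplexityGrid, seed, gridDim)
  assign <- assignPixels(emb$coords, gridDim)
  x <- as.matrix(assay(sce, "lognorm"))
  gmin <- matrixStats::rowMins(x); gmax <- matrixStats::rowMaxs(x)
  names(gmin) <- names(gmax) <- rownames(x)
  new("PixelMap", gridDim = as.integer(gridDim), assignment = assign,
    geneMin = gmin, geneMax = gmax, coords = emb$coords,
    method = emb$method, perplexity = as.numeric(emb$perplexity),
    seed = as.integer(seed), nChannels = as.integer(nChannels))
}

#' @rdname fitPixelMap
#' @param map a [PixelMap-class].
#' @export
panelGenes <- function(map) map@assignment$gene

# linear indices (column-major into an h x w matrix) of assigned pixels,
# in assignment order
.pixelIndex <- function(map) {
  h <- map@gridDim[1L]
  (map@assignment$col - 1L) * h + map@assignment$row
}

#' Render expression vectors as images
#'
#' Each gene's value v is normalized to (v - min_g)/(max_g - min_g) with the
#' per-gene statistics stored in the map, clipped to \[0,1\] (so query values
#' outside the training range saturate), and written at the gene's pixel;
#' genes that were constant in the reference (max = min) render as 0, and
#' pixels not assigned to any gene are exactly 0.
#'
#' `renderImages` renders a whole matrix into an image stack — a
#' `nCells x H x W` array holding the single intensity plane each image
#' consists of. `renderCell` renders one cell as an `H x W x nChannels`
#' array with the plane replicated across channels.
#'
#' @param x for `renderImages` a SingleCellExperiment with a `"lognorm"`
#'   assay, or a genes x cells matrix; for `renderCell` a named numeric
#'   vector or a single-column matrix. Gene names must cover the map's
#'   panel (align with [alignToPanel()] first if unsure).
#' @param map a [PixelMap-class].
#' @return `renderImages`: array `c(nCells, H, W)` with `dimnames[[1]]` the
#'   cell ids; `renderCell`: array `c(H, W, nChannels)`.
#' @export
renderImages <- function(x, map) {
  if (methods::is(x, "SummarizedExperiment")) x <- assay(x, "lognorm")
  x <- as.matrix(x)
  panel <- panelGenes(map)
  idx <- match(panel, rownames(x))
  if (anyNA(idx))
    stop("matrix lacks ", sum(is.na(idx)), " panel gene(s); ",
      "align to the panel first (alignToPanel)")
  v <- x[idx, , drop = FALSE]
  rng <- map@geneMax[panel] - map@geneMin[panel]
  norm <- (v - map@geneMin[panel]) / ifelse(rng > 0, rng, 1)
  norm[rng == 0, ] <- 0
  norm <- pmin(pmax(norm, 0), 1)
  h <- map@gridDim[1L]; w <- map@gridDim[2L]
  n <- ncol(v)
  planes <- matrix(0, h * w, n)
  planes[.pixelIndex(map), ] <- norm
  stack <- aperm(array(planes, c(h, w, n)), c(3, 1, 2))
  dimnames(stack) <- list(colnames(x), NULL, NULL)
  stack
}

#' @rdname renderImages
#' @export
renderCell <- function(x, map) {
  v <- if (is.matrix(x)) x else matrix(x, ncol = 1,
    dimnames = list(names(x), "cell"))
  if (is.null(rownames(v))) {
    if (nrow(v) != length(panelGenes(map)))
      stop("unnamed vector length (", nrow(v),
        ") does not match panel size (", length(panelGenes(map)), ")")
    rownames(v) <- panelGenes(map)
  }
  stack <- renderImages(v, map)
  plane <- stack[1L, , ]
  array(rep(plane, map@nChannels),
    c(map@gridDim[1L], map@gridDim[2L], map@nChannels))
}

#' Read rendered pixel values back as an expression vector
#'
#' Inverse of [renderCell()] on the assigned pixels: reads each gene's pixel
#' and undoes the min-max normalization, recovering the clipped input values.
#'
#' @param img an `H x W (x C)` array or an image stack row.
#' @param map a [PixelMap-class].
#' @return named numeric vector over the panel (values on the clipped
#'   normalized-then-denormalized scale).
#' @export
unrenderCell <- function(img, map) {
  plane <- if (length(dim(img)) == 3L) img[, , 1L] else img
  vals <- plane[cbind(map@assignment$row, map@assignment$col)]
  panel <- panelGenes(map)
  rng <- map@geneMax[panel] - map@geneMin[panel]
  setNames(vals * rng + map@geneMin[panel], panel)
}

#' Random-masking augmentation
#'
#' Zeros a uniformly random subset of the assigned gene pixels —
#' `round(maskFraction * nGenes)` of them, freshly drawn per image — leaving
#' unassigned pixels untouched. Used at training time only, to make the
#' classifier robust to the zero-filled genes that query data with partial
#' panel coverage produce.
#'
#' @param stack image stack (`n x H x W` array) from [renderImages()].
#' @param map the [PixelMap-class] the stack was rendered with.
#' @param maskFraction fraction of genes to zero, in \[0, 1).
#' @param seed integer seed; the same seed reproduces the same masks.
#' @return the masked stack.
#' @export
randomMask <- function(stack, map, maskFraction = 0.3, seed = 1L) {
  if (maskFraction < 0 || maskFraction >= 1)
    stop("maskFraction must be in [0, 1)")
  if (maskFraction == 0) return(stack)
  idx <- .pixelIndex(map)
  k <- round(maskFraction * length(idx))
  if (k == 0L) return(stack)
  set.seed(seed)
  n <- dim(stack)[1L]
  hw <- dim(stack)[2L] * dim(stack)[3L]
  flat <- matrix(aperm(stack, c(2, 3, 1)), hw, n)
  for (i in seq_len(n))
    flat[sample(idx, k), i] <- 0
  out <- aperm(array(flat, c(dim(stack)[2L], dim(stack)[3L], n)), c(3, 1, 2))
  dimnames(out) <- dimnames(stack)
  out
}

#' Persist / load a pixel map
#'
#' A map is stored as a plain-text directory: `assignment.tsv` (gene, row,
#' col; 1-based, row-major grid), `normstats.tsv` (gene, min, max),
#' `coords.tsv`, and `metadata.json` (grid, method, perplexity, seed,
#' channels). Deterministic: refitting with the same seed and saving yields
#' byte-identical files.
#'
#' @param map a [PixelMap-class].
#' @param dir directory to create/read.
#' @return `savePixelMap`: the directory, invisibly; `readPixelMap`: a
#'   [PixelMap-class].
#' @export
savePixelMap <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.table(df, file.path(dir, f),
    sep = "\t", quote = FALSE, row.names = FALSE)
  wr(map@assignment, "assignment.tsv")
  wr(data.frame(gene = names(map@geneMin),
    min = sprintf("%.17g", map@geneMin),
    max = sprintf("%.17g", map@geneMax)), "normstats.tsv")
  wr(data.frame(gene = rownames(map@coords),
    x = sprintf("%.17g", map@coords[, 1]),
    y = sprintf("%.17g", map@coords[, 2])), "coords.tsv")
  jsonlite::write_json(list(grid = map@gridDim, method = map@method,
    perplexity = map@perplexity, seed = map@seed,
    nChannels = map@nChannels, coordinateConvention =
      "pixel (row, col), 1-based, row-major"),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname savePixelMap
#' @export
readPixelMap <- function(dir) {
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
    header = TRUE, stringsAsFactors = FALSE)
  a <- rd("assignment.tsv")
  ns <- rd("normstats.tsv")
  co <- rd("coords.tsv")
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  coords <- as.matrix(co[, c("x", "y")])
  rownames(coords) <- co$gene
  new("PixelMap", gridDim = as.integer(meta$grid), assignment = a,
    geneMin = setNames(as.numeric(ns$min), ns$gene),
    geneMax = setNames(as.numeric(ns$max), ns$gene),
    coords = coords, method = meta$method,
    perplexity = as.numeric(meta$perplexity), seed = as.integer(meta$seed),
    nChannels = as.integer(meta$nChannels))
}

#' @rdname savePixelMap
#' @export
mapFingerprint <- function(map) {
  digest::digest(list(map@gridDim, map@assignment,
    round(unname(map@geneMin), 10), round(unname(map@geneMax), 10)))
}

setMethod("show", "PixelMap", function(object) {
  cat(sprintf("PixelMap: %d genes on a %dx%d grid (%s%s, seed %d)\n",
    nrow(object@assignment), object@gridDim[1L], object@gridDim[2L],
    object@method,
    if (!is.na(object@perplexity))
      sprintf(", perplexity %g", object@perplexity) else "",
    object@seed))
})
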