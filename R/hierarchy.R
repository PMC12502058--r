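#' Construct a cell-type hierarchy
#'
#' @param children named list mapping each base-type name to a character
#'   vector of its subtypes (possibly empty, `character(0)`). Order defines
#'   the index order at both levels.
#' @return a validated [CellTypeHierarchy-class].
#' @examples
#' h <- CellTypeHierarchy(list(T = c("CD4 T", "CD8 T"), NK = character(0)))
#' nBaseTypes(h)  # 2
#' @export
CellTypeHierarchy <- function(children) {
  if (is.null(names(children)) || any(!nzchar(names(children))))
    stop("children must be a fully named list (base type -> subtypes)")
  children <- lapply(children, function(x) {
    if (is.list(x) && length(x) == 0L) x <- character(0)   # JSON []
    if (is.list(x))
      stop("each subtype list must be a character vector; ",
        "deeper trees are not supported")
    if (is.null(x) || (length(x) == 1L && is.na(x))) character(0)
    else as.character(x)
  })
  new("CellTypeHierarchy", baseNames = names(children), children = children)
}

#' Read a hierarchy from a JSON file
#'
#' The file holds a single JSON object `{base: [subtypes...], ...}`; key
#' order in the file defines index order, so re-reading the same file always
#' yields identical label encodings.
#'
#' @param path path to the JSON file.
#' @return a [CellTypeHierarchy-class].
#' @export
readHierarchy <- function(path) {
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(obj)) stop("hierarchy file must contain a JSON object ",
    "mapping base types to subtype arrays")
  CellTypeHierarchy(obj)
}

#' Write a hierarchy to JSON
#' @param hier a [CellTypeHierarchy-class].
#' @param path output path.
#' @export
writeHierarchy <- function(hier, path) {
  jsonlite::write_json(hier@children, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname CellTypeHierarchy
#' @param hier a [CellTypeHierarchy-class].
#' @export
baseTypes <- function(hier) hier@baseNames

#' @rdname CellTypeHierarchy
#' @export
subTypes <- function(hier) unlist(hier@children, use.names = FALSE)

#' @rdname CellTypeHierarchy
#' @export
nBaseTypes <- function(hier) length(hier@baseNames)

#' @rdname CellTypeHierarchy
#' @export
nSubTypes <- function(hier) length(subTypes(hier))

#' @rdname CellTypeHierarchy
#' @param base a base-type name.
#' @export
childrenOf <- function(hier, base) {
  if (!base %in% hier@baseNames) stop("unknown base type: ", base)
  hier@children[[base]]
}

#' @rdname CellTypeHierarchy
#' @param subtype a subtype name.
#' @export
parentOf <- function(hier, subtype) {
  map <- subtypeParents(hier)
  if (!subtype %in% names(map)) stop("unknown subtype: ", subtype)
  unname(map[subtype])
}

#' @rdname CellTypeHierarchy
#' @export
subtypeParents <- function(hier) {
  n <- lengths(hier@children)
  setNames(rep(hier@baseNames, n), unlist(hier@children, use.names = FALSE))
}

#' @rdname CellTypeHierarchy
#' @export
isTerminal <- function(hier, base) {
  if (!all(base %in% hier@baseNames)) stop("unknown base type: ",
    paste(setdiff(base, hier@baseNames), collapse = ", "))
  unname(lengths(hier@children)[match(base, hier@baseNames)] == 0L)
}

#' Subtype indices belonging to one base type
#'
#' Subtype indices are global (1..nSubTypes, in base order then child order),
#' so the index sets of different base types partition the subtype index
#' range; this is what inference-time probability masking relies on.
#'
#' @param hier a [CellTypeHierarchy-class].
#' @param base base-type name or index.
#' @return integer vector of global subtype indices (possibly empty).
#' @export
subtypeIndicesOf <- function(hier, base) {
  if (is.character(base)) base <- match(base, hier@baseNames)
  if (is.na(base) || base < 1L || base > nBaseTypes(hier))
    stop("unknown base type")
  n <- lengths(hier@children)
  offset <- if (base == 1L) 0L else sum(n[seq_len(base - 1L)])
  if (n[base] == 0L) integer(0) else offset + seq_len(n[base])
}

#' Encode labels as class indices
#'
#' Maps base-type and subtype label vectors to 1-based class indices. Cells
#' whose base type is a terminal leaf, or whose subtype label is missing,
#' get `NA` as subtype index; such cells are excluded from the subtype loss
#' and subtype metrics.
#'
#' @param hier a [CellTypeHierarchy-class].
#' @param baseLabels character vector of base-type names.
#' @param subLabels optional character vector of subtype names; `NA` marks a
#'   missing subtype. Defaults to all-missing.
#' @return list with integer vectors `base` (in 1..nBaseTypes) and `sub`
#'   (in 1..nSubTypes or `NA`).
#' @export
encodeLabels <- function(hier, baseLabels, subLabels = NULL) {
  baseLabels <- as.character(baseLabels)
  if (is.null(subLabels)) subLabels <- rep(NA_character_, length(baseLabels))
  subLabels <- as.character(subLabels)
  if (length(subLabels) != length(baseLabels))
    stop("baseLabels and subLabels must have equal length")
  bi <- match(baseLabels, hier@baseNames)
  if (anyNA(bi))
    stop("unknown base label(s): ",
      paste(unique(baseLabels[is.na(bi)]), collapse = ", "))
  allSubs <- subTypes(hier)
  si <- match(subLabels, allSubs)
  bad <- which(!is.na(subLabels) & is.na(si))
  if (length(bad))
    stop("unknown subtype label(s) at row(s) ",
      paste(head(bad, 5L), collapse = ", "), ": ",
      paste(unique(subLabels[bad]), collapse = ", "))
  # a present subtype must belong to its paired base
  parents <- subtypeParents(hier)
  chk <- which(!is.na(si))
  wrong <- chk[parents[allSubs[si[chk]]] != baseLabels[chk]]
  if (length(wrong))
    stop("subtype not a child of its base label at row(s) ",
      paste(head(wrong, 5L), collapse = ", "), " (e.g. '",
      subLabels[wrong[1L]], "' under '", baseLabels[wrong[1L]], "')")
  list(base = bi, sub = si)
}

#' Decode class indices back to labels
#'
#' Inverse of [encodeLabels()]: `decodeLabels(hier, encodeLabels(hier, b, s))`
#' recovers `b` and `s` for every valid label pair.
#'
#' @param hier a [CellTypeHierarchy-class].
#' @param enc list with components `base` and `sub` as from [encodeLabels()].
#' @return list of character vectors `base`, `sub` (`NA` where no subtype).
#' @export
decodeLabels <- function(hier, enc) {
  subs <- subTypes(hier)
  list(base = hier@baseNames[enc$base],
       sub = ifelse(is.na(enc$sub), NA_character_, subs[enc$sub]))
}

#' Remove a subtype from the taxonomy
#'
#' Returns the hierarchy with one subtype deleted from its parent's child
#' list (the parent may become terminal). Used in novel-population
#' experiments: a population is "novel" to a model exactly when it is
#' absent from the taxonomy the model was trained against.
#'
#' @param hier a [CellTypeHierarchy-class].
#' @param subtype subtype name to remove.
#' @return a [CellTypeHierarchy-class] without that subtype.
#' @export
dropSubtype <- function(hier, subtype) {
  parent <- parentOf(hier, subtype)
  ch <- hier@children
  ch[[parent]] <- setdiff(ch[[parent]], subtype)
  CellTypeHierarchy(ch)
}

#' Export the label map
#'
#' Writes a provenance TSV with one row per class: name, level
#' (base/subtype) and 1-based index at its level.
#'
#' @param hier a [CellTypeHierarchy-class].
#' @param path output TSV path.
#' @export
writeLabelMap <- function(hier, path) {
  df <- rbind(
    data.frame(name = baseTypes(hier), level = "base",
      index = seq_len(nBaseTypes(hier))),
    if (nSubTypes(hier) > 0)
      data.frame(name = subTypes(hier), level = "subtype",
        index = seq_len(nSubTypes(hier))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "CellTypeHierarchy", function(object) {
  cat("CellTypeHierarchy with", nBaseTypes(object), "base types and",
    nSubTypes(object), "subtypes\n")
  for (b in object@baseNames) {
    ch <- object@children[[b]]
    if (length(ch)) cat("  ", b, ": ", paste(ch, collapse = ", "), "\n",
      sep = "")
    else cat("  ", b, " (terminal)\n", sep = "")
  }
})
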