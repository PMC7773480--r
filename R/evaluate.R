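.namedLookup <- function(values, ids, what) {
  if (is.null(names(values)))
    stop(what, " must be a named vector (names = cell ids)")
  miss <- setdiff(ids, names(values))
  if (length(miss))
    stop(what, " missing entries for ", length(miss), " matched cells, e.g. ",
         miss[1])
  values[ids]
}

#' Label accuracy of a matching
#'
#' Fraction of non-null matched pairs whose source and target labels agree.
#' Null-assigned cells are excluded from both numerator and denominator;
#' their share is reported separately by [matchedFractions()].
#'
#' @param matches a [MatchResult-class].
#' @param labelsS,labelsT named character vectors (names = cell ids) with
#'   labels mapped to a shared vocabulary.
#' @return scalar fraction in \[0, 1\].
#' @export
labelAccuracy <- function(matches, labelsS, labelsT) {
  p <- matchedPairs(matches)
  if (nrow(p) == 0) return(NA_real_)
  ls <- as.character(.namedLookup(labelsS, p$source, "labelsS"))
  lt <- as.character(.namedLookup(labelsT, p$target, "labelsT"))
  mean(ls == lt)
}

#' Pseudotime correlation across matched pairs
#'
#' Pearson and Spearman correlation of per-cell pseudotime between matched
#' source and target cells (non-null pairs only).
#'
#' @param matches a [MatchResult-class] with at least 3 non-null pairs.
#' @param ptS,ptT named numeric vectors of pseudotime per cell.
#' @return list with elements `pearson` and `spearman`; `NA` (with a
#'   warning) when either side is constant, where correlation is undefined.
#' @export
pseudotimeCorrelation <- function(matches, ptS, ptT) {
  p <- matchedPairs(matches)
  if (nrow(p) < 3) stop("need at least 3 non-null pairs")
  x <- as.numeric(.namedLookup(ptS, p$source, "ptS"))
  y <- as.numeric(.namedLookup(ptT, p$target, "ptT"))
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant pseudotime vector: correlation undefined")
    return(list(pearson = NA_real_, spearman = NA_real_))
  }
  list(pearson = cor(x, y, method = "pearson"),
       spearman = cor(x, y, method = "spearman"))
}

#' Matched cell fractions per side
#'
#' Fraction of cells on each side that participate in at least one non-null
#' match.
#'
#' @param matches a [MatchResult-class].
#' @return list with `source` and `target` fractions.
#' @export
matchedFractions <- function(matches) {
  p <- matchedPairs(matches)
  list(source = length(unique(p$source)) / matches@nSource,
       target = length(unique(p$target)) / matches@nTarget)
}

#' Cross-technology marker correlation across matches
#'
#' For markers measured (in technology-specific units) on both sides,
#' computes Pearson and Spearman correlations of the raw expression values
#' across matched pairs, e.g. a gene's transcript counts against its
#' protein channel.
#'
#' @param matches a [MatchResult-class].
#' @param exprS,exprT numeric matrices with cells in rows (rownames = cell
#'   ids) and marker columns.
#' @param markerMap data.frame with columns `marker`, `source`, `target`
#'   naming each shared marker's column in `exprS` and `exprT`; by default
#'   the common column names are used.
#' @return data.frame with columns `marker`, `pearson`, `spearman`.
#' @export
markerCorrelation <- function(matches, exprS, exprT, markerMap = NULL) {
  p <- matchedPairs(matches)
  if (is.null(markerMap)) {
    shared <- intersect(colnames(exprS), colnames(exprT))
    if (!length(shared)) stop("no shared marker columns and no markerMap")
    markerMap <- data.frame(marker = shared, source = shared,
                            target = shared, stringsAsFactors = FALSE)
  }
  miss <- setdiff(markerMap$source, colnames(exprS))
  if (length(miss)) stop("markers absent from exprS: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(markerMap$target, colnames(exprT))
  if (length(miss)) stop("markers absent from exprT: ",
                         paste(miss, collapse = ", "))
  is <- match(p$source, rownames(exprS))
  it <- match(p$target, rownames(exprT))
  if (any(is.na(is)) || any(is.na(it)))
    stop("matched cell ids missing from expression matrices")
  out <- lapply(seq_len(nrow(markerMap)), function(i) {
    x <- exprS[is, markerMap$source[i]]
    y <- exprT[it, markerMap$target[i]]
    data.frame(marker = markerMap$marker[i],
               pearson = if (sd(x) == 0 || sd(y) == 0) NA_real_
                         else cor(x, y),
               spearman = if (sd(x) == 0 || sd(y) == 0) NA_real_
                          else cor(x, y, method = "spearman"))
  })
  do.call(rbind, out)
}

#' Full evaluation report for a matching
#'
#' Convenience wrapper computing label accuracy, pseudotime correlations and
#' matched fractions against ground truth annotations.
#'
#' @param matches a [MatchResult-class].
#' @param truthS,truthT data.frames with rownames (or a `cell_id` column)
#'   and columns among `label`/`branch` and `pseudotime`.
#' @return list suitable for JSON serialization.
#' @export
evaluateMatches <- function(matches, truthS, truthT) {
  fix <- function(tr) {
    tr <- as.data.frame(tr)
    if ("cell_id" %in% names(tr)) rownames(tr) <- tr$cell_id
    if (!"label" %in% names(tr) && "branch" %in% names(tr))
      tr$label <- tr$branch
    tr
  }
  truthS <- fix(truthS)
  truthT <- fix(truthT)
  out <- list(
    n_pairs = nrow(matchedPairs(matches)),
    n_null = length(nullAssigned(matches)),
    matched_fraction = matchedFractions(matches))
  if ("label" %in% names(truthS) && "label" %in% names(truthT))
    out$label_accuracy <- labelAccuracy(
      matches, setNames(truthS$label, rownames(truthS)),
      setNames(truthT$label, rownames(truthT)))
  if ("pseudotime" %in% names(truthS) && "pseudotime" %in% names(truthT)) {
    pc <- pseudotimeCorrelation(
      matches, setNames(truthS$pseudotime, rownames(truthS)),
      setNames(truthT$pseudotime, rownames(truthT)))
    out$pseudotime_pearson <- pc$pearson
    out$pseudotime_spearman <- pc$spearman
  }
  out
}
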