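## TSV/JSON dialect: tab-separated, UTF-8, header required, '#' lines ignored.
## labels TSV: obs_id<TAB>label; coords TSV: obs_id<TAB>x<TAB>y;
## metadata JSON: {"method": str, "config": str, "sample": str,
##                 "n_clusters": int (optional)}.

readDialectTsv <- function(path, what) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L)
    stop(sprintf("%s file '%s' has no data rows", what, path))
  df
}

#' Read one labeling from the standardized TSV/JSON files
#'
#' Labels are joined to coordinates by observation id. Observation ids
#' present in the coordinate file but absent from the label file are
#' ignored with a warning; label ids missing from the coordinate file
#' are an error. Label values are recoded to dense integer codes.
#'
#' @param labelsPath TSV with columns \code{obs_id}, \code{label}.
#' @param coordsPath TSV with columns \code{obs_id}, \code{x}, \code{y}.
#' @param metaPath optional JSON with keys \code{method}, \code{config},
#'   \code{sample}.
#'
#' @return A \linkS4class{SpatialLabeling}.
#' @export
readLabeling <- function(labelsPath, coordsPath, metaPath = NULL) {
  lab <- readDialectTsv(labelsPath, "labels")
  if (!all(c("obs_id", "label") %in% colnames(lab)))
    stop("labels TSV must have columns 'obs_id' and 'label'")
  if (anyDuplicated(lab$obs_id))
    stop(sprintf("duplicated observation id in labels: '%s'",
                 lab$obs_id[duplicated(lab$obs_id)][1L]))

  crd <- readDialectTsv(coordsPath, "coords")
  if (!all(c("obs_id", "x", "y") %in% colnames(crd)))
    stop("coords TSV must have columns 'obs_id', 'x' and 'y'")
  if (anyDuplicated(crd$obs_id))
    stop(sprintf("duplicated observation id in coords: '%s'",
                 crd$obs_id[duplicated(crd$obs_id)][1L]))
  xy <- suppressWarnings(cbind(as.numeric(crd$x), as.numeric(crd$y)))
  bad <- which(!is.finite(xy[, 1L]) | !is.finite(xy[, 2L]))
  if (length(bad))
    stop(sprintf("non-numeric or non-finite coordinate at row %d of '%s'",
                 bad[1L], coordsPath))

  missing <- setdiff(lab$obs_id, crd$obs_id)
  if (length(missing))
    stop(sprintf("%d labeled observation(s) absent from coordinates (e.g. '%s')",
                 length(missing), missing[1L]))
  extra <- setdiff(crd$obs_id, lab$obs_id)
  if (length(extra))
    warning(sprintf("%d coordinate row(s) without labels ignored", length(extra)))

  idx <- match(lab$obs_id, crd$obs_id)
  meta <- list(method = "unknown", config = "default", sample = NA_character_)
  if (!is.null(metaPath)) {
    got <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    for (k in intersect(names(got), names(meta)))
      if (!is.null(got[[k]]) && length(got[[k]]) == 1L && !is.na(got[[k]]))
        meta[[k]] <- got[[k]]
  }
  SpatialLabeling(lab$obs_id, xy[idx, , drop = FALSE], lab$label,
                  methodId = meta$method, configId = meta$config,
                  sampleId = meta$sample)
}

#' Write a labeling back to the TSV/JSON dialect
#'
#' Round-trips with [readLabeling()]: labels are written as their
#' original strings, coordinates with full precision.
#'
#' @param x a \linkS4class{SpatialLabeling}.
#' @inheritParams readLabeling
#' @return Invisibly, \code{x}.
#' @export
writeLabeling <- function(x, labelsPath, coordsPath, metaPath = NULL) {
  stopifnot(is(x, "SpatialLabeling"))
  lab <- data.frame(obs_id = x@obsIds,
                    label = x@labelLevels[x@labels],
                    stringsAsFactors = FALSE)
  writeDialectTsv(lab, labelsPath)
  crd <- data.frame(obs_id = x@obsIds,
                    x = formatC(x@coords[, 1L], format = "g", digits = 17),
                    y = formatC(x@coords[, 2L], format = "g", digits = 17),
                    stringsAsFactors = FALSE)
  writeDialectTsv(crd, coordsPath)
  if (!is.null(metaPath))
    jsonlite::write_json(list(method = x@methodId, config = x@configId,
                              sample = x@sampleId),
                         metaPath, auto_unbox = TRUE, null = "null")
  invisible(x)
}

writeDialectTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
}

#' Assemble base clusterings into a LabelingCollection
#'
#' The shared observation index is the intersection of all input id
#' sets, in deterministic lexicographic order (C collation); ids lost to
#' the intersection are recorded in the collection's metadata.
#' Coordinates are taken from the first labeling and must agree with
#' every other labeling within \code{coordTol} per axis.
#'
#' @param labelings list of \linkS4class{SpatialLabeling} objects over
#'   the same sample.
#' @param coordTol absolute per-axis tolerance for coordinate agreement.
#'
#' @return A \linkS4class{LabelingCollection}.
#' @examples
#' a <- SpatialLabeling(c("a", "b", "c"), cbind(0:2, 0), c(1, 1, 2))
#' b <- SpatialLabeling(c("b", "c", "d"), cbind(1:3, 0), c(2, 2, 1))
#' cl <- buildCollection(list(a, b))
#' droppedObservations(cl)
#' @export
buildCollection <- function(labelings, coordTol = 1e-6) {
  stopifnot(length(labelings) >= 1L)
  for (l in labelings) stopifnot(is(l, "SpatialLabeling"))

  sids <- unique(stats::na.omit(vapply(labelings, function(l) l@sampleId,
                                       character(1))))
  if (length(sids) > 1L)
    stop(sprintf("labelings come from different samples: %s",
                 paste(sids, collapse = ", ")))

  idSets <- lapply(labelings, function(l) l@obsIds)
  shared <- Reduce(intersect, idSets)
  if (length(shared) == 0L)
    stop("empty intersection of observation ids across labelings")
  shared <- stringSort(shared)
  dropped <- stringSort(setdiff(unique(unlist(idSets)), shared))

  ref <- labelings[[1L]]
  coords <- ref@coords[match(shared, ref@obsIds), , drop = FALSE]
  rownames(coords) <- shared
  for (m in seq_along(labelings)[-1L]) {
    l <- labelings[[m]]
    cm <- l@coords[match(shared, l@obsIds), , drop = FALSE]
    dev <- abs(cm - coords)
    if (any(dev > coordTol)) {
      i <- which(apply(dev > coordTol, 1L, any))[1L]
      stop(sprintf("coordinate disagreement at observation '%s' (labeling %d)",
                   shared[i], m))
    }
  }

  cols <- lapply(labelings, function(l) {
    codes <- l@labels[match(shared, l@obsIds)]
    f <- factor(l@labelLevels[codes])  # re-densify after subsetting
    list(codes = as.integer(f), levels = levels(f))
  })
  L <- vapply(cols, `[[`, integer(length(shared)), "codes")
  L <- matrix(L, nrow = length(shared))
  rownames(L) <- shared

  prov <- data.frame(
    methodId = vapply(labelings, methodId, character(1)),
    configId = vapply(labelings, configId, character(1)),
    stringsAsFactors = FALSE)
  cn <- make.unique(paste(prov$methodId, prov$configId, sep = "."))
  colnames(L) <- cn
  rownames(prov) <- cn

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(labels = L),
    rowData = S4Vectors::DataFrame(x = coords[, 1L], y = coords[, 2L],
                                   row.names = shared),
    colData = S4Vectors::DataFrame(prov))
  S4Vectors::metadata(se) <- list(
    droppedObservations = dropped,
    labelLevels = lapply(cols, `[[`, "levels"),
    sampleId = if (length(sids)) sids else NA_character_)
  new("LabelingCollection", se)
}

## locale-independent lexicographic sort (C collation), deterministic
stringSort <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x)
}

#' Subset a collection to a set of columns
#'
#' Keeps metadata (per-column label levels) in step with the subset,
#' which plain \code{[} on the underlying SummarizedExperiment would not.
#'
#' @param collection a \linkS4class{LabelingCollection}.
#' @param columns integer or character column selector.
#' @return A \linkS4class{LabelingCollection}.
#' @export
subsetColumns <- function(collection, columns) {
  if (is.character(columns)) columns <- match(columns, colnames(collection))
  if (is.logical(columns)) columns <- which(columns)
  out <- collection[, columns]
  md <- S4Vectors::metadata(collection)
  md$labelLevels <- md$labelLevels[columns]
  S4Vectors::metadata(out) <- md
  new("LabelingCollection", out)
}
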