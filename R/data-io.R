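#' Construct a ParcelTimeseries
#'
#' @param values numeric matrix, rows = time points, columns = parcels.
#' @param parcelLabels optional character vector of column names; defaults to
#'   "R1".."Rp" when the matrix has no column names.
#' @param subjectId subject identifier string.
#' @return a [ParcelTimeseries-class].
#' @examples
#' ts <- parcelTimeseries(matrix(rnorm(20), 10, 2), subjectId = "s1")
#' nTimepoints(ts)
#' @export
parcelTimeseries <- function(values, parcelLabels = NULL, subjectId = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(parcelLabels)) {
    parcelLabels <- colnames(values) %||% defaultParcelLabels(ncol(values))
  }
  dimnames(values) <- NULL
  new("ParcelTimeseries", values = values,
      parcelLabels = as.character(parcelLabels),
      subjectId = as.character(subjectId))
}

#' @rdname accessors
setMethod("tsValues", "ParcelTimeseries", function(object) object@values)

#' @rdname accessors
setMethod("parcelLabels", "ParcelTimeseries", function(object) object@parcelLabels)

#' @rdname accessors
setMethod("subjectId", "ParcelTimeseries", function(object) object@subjectId)

#' @rdname accessors
setMethod("nTimepoints", "ParcelTimeseries", function(object) nrow(object@values))

#' @rdname accessors
setMethod("nParcels", "ParcelTimeseries", function(object) ncol(object@values))

setMethod("show", "ParcelTimeseries", function(object) {
  cat(sprintf("ParcelTimeseries '%s': %d time points x %d parcels\n",
              object@subjectId, nrow(object@values), ncol(object@values)))
  cat("parcels:", paste(utils::head(object@parcelLabels, 8L), collapse = ", "),
      if (length(object@parcelLabels) > 8L) "..." else "", "\n")
})

#' Read a delimited timeseries file
#'
#' Reads a rectangular numeric table (comma by default, tab accepted), one
#' row per time point, one column per parcel, with an optional single header
#' row of parcel labels.  Ragged rows, non-numeric cells and empty files are
#' rejected with distinct errors.
#'
#' @param path file to read.
#' @param delimiter field separator, "," (default) or "\t".
#' @param subjectId subject identifier to attach; defaults to the file name
#'   without extension.
#' @return a [ParcelTimeseries-class].
#' @seealso [writeTimeseries()]
#' @export
readTimeseries <- function(path, delimiter = ",", subjectId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty timeseries file: ", path, call. = FALSE)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in timeseries file: ", path, call. = FALSE)
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  hasHeader <- anyNA(first)
  labels <- NULL
  if (hasHeader) {
    labels <- trimws(fields[[1L]])
    fields <- fields[-1L]
    if (length(fields) == 0L)
      stop("timeseries file contains only a header: ", path, call. = FALSE)
  }
  values <- suppressWarnings(
    matrix(as.numeric(unlist(fields, use.names = FALSE)),
           nrow = length(fields), byrow = TRUE)
  )
  if (anyNA(values))
    stop("non-numeric cell in timeseries file: ", path, call. = FALSE)
  if (nrow(values) < 2L)
    stop("timeseries must have at least 2 time points: ", path, call. = FALSE)
  parcelTimeseries(values, parcelLabels = labels,
                   subjectId = subjectId %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a timeseries to a delimited file
#'
#' Writes the parcel labels as a single header row followed by one row per
#' time point.  Full double precision is kept so read/write round trips are
#' lossless well below 1e-12.
#'
#' @param ts a [ParcelTimeseries-class].
#' @param path output file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
writeTimeseries <- function(ts, path, delimiter = ",") {
  stopifnot(is(ts, "ParcelTimeseries"))
  header <- paste(parcelLabels(ts), collapse = delimiter)
  body <- apply(tsValues(ts), 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = delimiter))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a subjects table
#'
#' CSV with columns `subject_id`, `group`, `path`; subject ids must be
#' unique and every group must be non-empty.
#'
#' @param path CSV file.
#' @return data.frame with character columns subject_id, group, path.
#' @export
readSubjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateSubjects(df)
}

validateSubjects <- function(df) {
  need <- c("subject_id", "group")
  if (!all(need %in% names(df)))
    stop("subjects table needs columns 'subject_id' and 'group'", call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in subjects table", call. = FALSE)
  if (any(!nzchar(df$group)))
    stop("empty group label in subjects table", call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  df
}

#' @rdname centerColumns
setMethod("centerColumns", "ParcelTimeseries", function(object) {
  v <- object@values
  v <- sweep(v, 2L, colMeans(v), "-")
  initialize(object, values = v)
})

#' @rdname centerColumns
setMethod("centerColumns", "matrix", function(object) {
  sweep(object, 2L, colMeans(object), "-")
})

#' @rdname scatterMatrix
#' @param scale divide by N to obtain the sample covariance (default FALSE:
#'   the raw cross-product is what the Wishart likelihood expects).
setMethod("scatterMatrix", "ParcelTimeseries", function(object, scale = FALSE) {
  y <- tsValues(centerColumns(object))
  s <- crossprod(y)
  if (scale) s <- s / nrow(y)
  new("ScatterMatrix", values = symmetrize(s),
      nTimepoints = nrow(y), subjectId = subjectId(object))
})

#' @rdname scatterMatrix
#' @param subjectId identifier recorded on the result.
setMethod("scatterMatrix", "matrix", function(object, scale = FALSE, subjectId = "") {
  scatterMatrix(parcelTimeseries(object, subjectId = subjectId), scale = scale)
})

#' @rdname accessors
setMethod("tsValues", "ScatterMatrix", function(object) object@values)

#' @rdname accessors
setMethod("nTimepoints", "ScatterMatrix", function(object) object@nTimepoints)

#' @rdname accessors
setMethod("subjectId", "ScatterMatrix", function(object) object@subjectId)

#' @rdname accessors
setMethod("nParcels", "ScatterMatrix", function(object) ncol(object@values))

setMethod("show", "ScatterMatrix", function(object) {
  cat(sprintf("ScatterMatrix '%s': %d x %d from N = %d time points\n",
              object@subjectId, nrow(object@values), ncol(object@values),
              object@nTimepoints))
})

#' Coerce package matrices back to base matrices
#'
#' @param x a [ScatterMatrix-class].
#' @param ... unused.
#' @return the underlying numeric matrix.
#' @export
as.matrix.ScatterMatrix <- function(x, ...) x@values

#' Write / read a scatter matrix as CSV plus a JSON sidecar
#'
#' The matrix goes to `<path>` as a p x p CSV; subject id and N go to
#' `<path>.json`.
#'
#' @param s a [ScatterMatrix-class].
#' @param path CSV file path.
#' @return `path` invisibly (write) or a [ScatterMatrix-class] (read).
#' @export
writeScatter <- function(s, path) {
  stopifnot(is(s, "ScatterMatrix"))
  utils::write.table(s@values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(subject_id = s@subjectId, n_timepoints = s@nTimepoints),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeScatter
#' @export
readScatter <- function(path) {
  v <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"))
  new("ScatterMatrix", values = symmetrize(v),
      nTimepoints = as.integer(meta$n_timepoints),
      subjectId = as.character(meta$subject_id))
}

#' Build a design matrix from a subjects table
#'
#' Column one is the intercept.  For two groups, column two is the group
#' indicator: 0 for the reference group, 1 otherwise (e.g. 0 = conventional,
#' 1 = short sleeper).  With more groups, one indicator column is added per
#' non-reference level.
#'
#' @param subjects data.frame with columns subject_id and group.
#' @param referenceGroup the group coded 0.
#' @return numeric matrix with n rows, a leading all-ones column, and named
#'   columns; guaranteed full column rank.
#' @examples
#' s <- data.frame(subject_id = c("a", "b", "c"),
#'                 group = c("conv", "short", "conv"))
#' buildDesign(s, "conv")
#' @export
buildDesign <- function(subjects, referenceGroup) {
  subjects <- validateSubjects(subjects)
  groups <- subjects$group
  if (!referenceGroup %in% groups)
    stop("reference group '", referenceGroup, "' not present in subjects table",
         call. = FALSE)
  others <- setdiff(unique(groups), referenceGroup)
  X <- cbind(intercept = rep(1, nrow(subjects)))
  for (g in others) X <- cbind(X, as.numeric(groups == g))
  colnames(X) <- c("intercept", if (length(others)) paste0("group_", others))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  X
}
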