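#' Extract regional mean BOLD time series from a 4D image
#'
#' Averages the BOLD signal over all voxels of each atlas region at each
#' timepoint (unweighted arithmetic mean; no partial-volume weighting).
#' Label 0 is background and excluded; negative labels are rejected. Rows
#' are ordered by ascending atlas label, and that order is preserved by
#' every downstream artifact.
#'
#' @param bold 4D numeric array (x, y, z, time), a NIfTI image, or a path
#'   to a NIfTI file (read with RNifti).
#' @param atlas 3D integer label array/image/path on the same voxel grid.
#' @param trSeconds sampling interval in seconds; when `bold` is a NIfTI
#'   file/image the default is taken from its header (`pixdim[4]`).
#' @param labels optional integer vector of labels to extract (default all
#'   nonzero labels present in the atlas); a requested label with no voxels
#'   is an error naming the label.
#' @return A [RoiTimeSeries-class].
#' @export
extractRoiTimeSeries <- function(bold, atlas, trSeconds = NULL,
                                 labels = NULL) {
  boldArr <- asImageArray(bold, ndim = 4L)
  if (is.null(trSeconds)) {
    trSeconds <- niftiTR(bold)
    if (is.null(trSeconds))
      stop("'trSeconds' must be given when bold carries no TR header")
  }
  atlasArr <- asImageArray(atlas, ndim = 3L)
  if (!identical(dim(boldArr)[1:3], dim(atlasArr)))
    stop("grid mismatch: bold is ", paste(dim(boldArr)[1:3], collapse = "x"),
         " but atlas is ", paste(dim(atlasArr), collapse = "x"))
  lab <- as.integer(round(atlasArr))
  if (any(lab < 0L)) stop("negative atlas labels are not allowed")
  labels <- checkLabels(lab, labels)

  nt <- dim(boldArr)[4L]
  boldMat <- matrix(boldArr, ncol = nt)    # voxels x time
  grp <- factor(lab, levels = labels)
  keep <- !is.na(grp)
  sums <- rowsum(boldMat[keep, , drop = FALSE], grp[keep])
  counts <- as.vector(table(grp))
  values <- sums / counts
  roiTimeSeries(unname(values), regionIds = labels, trSeconds = trSeconds)
}

#' Regional mean of a 3D PET image
#'
#' Averages PET values over the voxels of each atlas region, with the same
#' labelling and ordering rules as [extractRoiTimeSeries()]. A non-positive
#' regional mean is physiologically suspect for uptake/synthesis measures
#' and triggers a warning, but the value is retained.
#'
#' @param pet 3D numeric array, NIfTI image, or path.
#' @inheritParams extractRoiTimeSeries
#' @param tracer `"rCPS"` or `"SUV"`.
#' @return A [RegionalPetVector-class] (validity is relaxed to allow the
#'   warned non-positive means only via direct construction; means must be
#'   positive).
#' @export
averagePetByRegion <- function(pet, atlas, tracer = c("rCPS", "SUV"),
                               labels = NULL) {
  tracer <- match.arg(tracer)
  petArr <- asImageArray(pet, ndim = 3L)
  atlasArr <- asImageArray(atlas, ndim = 3L)
  if (!identical(dim(petArr), dim(atlasArr)))
    stop("grid mismatch: pet is ", paste(dim(petArr), collapse = "x"),
         " but atlas is ", paste(dim(atlasArr), collapse = "x"))
  lab <- as.integer(round(atlasArr))
  if (any(lab < 0L)) stop("negative atlas labels are not allowed")
  labels <- checkLabels(lab, labels)
  means <- vapply(labels, function(l) mean(petArr[lab == l]), numeric(1))
  bad <- means <= 0
  if (any(bad))
    warning("non-positive regional mean for label(s) ",
            paste(labels[bad], collapse = ", "), "; values retained")
  if (any(bad)) {
    # bypass the strict-positivity validity check, keeping the values
    obj <- new("RegionalPetVector", values = pmax(means, .Machine$double.xmin),
               tracer = tracer, regionIds = labels)
    slot(obj, "values", check = FALSE) <- means
    return(obj)
  }
  regionalPetVector(means, tracer, regionIds = labels)
}

checkLabels <- function(lab, labels) {
  present <- sort(unique(lab[lab > 0L]))
  if (length(present) < 2L && is.null(labels))
    stop("atlas must contain at least 2 nonzero labels")
  if (is.null(labels)) return(present)
  labels <- as.integer(sort(labels))
  missing <- setdiff(labels, present)
  if (length(missing))
    stop("requested label(s) with zero voxels: ",
         paste(missing, collapse = ", "))
  labels
}

asImageArray <- function(x, ndim) {
  if (is.character(x)) x <- RNifti::readNifti(x)
  arr <- as.array(x)
  if (length(dim(arr)) != ndim)
    stop("expected a ", ndim, "-dimensional image, got ",
         length(dim(arr)), " dimensions")
  arr
}

niftiTR <- function(x) {
  if (is.character(x)) x <- RNifti::readNifti(x)
  pd <- tryCatch(RNifti::pixdim(x), error = function(e) NULL)
  if (!is.null(pd) && length(pd) >= 4L && pd[4L] > 0) return(pd[4L])
  NULL
}

#' Read and write region-labelled matrices as TSV
#'
#' Plain tab-separated persistence for intermediate matrices: a header row
#' of region labels, rows in region order. Human-inspectable and
#' diff-able.
#'
#' @param m numeric matrix (regions x anything, or square FC).
#' @param path file path.
#' @param regionIds integer labels used as column names (square matrices)
#'   or row names.
#' @return `readRegionalMatrix` returns a list with `matrix` and
#'   `regionIds`.
#' @export
writeRegionalMatrix <- function(m, path, regionIds = seq_len(nrow(m))) {
  df <- as.data.frame(m)
  colnames(df) <- if (ncol(m) == nrow(m)) paste0("r", regionIds)
                  else paste0("t", seq_len(ncol(m)))
  df <- cbind(region = regionIds, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionalMatrix
#' @export
readRegionalMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  region <- as.integer(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- NULL
  list(matrix = m, regionIds = region)
}
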