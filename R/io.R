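## Plain-text (TSV) serialization of the grid containers. MSI vendor data is
## expected to arrive already converted to this grid format (one row per
## pixel over a shared feature axis); all annotations travel in '#key value'
## header lines so a file round-trips to an identical object.

.writeHeader <- function(con, fields) {
    for (nm in names(fields))
        writeLines(sprintf("#%s\t%s", nm,
                           paste(fields[[nm]], collapse = "\t")), con)
}

.readHeader <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    fields <- list()
    for (l in hdr) {
        parts <- strsplit(sub("^#", "", l), "\t")[[1L]]
        fields[[parts[1L]]] <- parts[-1L]
    }
    list(fields = fields, nSkip = length(hdr))
}

#' Read and write MSI grid data as TSV
#'
#' Serializes an \linkS4class{MSIDataset} or \linkS4class{PeakTable} to a
#' single TSV file: '#'-prefixed header lines carry the sample annotations,
#' grid geometry and feature axis; the body has one row per pixel
#' (\code{row}, \code{col}, then one column per feature).
#'
#' @param object the dataset to write.
#' @param path file path.
#' @return \code{readMSIDataset} / \code{readPeakTable} return the restored
#'   object; the writers return \code{path} invisibly.
#' @name msi-io
NULL

#' @rdname msi-io
#' @export
writeMSIDataset <- function(object, path) {
    stopifnot(is(object, "MSIDataset"))
    con <- file(path, "w")
    on.exit(close(con))
    .writeHeader(con, list(class = "MSIDataset",
                           sample_id = object@sampleId,
                           treatment = object@treatment,
                           pair_id = object@pairId,
                           grid_shape = object@gridShape,
                           pixel_um = object@pixelUm,
                           mz = format(object@mz, digits = 10)))
    df <- data.frame(object@coords, object@spectra, check.names = FALSE)
    colnames(df) <- c("row", "col", sprintf("f%d", seq_along(object@mz)))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname msi-io
#' @export
readMSIDataset <- function(path) {
    h <- .readHeader(path)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            skip = h$nSkip, check.names = FALSE)
    MSIDataset(as.matrix(df[, -(1:2), drop = FALSE]),
               mz = as.numeric(h$fields$mz),
               coords = as.matrix(df[, 1:2]),
               gridShape = as.integer(h$fields$grid_shape),
               pixelUm = as.numeric(h$fields$pixel_um),
               sampleId = h$fields$sample_id,
               treatment = h$fields$treatment,
               pairId = h$fields$pair_id)
}

#' @rdname msi-io
#' @export
writePeakTable <- function(object, path) {
    stopifnot(is(object, "PeakTable"))
    con <- file(path, "w")
    on.exit(close(con))
    .writeHeader(con, list(class = "PeakTable",
                           sample_id = object@sampleId,
                           treatment = object@treatment,
                           pair_id = object@pairId,
                           grid_shape = object@gridShape,
                           pixel_um = object@pixelUm,
                           normalized = object@normalized,
                           feature_mz = format(object@featureMz, digits = 10)))
    df <- data.frame(object@coords, tic = object@tic, object@intensities,
                     check.names = FALSE)
    colnames(df) <- c("row", "col", "tic",
                      sprintf("f%d", seq_along(object@featureMz)))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname msi-io
#' @export
readPeakTable <- function(path) {
    h <- .readHeader(path)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            skip = h$nSkip, check.names = FALSE)
    PeakTable(as.matrix(df[, -(1:3), drop = FALSE]),
              featureMz = as.numeric(h$fields$feature_mz),
              coords = as.matrix(df[, 1:2]),
              gridShape = as.integer(h$fields$grid_shape),
              pixelUm = as.numeric(h$fields$pixel_um),
              tic = df$tic,
              normalized = as.logical(h$fields$normalized),
              sampleId = h$fields$sample_id,
              treatment = h$fields$treatment,
              pairId = h$fields$pair_id)
}

#' Write a cell assignment as TSV
#'
#' One row per pixel: \code{row}, \code{col}, \code{is_cell},
#' \code{cell_id}, \code{organization}.
#'
#' @param object a \linkS4class{CellAssignment}.
#' @param path file path.
#' @export
writeCellAssignment <- function(object, path) {
    stopifnot(is(object, "CellAssignment"))
    con <- file(path, "w")
    on.exit(close(con))
    .writeHeader(con, list(class = "CellAssignment",
                           sample_id = object@sampleId,
                           treatment = object@treatment,
                           pair_id = object@pairId,
                           grid_shape = object@gridShape,
                           pixel_um = object@pixelUm))
    df <- data.frame(object@coords, is_cell = object@isCell,
                     cell_id = object@cellId,
                     organization = object@organization)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
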