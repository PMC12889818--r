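#' Nuclear label map
#'
#' 2-D integer grid; 0 is background, nuclei are labeled 1..N contiguously.
#'
#' @slot labels integer matrix.
#' @slot pixelSize micrometres per pixel.
#' @exportClass LabelMap
setClass("LabelMap", slots = c(labels = "matrix", pixelSize = "numeric"))

setValidity("LabelMap", function(object) {
    l <- object@labels
    if (any(l < 0)) return("labels must be nonnegative")
    n <- max(l)
    if (n > 0 && !setequal(unique(as.integer(l[l > 0])), seq_len(n)))
        return("labels must be contiguous positive integers")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
})

setMethod("show", "LabelMap", function(object) {
    cat("LabelMap:", max(object@labels), "nuclei on a",
        nrow(object@labels), "x", ncol(object@labels), "grid @",
        object@pixelSize, "um/px\n")
})

#' @rdname LabelMap-class
#' @param x a \linkS4class{LabelMap}
#' @export
setMethod("length", "LabelMap", function(x) max(x@labels))

#' Segment nuclei from a quantized Hoechst channel
#'
#' Otsu-binarizes the nuclear channel, splits touching nuclei by a
#' watershed on the Euclidean distance transform of the mask, removes
#' objects smaller than \code{minAreaPx}, and relabels contiguously. The
#' binarization rule, watershed locality and size filter are exposed as
#' arguments because the underlying protocol fixes none of them.
#'
#' @param hoechst 8-bit (0-255) matrix.
#' @param minAreaPx minimum object size in pixels (default 20, about
#'   1.6 um^2 at 0.284 um pixels — a debris filter).
#' @param pixelSize micrometres per pixel.
#' @param ext watershed neighborhood radius in pixels (locality of the
#'   distance-transform maxima used as implicit seeds).
#' @param tolerance watershed merge tolerance (minimum depth separating
#'   two objects).
#' @param threshold optional manual binarization threshold (0-255); by
#'   default Otsu's threshold is computed.
#' @return a \linkS4class{LabelMap} (zero labels for a blank channel).
#' @export
segmentNuclei <- function(hoechst, minAreaPx = 20, pixelSize = 0.284,
                          ext = 5, tolerance = 1, threshold = NULL) {
    stopIfNot(is.matrix(hoechst), "hoechst must be a matrix")
    x <- hoechst / 255
    empty <- function() new("LabelMap",
        labels = matrix(0L, nrow(hoechst), ncol(hoechst)),
        pixelSize = pixelSize)
    if (max(x) <= 0) return(empty())
    th <- if (is.null(threshold))
        EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)
    else threshold / 255
    mask <- x > th
    if (!any(mask)) return(empty())
    dm <- EBImage::distmap(EBImage::Image(mask))
    ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance,
                                                ext = ext))
    areas <- tabulate(ws[ws > 0])
    keep <- which(areas >= minAreaPx)
    relab <- integer(length(areas))
    relab[keep] <- seq_along(keep)
    out <- matrix(0L, nrow(ws), ncol(ws))
    pos <- ws > 0
    out[pos] <- relab[ws[pos]]
    new("LabelMap", labels = out, pixelSize = pixelSize)
}

#' Measure per-cell size, centroid and marker MFIs
#'
#' For every labeled nucleus: area in pixels, centroid in micrometres
#' (0-based pixel centers, x along rows, y along columns, from the top-left
#' pixel center), and the mean fluorescence intensity of every panel
#' marker over the nucleus pixels — taken from the Gaussian-smoothed
#' channel for membrane markers and from the unsmoothed channel for
#' nuclear markers.
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param stack a \linkS4class{ChannelStack} sharing the label grid shape.
#' @param panel a \linkS4class{MarkerPanel}; all its markers must exist in
#'   the stack.
#' @param smoothRadiusPx Gaussian sigma for membrane smoothing (pixels).
#' @param sampleId,genotype labels copied into every record.
#' @return data.frame of cell records (cell_id, sample_id, genotype, x_um,
#'   y_um, area_px, one MFI column per marker).
#' @export
measureCells <- function(labels, stack, panel, smoothRadiusPx = 4,
                         sampleId = "sample_1", genotype = "control") {
    stopIfNot(is(labels, "LabelMap"), "labels must be a LabelMap")
    stopIfNot(is(stack, "ChannelStack"), "stack must be a ChannelStack")
    if (!identical(dim(labels@labels), dim(stack)))
        stop("labels and stack must share one shape", call. = FALSE)
    miss <- setdiff(markerNames(panel), channelNames(stack))
    if (length(miss))
        stop("stack is missing panel marker(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    lab <- labels@labels
    n <- max(lab)
    px <- labels@pixelSize
    if (n == 0)
        return(cbind(data.frame(cell_id = character(),
                                sample_id = character(),
                                genotype = character(), x_um = numeric(),
                                y_um = numeric(), area_px = integer()),
                     stats::setNames(as.data.frame(
                         matrix(numeric(), 0, length(markerNames(panel)))),
                         markerNames(panel))))
    idx <- which(lab > 0)
    lv <- lab[idx]
    area <- tabulate(lv, nbins = n)
    ri <- (idx - 1) %% nrow(lab)        # 0-based row (x)
    ci <- (idx - 1) %/% nrow(lab)       # 0-based col (y)
    xum <- as.numeric(rowsum(ri, lv)) / area * px
    yum <- as.numeric(rowsum(ci, lv)) / area * px
    rec <- data.frame(cell_id = sprintf("cell_%06d", seq_len(n)),
                      sample_id = sampleId, genotype = genotype,
                      x_um = xum, y_um = yum, area_px = area,
                      stringsAsFactors = FALSE)
    for (m in markerNames(panel)) {
        ch <- getChannel(stack, m)
        if (!panel@nuclear[[m]])
            ch <- smoothMembraneChannel(ch, smoothRadiusPx)
        rec[[m]] <- as.numeric(rowsum(ch[idx], lv)) / area
    }
    rec
}
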