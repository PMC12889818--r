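#' Render a simulated cell table to a multi-channel image stack
#'
#' Produces one channel per panel marker plus a Hoechst nuclear channel.
#' Nuclei are drawn as 2-D Gaussian blobs; nuclear markers (GFP, Ki67) are
#' drawn over the nucleus scaled by the cell's MFI; membrane markers are
#' drawn as annuli around the nucleus scaled by the cell's MFI. Optional
#' Poisson shot noise and linear channel spillover are applied per the
#' config. Ground truth is untouched by rendering.
#'
#' @param cells cell table from \code{\link{generateCellTable}} (or any
#'   table with x_um, y_um and MFI columns for the panel's markers).
#' @param config a \linkS4class{SimConfig}; supplies pixel size, field
#'   size, panel, noise scale and spillover matrix.
#' @param nucleusSigmaPx Gaussian sigma of the rendered nucleus, pixels.
#' @param membraneRadiusPx radius of the membrane annulus, pixels.
#' @param intensityScale raw intensity units per MFI unit.
#' @return a \linkS4class{ChannelStack} (raw, unquantized intensities).
#' @export
renderMultiplexImage <- function(cells, config, nucleusSigmaPx = 2.5,
                                 membraneRadiusPx = 4,
                                 intensityScale = 12) {
    panel <- config@panel
    markers <- markerNames(panel)
    miss <- setdiff(markers, names(cells))
    if (length(miss))
        stop("cells table lacks MFI columns: ",
             paste(miss, collapse = ", "), call. = FALSE)
    px <- config@pixelSize
    nx <- ceiling(config@fieldSize[1] / px)
    ny <- ceiling(config@fieldSize[2] / px)
    cx <- cells$x_um / px
    cy <- cells$y_um / px
    if (any(cx < 0 | cx > nx - 1 | cy < 0 | cy > ny - 1))
        stop("cells do not fit within the field at the configured pixel ",
             "size", call. = FALSE)
    if (anyDuplicated(round(cbind(cx, cy), 6)))
        stop("overlapping identical centroids; regenerate with a new seed",
             call. = FALSE)

    blank <- function() matrix(0, nx, ny)
    chans <- c(list(Hoechst = blank()),
               stats::setNames(lapply(markers, function(m) blank()),
                               markers))
    hw <- ceiling(max(4 * nucleusSigmaPx, membraneRadiusPx + 3))
    for (i in seq_len(nrow(cells))) {
        x0 <- round(cx[i]); y0 <- round(cy[i])
        xr <- max(1, x0 + 1 - hw):min(nx, x0 + 1 + hw)
        yr <- max(1, y0 + 1 - hw):min(ny, y0 + 1 + hw)
        dx <- (xr - 1) - cx[i]
        dy <- (yr - 1) - cy[i]
        d2 <- outer(dx^2, dy^2, "+")
        blob <- exp(-d2 / (2 * nucleusSigmaPx^2))
        ring <- exp(-(sqrt(d2) - membraneRadiusPx)^2 / 2)
        chans$Hoechst[xr, yr] <- chans$Hoechst[xr, yr] + 220 * blob
        for (m in markers) {
            amp <- intensityScale * cells[[m]][i]
            shape <- if (panel@nuclear[[m]]) blob else ring
            chans[[m]][xr, yr] <- chans[[m]][xr, yr] + amp * shape
        }
    }
    # channel spillover (markers only; identity = channels independent)
    S <- config@spillover
    if (any(S != diag(nrow(S)))) {
        orig <- chans[markers]
        for (m in markers) {
            mix <- blank()
            for (k in markers) if (S[m, k] != 0)
                mix <- mix + S[m, k] * orig[[k]]
            chans[[m]] <- mix
        }
    }
    if (config@noisePoissonScale > 0) {
        set.seed(deriveSeed(config@seed, 23))
        sc <- config@noisePoissonScale
        chans <- lapply(chans, function(x)
            matrix(stats::rpois(length(x), pmax(x, 0) * sc) / sc, nx, ny))
    }
    membrane <- c(Hoechst = FALSE, !panel@nuclear)
    names(membrane) <- c("Hoechst", markers)
    new("ChannelStack", channels = chans, pixelSize = px,
        membrane = membrane)
}

#' Read / write multi-page TIFF channel stacks
#'
#' One page per channel, 32-bit float, intensities scaled by 1/255 (the
#' tiff package's unit range) and rescaled on read. Channel names, the
#' membrane flags and the pixel size are recorded in a JSON sidecar file
#' (\code{<path>.json}) next to the TIFF.
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param path TIFF file path.
#' @export
writeChannelStack <- function(stack, path) {
    scale <- max(255, vapply(stack@channels, max, numeric(1)))
    pages <- lapply(stack@channels, function(x) x / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(markers = channelNames(stack),
                              pixel_size_um = stack@pixelSize,
                              membrane = as.list(stack@membrane),
                              intensity_scale = scale),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @describeIn writeChannelStack read a stack written by
#'   \code{writeChannelStack}.
#' @export
readChannelStack <- function(path) {
    meta_path <- paste0(path, ".json")
    if (!file.exists(meta_path))
        stop("channel-metadata sidecar not found: ", meta_path,
             call. = FALSE)
    meta <- jsonlite::fromJSON(meta_path)
    pages <- tiff::readTIFF(path, all = TRUE)
    scale <- if (is.null(meta$intensity_scale)) 255 else
        as.numeric(meta$intensity_scale)
    chans <- lapply(pages, function(p) matrix(p * scale, nrow(p),
                                              ncol(p)))
    names(chans) <- meta$markers
    membrane <- unlist(meta$membrane)
    new("ChannelStack", channels = chans,
        pixelSize = as.numeric(meta$pixel_size_um),
        membrane = membrane[meta$markers])
}
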