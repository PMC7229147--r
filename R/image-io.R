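#' Read a section image channel as an 8-bit grayscale matrix
#'
#' Reads a PNG or TIFF section image and returns an integer matrix in
#' 0..255. RGB images are reduced to the channel named by `channel`:
#' `"nuclei"` takes the blue plane (Hoechst-style counterstain) and
#' `"prolif"` the green plane (PHH3/Alexa-488-style proliferation marker);
#' single-plane images are used as-is. Sub-8-bit precision from
#' higher-depth sources is rescaled onto 0..255.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param channel `"nuclei"` or `"prolif"`.
#' @return Integer matrix (rows x columns) in 0..255.
#' @export
readSectionImage <- function(path, channel = c("nuclei", "prolif")) {
    channel <- match.arg(channel)
    if (is.null(path) || !file.exists(path))
        inputError(sprintf("image file not found: %s", path %||% "<NULL>"))
    ext <- tolower(tools::file_ext(path))
    img <- if (ext == "png") {
        png::readPNG(path)
    } else if (ext %in% c("tif", "tiff")) {
        if (!requireNamespace("tiff", quietly = TRUE))
            inputError("reading TIFF requires the 'tiff' package")
        tiff::readTIFF(path)
    } else {
        inputError(sprintf("unsupported image format: .%s", ext))
    }
    if (length(dim(img)) == 3L) {
        plane <- if (channel == "nuclei") 3L else 2L
        if (dim(img)[3] < plane) plane <- 1L
        img <- img[, , plane]
    }
    m <- round(img * 255)
    storage.mode(m) <- "integer"
    m
}

#' Write an 8-bit grayscale matrix as PNG
#'
#' @param image integer matrix in 0..255.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeGrayPNG <- function(image, path) {
    .checkGray(image)
    png::writePNG(image / 255, target = path)
    invisible(path)
}
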