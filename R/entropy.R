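# Spatial entropy of binarised section images.
#
# The statistic S sums, over all ordered pairs of distinct foreground
# pixels, the log of their Euclidean distance divided by the section's
# maximum width W_max:
#
#   S = sum_{(i,j) != (k,l)} Z_ij Z_kl ln( sqrt((k-i)^2 + (l-j)^2) / W_max )
#
# Self-pairs (zero distance) are excluded -- the literal quadruple sum is
# undefined at ln 0 -- and each unordered pair therefore contributes twice.
# Dividing distances by W_max makes sections of different widths
# comparable. S is large (less negative / more positive) when foreground
# is spread out or irregular, and small when points are tightly clustered.

#' Otsu threshold of an 8-bit grayscale image
#'
#' Exhaustively maximises the between-class intensity variance over the
#' 256-bin histogram. Pixels strictly greater than the returned threshold
#' are foreground; ties are resolved to the first (lowest) maximising
#' threshold.
#'
#' @param image integer matrix with values in 0..255.
#' @return Integer threshold in 0..255.
#' @export
otsuThreshold <- function(image) {
    .checkGray(image)
    counts <- tabulate(as.integer(image) + 1L, nbins = 256L)
    if (sum(counts > 0L) < 2L)
        inputError("degenerate image: fewer than two distinct intensities")
    p <- counts / sum(counts)
    levels <- 0:255
    omega <- cumsum(p)               # weight of class {0..T}
    mu <- cumsum(p * levels)         # first moment of class {0..T}
    muT <- mu[256]
    w0 <- omega[-256]
    w1 <- 1 - w0
    valid <- w0 > 0 & w1 > 0
    sigmaB <- rep(-Inf, 255)
    sigmaB[valid] <- (muT * w0[valid] - mu[-256][valid])^2 /
        (w0[valid] * w1[valid])
    which.max(sigmaB) - 1L           # first argmax; threshold T in 0..254
}

.checkGray <- function(image) {
    if (!is.matrix(image) || !is.numeric(image))
        inputError("image must be a numeric matrix")
    if (any(is.na(image)) || any(image < 0) || any(image > 255))
        inputError("image values must lie in [0, 255]")
    invisible(TRUE)
}

#' Binarise a grayscale image at a threshold
#'
#' Foreground (`TRUE`) is every pixel strictly greater than `threshold`,
#' matching the convention of [otsuThreshold()].
#'
#' @param image integer matrix with values in 0..255.
#' @param threshold integer in 0..255.
#' @return Logical matrix of the same shape.
#' @export
binarise <- function(image, threshold) {
    .checkGray(image)
    if (length(threshold) != 1L || is.na(threshold) ||
        threshold < 0 || threshold > 255)
        inputError("threshold must be a single value in [0, 255]")
    image > threshold
}

#' Maximum width of a binary mask
#'
#' The maximum, over rows, of the horizontal span of foreground pixels
#' (last foreground column minus first, plus one). Applied to the
#' nuclei-channel mask it measures the medio-lateral tissue extent W_max
#' used to normalise the entropy statistic; images must be oriented with
#' the medio-lateral axis horizontal.
#'
#' @param mask logical matrix.
#' @return Integer width in pixels (>= 1).
#' @export
maxWidth <- function(mask) {
    if (!is.logical(mask) || !is.matrix(mask))
        inputError("mask must be a logical matrix")
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L)
        inputError("empty mask: no foreground pixels")
    spans <- tapply(idx[, 2], idx[, 1], function(v) max(v) - min(v) + 1L)
    as.integer(max(spans))
}

# Sum of log pairwise Euclidean distances over unordered pairs, blocked to
# bound memory on large foreground sets.
.sumLogPairDist <- function(coords, block = 2048L) {
    n <- nrow(coords)
    if (n <= block)
        return(sum(log(dist(coords))))
    starts <- seq(1L, n, by = block)
    total <- 0
    for (a in seq_along(starts)) {
        ia <- starts[a]:min(starts[a] + block - 1L, n)
        A <- coords[ia, , drop = FALSE]
        total <- total + sum(log(dist(A)))
        for (b in seq_along(starts)) {
            if (b <= a) next
            ib <- starts[b]:min(starts[b] + block - 1L, n)
            B <- coords[ib, , drop = FALSE]
            d2 <- outer(rowSums(A^2), rowSums(B^2), "+") -
                2 * tcrossprod(A, B)
            d2[d2 < 0] <- 0
            total <- total + 0.5 * sum(log(d2))
        }
    }
    total
}

#' Entropy statistic of a foreground point set
#'
#' `entropyS()` evaluates the statistic on a binary mask, taking pixel
#' centres as 0-based integer coordinates; `entropyPoints()` evaluates the
#' same statistic on arbitrary continuous coordinates (the ground-truth
#' oracle for rendered images). Both return the ordered-pair sum `S`
#' together with the per-pair mean `S / (N (N - 1))` -- the raw sum grows
#' like the squared foreground count, so the per-pair mean is the quantity
#' to compare across sections with different cell numbers.
#'
#' @param mask logical matrix with at least 2 foreground pixels.
#' @param wMax normalising width (pixels), from [maxWidth()] of the
#'   nuclei-channel mask; must be positive.
#' @return A list with elements `S`, `SPerPair` and `N`.
#' @examples
#' m <- matrix(FALSE, 5, 9)
#' m[1, 1] <- m[1, 9] <- TRUE        # two pixels 8 apart
#' entropyS(m, wMax = 4)$S           # 2 * log(2)
#' @export
entropyS <- function(mask, wMax) {
    if (!is.logical(mask) || !is.matrix(mask))
        inputError("mask must be a logical matrix")
    idx <- which(mask, arr.ind = TRUE)
    entropyPoints(idx - 1, wMax)
}

#' @rdname entropyS
#' @param points n x 2 numeric matrix of coordinates (n >= 2, all rows
#'   distinct).
#' @export
entropyPoints <- function(points, wMax) {
    if (length(wMax) != 1L || is.na(wMax) || wMax <= 0)
        inputError("wMax must be a single positive number")
    points <- as.matrix(points)
    n <- nrow(points)
    if (n < 2L)
        inputError("entropy undefined: fewer than 2 foreground points")
    s <- 2 * .sumLogPairDist(points) - n * (n - 1) * log(wMax)
    if (!is.finite(s))
        numericError("coincident points give an undefined entropy")
    list(S = s, SPerPair = s / (n * (n - 1)), N = n)
}

#' Measure one section: threshold, binarise, width, entropy
#'
#' Runs the full per-section pipeline on a paired-channel image: each
#' channel is Otsu-thresholded and binarised; the maximum width W_max is
#' measured on the nuclei (all-cell counterstain) mask as the tissue
#' extent; the entropy S is computed on the proliferating-cell mask,
#' normalised by that W_max.
#'
#' @param nuclei,prolif integer matrices in 0..255 of identical shape
#'   (nuclei counterstain and proliferation-marker channels).
#' @param species,individual,position,section metadata recorded in the
#'   output row; `position` is `"joint"` or `"phalanx"`.
#' @param thresholdOverride optional fixed threshold applied to both
#'   channels instead of Otsu.
#' @param centroidMode if `TRUE`, each connected foreground component of
#'   the proliferation mask is reduced to its centroid before the entropy
#'   sum (one point per cell blob); default `FALSE`, summing over raw
#'   pixels. Requires the EBImage package.
#' @return One-row data.frame: species, individual, position, section, N,
#'   W_max, S, S_per_pair, thr_nuclei, thr_prolif.
#' @export
measureSection <- function(nuclei, prolif, species = NA, individual = NA,
                           position = NA, section = NA,
                           thresholdOverride = NULL, centroidMode = FALSE) {
    if (!identical(dim(nuclei), dim(prolif)))
        inputError("nuclei and proliferation images must have the same shape")
    thrN <- if (is.null(thresholdOverride)) otsuThreshold(nuclei)
            else as.integer(thresholdOverride)
    thrP <- if (is.null(thresholdOverride)) otsuThreshold(prolif)
            else as.integer(thresholdOverride)
    maskN <- binarise(nuclei, thrN)
    maskP <- binarise(prolif, thrP)
    w <- maxWidth(maskN)
    ent <- if (centroidMode)
        entropyPoints(.componentCentroids(maskP), w)
    else entropyS(maskP, w)
    data.frame(species = species, individual = individual,
               position = position, section = section,
               N = ent$N, W_max = w, S = ent$S, S_per_pair = ent$SPerPair,
               thr_nuclei = thrN, thr_prolif = thrP,
               stringsAsFactors = FALSE)
}

.componentCentroids <- function(mask) {
    if (!requireNamespace("EBImage", quietly = TRUE))
        inputError("centroid mode requires the EBImage package")
    lab <- EBImage::bwlabel(mask * 1)
    idx <- which(lab > 0, arr.ind = TRUE)
    g <- lab[lab > 0]
    cbind(tapply(idx[, 1] - 1, g, mean), tapply(idx[, 2] - 1, g, mean))
}

#' Nested averaging of section entropies
#'
#' Reproduces the nested design behind the species comparison: each
#' individual's value is the arithmetic mean of its (three) section
#' entropies; each species x position value is the mean over its (three)
#' individuals; and per species the joint/phalanx ratio of those means is
#' reported.
#'
#' @param measurements data.frame of per-section rows as produced by
#'   [measureSection()] (columns species, individual, position, S).
#' @return A list with `individuals` (species, individual, position,
#'   mean_S, n_sections), `species` (species, position, mean_S,
#'   n_individuals) and `ratios` (species, joint, phalanx, ratio); the
#'   ratio is `NA` when the phalanx mean is 0.
#' @export
summarizeEntropy <- function(measurements) {
    req <- c("species", "individual", "position", "S")
    if (!all(req %in% names(measurements)))
        inputError(sprintf("measurements must have columns: %s",
                           paste(req, collapse = ", ")))
    if (nrow(measurements) == 0L)
        inputError("no measurements to summarise")
    ind <- aggregate(S ~ species + position + individual,
                     data = measurements, FUN = mean)
    nsec <- aggregate(S ~ species + position + individual,
                      data = measurements, FUN = length)
    ind$n_sections <- nsec$S
    names(ind)[names(ind) == "S"] <- "mean_S"
    sp <- aggregate(mean_S ~ species + position, data = ind, FUN = mean)
    nind <- aggregate(mean_S ~ species + position, data = ind, FUN = length)
    sp$n_individuals <- nind$mean_S
    wide <- merge(
        sp[sp$position == "joint", c("species", "mean_S")],
        sp[sp$position == "phalanx", c("species", "mean_S")],
        by = "species", suffixes = c("_joint", "_phalanx"), all = TRUE)
    wide$ratio <- ifelse(
        !is.na(wide$mean_S_phalanx) & wide$mean_S_phalanx != 0,
        wide$mean_S_joint / wide$mean_S_phalanx, NA_real_)
    names(wide) <- c("species", "joint", "phalanx", "ratio")
    list(individuals = ind[order(ind$species, ind$position, ind$individual), ],
         species = sp[order(sp$species, sp$position), ],
         ratios = wide[order(wide$species), ])
}
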