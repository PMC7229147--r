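# Synthetic-data generators. All are pure functions of (parameters, seed):
# randomness is drawn under a locally-set seed and the caller's RNG state
# is restored afterwards, so repeated calls with the same seed are
# identical and no global state leaks.

withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)
        old <- if (had) get(".Random.seed", envir = globalenv())
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

#' Generate a random rooted binary tree
#'
#' Builds a topology by random sequential pairing (coalescent-style): the
#' tip pool is repeatedly reduced by joining two uniformly chosen
#' subtrees until one remains. All branch lengths are 1 ("unscaled").
#'
#' @param nTips number of tips (>= 2); labels are `t1..tn`.
#' @param seed optional integer seed; the same seed gives an identical
#'   tree.
#' @return A `phylo` tree with `nTips - 1` internal nodes and unit branch
#'   lengths.
#' @export
generateRandomTree <- function(nTips, seed = NULL) {
    if (length(nTips) != 1L || is.na(nTips) || nTips < 2)
        inputError("nTips must be an integer >= 2")
    withSeed(seed, {
        pool <- paste0("t", seq_len(nTips))
        while (length(pool) > 1L) {
            pick <- sample(length(pool), 2L)
            pool <- c(pool[-pick],
                      sprintf("(%s,%s)", pool[pick[1]], pool[pick[2]]))
        }
        readNewick(text = paste0(pool, ";"))
    })
}

#' Simulate Mk characters along a tree
#'
#' Forward simulation consistent with [transitionMatrix()]: each
#' character's root state is drawn uniformly over the k states and each
#' edge transitions the child's state with the model's transition
#' probabilities at that edge's length.
#'
#' @param tree a `phylo` tree.
#' @param model the generating [MkModel-class].
#' @param nChars number of independent characters (>= 1).
#' @param seed optional integer seed.
#' @return A [SimulatedCharacterSet-class]; `@states` is a tips x
#'   characters integer matrix of 0-based states.
#' @export
simulateMkCharacters <- function(tree, model, nChars, seed = NULL) {
    if (nChars < 1L) inputError("nChars must be >= 1")
    withSeed(seed, {
        k <- model@k
        ntip <- length(tree$tip.label)
        nn <- ntip + tree$Nnode
        tr <- stats::reorder(tree, "postorder")
        ord <- rev(seq_len(nrow(tr$edge)))   # parents before children
        edges <- tr$edge[ord, , drop = FALSE]
        elen <- tr$edge.length[ord]
        cache <- .transitionCache(model, elen)
        st <- matrix(NA_integer_, nn, nChars)
        st[.rootNode(tree), ] <- sample.int(k, nChars, replace = TRUE)
        for (e in seq_len(nrow(edges))) {
            cp <- t(apply(.lookupP(cache, elen[e]), 1, cumsum))
            r <- runif(nChars)
            st[edges[e, 2], ] <-
                1L + as.integer(rowSums(r > cp[st[edges[e, 1], ], ,
                                               drop = FALSE]))
        }
        states <- st[seq_len(ntip), , drop = FALSE] - 1L
        rownames(states) <- tree$tip.label
        new("SimulatedCharacterSet", tree = tree, model = model,
            states = states,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    })
}

#' Generate a planar point pattern of known disorder
#'
#' Three generating laws over a `width` x `height` rectangle:
#' `"poisson"` draws n i.i.d. uniform points (complete spatial
#' randomness); `"grid"` places the largest perfect square s^2 <= n of
#' points on a centred square lattice (maximal regularity); `"cluster"`
#' is a Thomas-type process -- `nParents` uniform parent locations, each
#' point a Gaussian offset (sd `radius`) from a uniformly assigned
#' parent, redrawn until inside the region.
#'
#' @param kind `"poisson"`, `"grid"` or `"cluster"`.
#' @param n requested number of points (>= 2).
#' @param width,height region extent (> 0).
#' @param params list of generator parameters: `nParents` (default 5) and
#'   `radius` (default `min(width, height)/20`) for `"cluster"`.
#' @param seed optional integer seed.
#' @return A [PointPattern-class]; for `"grid"` the realised count s^2 is
#'   recorded in `@params$nUsed`.
#' @export
generatePointPattern <- function(kind, n, width, height,
                                 params = list(), seed = NULL) {
    if (!is.character(kind) || length(kind) != 1L ||
        !kind %in% c("poisson", "grid", "cluster"))
        inputError(sprintf("unknown point pattern kind: %s",
                           paste(kind, collapse = ",")))
    if (n < 2L) inputError("n must be >= 2")
    if (width <= 0 || height <= 0)
        inputError("region extent must be positive")
    withSeed(seed, {
        if (kind == "poisson") {
            pts <- cbind(runif(n, 0, width), runif(n, 0, height))
        } else if (kind == "grid") {
            s <- floor(sqrt(n))
            xs <- (seq_len(s) - 0.5) / s * width
            ys <- (seq_len(s) - 0.5) / s * height
            pts <- as.matrix(expand.grid(x = xs, y = ys))
            params$nUsed <- s * s
        } else {
            nParents <- params$nParents %||% 5L
            radius <- params$radius %||% (min(width, height) / 20)
            parents <- cbind(runif(nParents, 0, width),
                             runif(nParents, 0, height))
            assign <- sample.int(nParents, n, replace = TRUE)
            pts <- parents[assign, , drop = FALSE] +
                matrix(rnorm(2 * n, sd = radius), n, 2)
            bad <- which(pts[, 1] < 0 | pts[, 1] > width |
                         pts[, 2] < 0 | pts[, 2] > height)
            while (length(bad)) {
                pts[bad, ] <- parents[assign[bad], , drop = FALSE] +
                    matrix(rnorm(2 * length(bad), sd = radius),
                           length(bad), 2)
                bad <- which(pts[, 1] < 0 | pts[, 1] > width |
                             pts[, 2] < 0 | pts[, 2] > height)
            }
        }
        dimnames(pts) <- NULL
        new("PointPattern", points = pts, width = width, height = height,
            kind = kind, params = params,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    })
}

.addBlobs <- function(mat, rows, cols, sigma, peak) {
    size <- nrow(mat)
    r <- ceiling(3.5 * sigma)
    for (i in seq_along(rows)) {
        r0 <- max(1L, floor(rows[i] - r))
        r1 <- min(size, ceiling(rows[i] + r))
        c0 <- max(1L, floor(cols[i] - r))
        c1 <- min(ncol(mat), ceiling(cols[i] + r))
        rr <- r0:r1
        cc <- c0:c1
        patch <- peak * exp(-(outer((rr - rows[i])^2, (cc - cols[i])^2,
                                    "+")) / (2 * sigma^2))
        mat[rr, cc] <- mat[rr, cc] + patch
    }
    mat
}

.clip8bit <- function(mat) {
    mat <- round(mat)
    mat[mat < 0] <- 0
    mat[mat > 255] <- 255
    storage.mode(mat) <- "integer"
    mat
}

#' Render a point pattern as a paired-channel section image
#'
#' Emulates a confocal section image pair. The proliferation channel
#' places a Gaussian blob (sd `sigma`, amplitude `peak`) at each pattern
#' point; the nuclei channel is a filled elliptical tissue silhouette
#' (circumscribing the pattern's rectangular region) overlaid with a
#' denser field of nucleus blobs; both receive additive Gaussian noise.
#' The returned ground truth (true blob centres in 0-based pixel
#' coordinates and true tissue width in pixels) feeds the
#' continuous-coordinate entropy oracle.
#'
#' @param pattern a [PointPattern-class].
#' @param imageSize square image side in pixels (>= 32).
#' @param sigma blob point-spread sd in pixels (> 0).
#' @param peak proliferation blob amplitude (0..255).
#' @param noiseSd additive Gaussian noise sd; 0 for noise-free renders.
#' @param background mean background level.
#' @param tissueLevel nuclei-channel silhouette intensity.
#' @param nucleiPeak,nucleiDensity amplitude and per-point multiplicity of
#'   the nucleus blob field.
#' @param scale pattern-units-to-pixels factor; `NULL` (default) chooses
#'   the largest scale at which the silhouette fits the image.
#' @param seed optional integer seed (noise and nucleus field).
#' @return A list with `nuclei`, `prolif` (integer matrices in 0..255)
#'   and `truth` (`centres`, `tissueWidthPx`, `scale`).
#' @export
renderSection <- function(pattern, imageSize = 256L, sigma = 1.2,
                          peak = 200, noiseSd = 4, background = 8,
                          tissueLevel = 90, nucleiPeak = 180,
                          nucleiDensity = 4, scale = NULL, seed = NULL) {
    if (imageSize < 32L) inputError("imageSize must be >= 32")
    if (sigma <= 0) inputError("sigma must be > 0")
    w <- pattern@width
    h <- pattern@height
    margin <- 3 * sigma + 2
    if (is.null(scale))
        scale <- (imageSize - 2 * margin) / (sqrt(2) * max(w, h))
    a <- sqrt(2) * w * scale / 2      # ellipse semi-axes circumscribing
    b <- sqrt(2) * h * scale / 2      # the pattern rectangle
    cx <- (imageSize + 1) / 2
    rows <- cx + (pattern@points[, 2] - h / 2) * scale
    cols <- cx + (pattern@points[, 1] - w / 2) * scale
    if (any(rows < 1 + sigma | rows > imageSize - sigma |
            cols < 1 + sigma | cols > imageSize - sigma))
        inputError("render error: blobs fall outside the image at this scale")
    if (cx + a > imageSize || cx + b > imageSize)
        inputError("render error: tissue silhouette exceeds the image")

    withSeed(seed, {
        prolif <- .addBlobs(matrix(0, imageSize, imageSize), rows, cols,
                            sigma, peak)
        if (noiseSd > 0)
            prolif <- prolif + background +
                matrix(rnorm(imageSize^2, sd = noiseSd),
                       imageSize, imageSize)
        grid <- seq_len(imageSize)
        inside <- outer(((grid - cx) / b)^2, ((grid - cx) / a)^2, "+") <= 1
        nuclei <- matrix(0, imageSize, imageSize)
        nuclei[inside] <- tissueLevel
        nNuc <- max(100L, round(nucleiDensity * nrow(pattern@points)))
        nr <- numeric(0)
        nc <- numeric(0)
        while (length(nr) < nNuc) {
            cr <- runif(nNuc, cx - b, cx + b)
            cc <- runif(nNuc, cx - a, cx + a)
            keep <- ((cr - cx) / b)^2 + ((cc - cx) / a)^2 <= 0.95
            nr <- c(nr, cr[keep])
            nc <- c(nc, cc[keep])
        }
        nuclei <- .addBlobs(nuclei, nr[seq_len(nNuc)], nc[seq_len(nNuc)],
                            sigma, nucleiPeak)
        if (noiseSd > 0)
            nuclei <- nuclei + background +
                matrix(rnorm(imageSize^2, sd = noiseSd),
                       imageSize, imageSize)
        list(nuclei = .clip8bit(nuclei), prolif = .clip8bit(prolif),
             truth = list(centres = cbind(rows, cols) - 1,
                          tissueWidthPx = 2 * a, scale = scale))
    })
}
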