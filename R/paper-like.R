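# A study-shaped synthetic image dataset: 3 species series x 2 section
# positions x 3 individuals x 3 section replicates = 54 paired-channel
# images, with planted joint/phalanx entropy ratios.
#
# The three series emulate the qualitative species contrasts reported for
# the real sections: a "moorhen-like" series whose joint entropy is about
# five times its phalanx entropy, a "grebe-like" series at about double,
# and a "coot-like" series at about parity. Because S sums over all
# ordered foreground-pixel pairs it scales like the squared number of
# proliferating cells at a fixed pattern law and section geometry, so the
# planted ratios are realised through cell abundance: all patterns are
# complete-spatial-randomness draws and only the per-position cell count
# differs. Joint sections are rendered wider than phalanx sections, so
# the W_max normalisation is exercised for real.
#
# The cell counts below were calibrated once by a pilot run of the full
# image pipeline (calibratePaperLike(): grid of counts per geometry,
# quadratic fit of mean S against count, solve for the target ratio) and
# then frozen; the emitted manifest records them alongside the targets.

.paperLikeDesign <- function() {
    list(
        joint   = list(width = 150, height = 95),
        phalanx = list(width = 110, height = 70),
        imageSize = 256L,
        sigma = 1.2, peak = 200, noiseSd = 4,
        nPhalanx = 70L,
        targetRatio = c(moorhen_like = 5, grebe_like = 2, coot_like = 1),
        # pilot-calibrated joint cell counts (see calibratePaperLike)
        nJoint = c(moorhen_like = 164L, grebe_like = 100L, coot_like = 67L)
    )
}

.renderPaperSection <- function(position, nCells, design) {
    geom <- design[[position]]
    pat <- generatePointPattern("poisson", nCells, geom$width, geom$height)
    renderSection(pat, imageSize = design$imageSize, sigma = design$sigma,
                  peak = design$peak, noiseSd = design$noiseSd, scale = 1)
}

#' Generate the study-shaped synthetic section dataset
#'
#' Writes 54 paired-channel PNG section images (3 species series x
#' {joint, phalanx} x 3 individuals x 3 section replicates) in the layout
#' `species/individual_i/position/section_j_{nuclei|prolif}.png`, plus a
#' `manifest.tsv` with one row per section pair recording metadata,
#' ground-truth cell counts and the calibration constants used. The
#' planted structure gives the moorhen-like series a joint/phalanx
#' entropy ratio of about 5, the grebe-like series about 2 and the
#' coot-like series about 1 (see the package vignette for how the ratios
#' are planted and calibrated).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of it.
#' @return Invisibly, the manifest data.frame (paths relative to `dir`).
#' @export
makePaperLikeDataset <- function(dir, seed = 1L) {
    design <- .paperLikeDesign()
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- list()
    withSeed(seed, {
        for (species in names(design$targetRatio)) {
            for (individual in 1:3) {
                for (position in c("joint", "phalanx")) {
                    n <- if (position == "joint")
                        design$nJoint[[species]] else design$nPhalanx
                    sub <- file.path(species,
                                     sprintf("individual_%d", individual),
                                     position)
                    dir.create(file.path(dir, sub), recursive = TRUE,
                               showWarnings = FALSE)
                    for (section in 1:3) {
                        ren <- .renderPaperSection(position, n, design)
                        np <- file.path(sub, sprintf(
                            "section_%d_nuclei.png", section))
                        pp <- file.path(sub, sprintf(
                            "section_%d_prolif.png", section))
                        writeGrayPNG(ren$nuclei, file.path(dir, np))
                        writeGrayPNG(ren$prolif, file.path(dir, pp))
                        rows[[length(rows) + 1L]] <- data.frame(
                            species = species, individual = individual,
                            position = position, section = section,
                            nuclei_path = np, prolif_path = pp,
                            n_cells = n,
                            true_width_px = ren$truth$tissueWidthPx,
                            target_ratio =
                                design$targetRatio[[species]],
                            calib_n_joint = design$nJoint[[species]],
                            calib_n_phalanx = design$nPhalanx,
                            stringsAsFactors = FALSE)
                    }
                }
            }
        }
    })
    manifest <- do.call(rbind, rows)
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(manifest)
}

#' Calibrate the planted entropy ratios (pilot simulation)
#'
#' Runs the full image pipeline (pattern, render, Otsu, entropy) over a
#' grid of cell counts for each section geometry, fits the mean entropy
#' as a quadratic in the count (S is a sum over ordered pairs, so
#' `S(n) ~ alpha n^2 + beta n`), and solves for the joint-section counts
#' that achieve the target joint/phalanx ratios at the fixed phalanx
#' count. This is how the constants frozen in the generator were obtained;
#' rerunning it is only needed if the render settings change.
#'
#' @param nGrid cell counts to pilot per geometry.
#' @param reps pattern replicates per count.
#' @param seed integer seed for the pilot draws.
#' @return A list with the fitted coefficients per geometry and the
#'   solved joint counts per series.
#' @export
calibratePaperLike <- function(nGrid = c(40L, 70L, 110L, 160L, 210L),
                               reps = 6L, seed = 20260101L) {
    design <- .paperLikeDesign()
    pilot <- function(position) {
        out <- lapply(nGrid, function(n) {
            s <- vapply(seq_len(reps), function(i) {
                ren <- .renderPaperSection(position, n, design)
                measureSection(ren$nuclei, ren$prolif)$S
            }, numeric(1))
            data.frame(n = n, S = mean(s))
        })
        do.call(rbind, out)
    }
    withSeed(seed, {
        dj <- pilot("joint")
        dp <- pilot("phalanx")
        fit <- function(d) stats::coef(stats::lm(S ~ 0 + I(n^2) + n,
                                                 data = d))
        cj <- fit(dj)
        cp <- fit(dp)
        sPhal <- cp[1] * design$nPhalanx^2 + cp[2] * design$nPhalanx
        solveN <- function(target) {
            # positive root of cj1 n^2 + cj2 n = target * sPhal
            disc <- cj[2]^2 + 4 * cj[1] * target * sPhal
            roots <- (-cj[2] + c(-1, 1) * sqrt(disc)) / (2 * cj[1])
            as.integer(round(max(roots)))
        }
        list(joint = cj, phalanx = cp, sPhalanx = unname(sPhal),
             nJoint = vapply(design$targetRatio, solveN, integer(1)))
    })
}
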