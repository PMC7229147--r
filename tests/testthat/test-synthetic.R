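test_that("random trees are binary, unit-length and deterministic", {
    expect_equal(ape::write.tree(generateRandomTree(2, seed = 1)),
                 ape::write.tree(readNewick(text = "(t1:1,t2:1);")))
    a <- generateRandomTree(8, seed = 42)
    b <- generateRandomTree(8, seed = 42)
    expect_identical(ape::write.tree(a), ape::write.tree(b))
    tr <- generateRandomTree(16, seed = 3)
    expect_identical(tr$Nnode, 15L)            # 2n - 2 edges, n - 1 nodes
    expect_identical(nrow(tr$edge), 30L)
    expect_true(all(tr$edge.length == 1))
    expect_webfoot_input_error(generateRandomTree(1))
})

test_that("Mk simulation respects the zero-rate and stationary limits", {
    tr <- generateRandomTree(6, seed = 8)
    frozen <- simulateMkCharacters(tr, MkModel(4, 0), 30, seed = 9)
    expect_true(all(apply(frozen@states, 2,
                          function(x) length(unique(x)) == 1L)))
    # long branches randomise tips: frequencies near 1/2 each
    long <- tr
    long$edge.length <- rep(100, nrow(tr$edge))
    sat <- simulateMkCharacters(long, MkModel(2, 1), 2000, seed = 10)
    freq <- mean(sat@states == 0)
    expect_lt(abs(freq - 0.5), 0.03)          # 3 sd binomial bound
    # determinism
    again <- simulateMkCharacters(tr, MkModel(4, 0.3), 25, seed = 77)
    expect_identical(again@states,
                     simulateMkCharacters(tr, MkModel(4, 0.3), 25,
                                          seed = 77)@states)
})

test_that("simulated characters are consistent with the pruning model", {
    # tip-pattern frequencies on a cherry match pruning probabilities
    tr <- readNewick(text = "(A:1,B:1);")
    m <- MkModel(2, 0.5)
    sim <- simulateMkCharacters(tr, m, 4000, seed = 123)
    pSame <- mean(sim@states[1, ] == sim@states[2, ])
    P <- transitionMatrix(m, 1)
    expected <- sum(P[1, ]^2)   # both tips equal given uniform root
    expect_lt(abs(pSame - expected), 0.025)
})

test_that("point patterns honour their generating law", {
    g <- generatePointPattern("grid", 9, 12, 12)
    expect_identical(g@params$nUsed, 9)
    expect_equal(sort(unique(g@points[, 1])), c(2, 6, 10))
    expect_equal(sort(unique(g@points[, 2])), c(2, 6, 10))

    p <- generatePointPattern("poisson", 100, 50, 30, seed = 2)
    expect_true(all(p@points[, 1] >= 0 & p@points[, 1] <= 50))
    expect_true(all(p@points[, 2] >= 0 & p@points[, 2] <= 30))
    expect_identical(nrow(p@points), 100L)

    cl <- generatePointPattern("cluster", 40, 50, 50,
                               list(nParents = 4L, radius = 1e-9),
                               seed = 3)
    expect_lte(nrow(unique(round(cl@points, 3))), 4L)

    expect_webfoot_input_error(
        generatePointPattern("hexagonal", 10, 10, 10))
    d1 <- generatePointPattern("cluster", 30, 20, 20, seed = 5)
    d2 <- generatePointPattern("cluster", 30, 20, 20, seed = 5)
    expect_identical(d1@points, d2@points)
})

test_that("rendering places blobs at the planted centres", {
    pts <- rbind(c(30.5, 20.5), c(80.5, 45.5))  # land on pixel centres
    pat <- new("PointPattern", points = pts, width = 110, height = 70,
               kind = "poisson", params = list(), seed = NA_integer_)
    ren <- renderSection(pat, scale = 1, noiseSd = 0, seed = 1)
    # exactly two local maxima, at the planted centres (0-based truth)
    pk <- which(ren$prolif == max(ren$prolif), arr.ind = TRUE)
    expect_identical(nrow(pk), 2L)
    got <- pk[order(pk[, 1]), ] - 1
    truth <- ren$truth$centres[order(ren$truth$centres[, 1]), ]
    expect_lt(max(abs(got - truth)), 1)

    # thresholded foreground area matches the analytic blob area
    p <- generatePointPattern("poisson", 60, 110, 70, seed = 31)
    ren2 <- renderSection(p, scale = 1, noiseSd = 0, seed = 31)
    thr <- otsuThreshold(ren2$prolif)
    N <- sum(binarise(ren2$prolif, thr))
    area <- pi * 2 * 1.2^2 * log(200 / thr)   # pixels above thr per blob
    expect_lt(abs(N - 60 * area) / (60 * area), 0.10)

    # determinism of both channels
    renA <- renderSection(p, scale = 1, seed = 4)
    renB <- renderSection(p, scale = 1, seed = 4)
    expect_identical(renA$nuclei, renB$nuclei)
    expect_identical(renA$prolif, renB$prolif)

    # blobs that would leave the image are a render error
    far <- new("PointPattern", points = rbind(c(0.5, 35), c(60, 35)),
               width = 120, height = 70, kind = "poisson",
               params = list(), seed = NA_integer_)
    expect_webfoot_input_error(renderSection(far, imageSize = 64,
                                             scale = 1))
})

test_that("the study-shaped dataset has the full nested layout", {
    d <- withr::local_tempdir()
    man <- makePaperLikeDataset(d, seed = 5)
    expect_identical(nrow(man), 54L)           # 3 x 2 x 3 x 3
    expect_identical(length(unique(man$species)), 3L)
    expect_true(all(table(man$species, man$position) == 9))
    expect_true(all(file.exists(file.path(d, man$nuclei_path))))
    expect_true(all(file.exists(file.path(d, man$prolif_path))))
    expect_true(all(c("n_cells", "target_ratio", "calib_n_joint")
                    %in% names(man)))
    # round-trip: written PNG reads back identically
    img <- readSectionImage(file.path(d, man$nuclei_path[1]), "nuclei")
    expect_true(is.integer(img) && all(img >= 0 & img <= 255))
})
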