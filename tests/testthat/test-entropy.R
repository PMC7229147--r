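test_that("Otsu threshold equals the exhaustive variance scan", {
    img <- matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10)
    thr <- otsuThreshold(img)
    expect_identical(thr, otsuScan(img))
    expect_true(thr >= 10 && thr <= 199)   # separates the two classes
    expect_identical(sum(binarise(img, thr)), 50L)

    set.seed(88)
    mix <- matrix(pmin(255, pmax(0, round(c(rnorm(600, 40, 10),
                                            rnorm(424, 180, 10))))),
                  32, 32)
    expect_identical(otsuThreshold(mix), otsuScan(mix))

    expect_webfoot_input_error(otsuThreshold(matrix(7L, 4, 4)))
})

test_that("binarisation is strict-greater and shape preserving", {
    z <- matrix(0L, 3, 4)
    expect_identical(binarise(z, 0), matrix(FALSE, 3, 4))
    expect_identical(binarise(z + 255L, 0), matrix(TRUE, 3, 4))
    checker <- outer(1:6, 1:7, function(i, j) ((i + j) %% 2) * 255L)
    mask <- binarise(checker, 100)
    expect_identical(sum(mask), sum(checker == 255L))
    expect_webfoot_input_error(binarise(z, 300))
})

test_that("maximum width is the widest row span of foreground", {
    m <- matrix(FALSE, 6, 12)
    m[3, 5] <- TRUE
    expect_identical(maxWidth(m), 1L)
    m2 <- matrix(FALSE, 6, 12)
    m2[2:4, 3:10] <- TRUE
    expect_identical(maxWidth(m2), 8L)
    # L-shape: vertical arm 2 wide, horizontal arm 5 wide
    L <- matrix(FALSE, 8, 8)
    L[1:8, 1:2] <- TRUE
    L[7:8, 1:5] <- TRUE
    expect_identical(maxWidth(L), 5L)
    expect_webfoot_input_error(maxWidth(matrix(FALSE, 3, 3)))
})

test_that("entropy worked examples match their closed forms", {
    # two pixels exactly wMax apart
    m <- matrix(FALSE, 3, 6)
    m[2, 1] <- m[2, 6] <- TRUE
    expect_equal(entropyS(m, wMax = 5)$S, 0, tolerance = 1e-9)
    # two pixels at 2 * wMax
    m2 <- matrix(FALSE, 3, 9)
    m2[1, 1] <- m2[1, 9] <- TRUE
    expect_equal(entropyS(m2, wMax = 4)$S, 2 * log(2), tolerance = 1e-9)
    # 3-4-5 right triangle, wMax = 5
    m3 <- matrix(FALSE, 6, 6)
    m3[1, 1] <- m3[1, 4] <- m3[5, 1] <- TRUE
    expect_equal(entropyS(m3, 5)$S, 2 * (log(3 / 5) + log(4 / 5)),
                 tolerance = 1e-9)
    expect_equal(entropyS(m3, 5)$SPerPair,
                 2 * (log(3 / 5) + log(4 / 5)) / 6, tolerance = 1e-12)
    expect_webfoot_input_error(entropyS(m, wMax = 0))
    single <- matrix(FALSE, 2, 2)
    single[1, 1] <- TRUE
    expect_webfoot_input_error(entropyS(single, 1))
})

test_that("entropy equals the naive ordered-pair double loop", {
    set.seed(9)
    for (i in 1:10) {
        m <- matrix(runif(30 * 30) < 0.08, 30, 30)
        if (sum(m) < 2) next
        w <- sample(5:40, 1)
        expect_equal(entropyS(m, w)$S, naiveEntropy(m, w),
                     tolerance = 1e-9)
    }
})

test_that("the blocked pair sum equals the direct one", {
    set.seed(4)
    pts <- cbind(runif(300, 0, 50), runif(300, 0, 50))
    expect_equal(webfoot:::.sumLogPairDist(pts, block = 37L),
                 sum(log(dist(pts))), tolerance = 1e-9)
})

test_that("entropy is invariant to translation and transposition", {
    set.seed(10)
    m <- matrix(FALSE, 40, 40)
    m[cbind(sample(10:20, 8), sample(5:15, 8))] <- TRUE
    base <- entropyS(m, 12)$S
    shifted <- matrix(FALSE, 40, 40)
    shifted[which(m, arr.ind = TRUE) + 15] <- TRUE
    expect_identical(entropyS(shifted, 12)$S, base)
    expect_identical(entropyS(t(m), 12)$S, base)
})

test_that("entropy is scale-consistent", {
    set.seed(12)
    pts <- cbind(runif(40, 0, 30), runif(40, 0, 30))
    base <- entropyPoints(pts, 20)$S
    expect_equal(entropyPoints(pts * 3.7, 20 * 3.7)$S, base,
                 tolerance = 1e-9)
    # rasterised version: integer upscaling within discretisation tolerance
    m <- matrix(FALSE, 60, 60)
    m[cbind(sample(1:60, 14), sample(1:60, 14))] <- TRUE
    idx <- which(m, arr.ind = TRUE)
    up <- matrix(FALSE, 155, 155)
    up[round((idx - 1) * 2.5) + 1] <- TRUE   # non-integer factor: rounding
    # wMax beyond the max pairwise distance keeps all log terms one-signed,
    # so the relative comparison is well conditioned
    s1 <- entropyS(m, 90)$S
    s2 <- entropyS(up, 90 * 2.5)$S
    expect_lt(abs(s2 - s1) / abs(s1), 0.02)
})

test_that("clustered patterns score lower mean entropy than random ones", {
    n <- 60
    w <- 100
    mean_S <- function(kind, params) {
        mean(vapply(1:50, function(s) {
            p <- generatePointPattern(kind, n, w, w, params, seed = 4000 + s)
            entropyPoints(p@points, w)$S
        }, numeric(1)))
    }
    sClust <- mean_S("cluster", list(nParents = 5L, radius = 3))
    sRand <- mean_S("poisson", list())
    expect_lt(sClust, sRand)
})

test_that("sections are measured deterministically and match the
           ground-truth centre oracle", {
    p <- generatePointPattern("poisson", 80, 110, 70, seed = 6)
    ren <- renderSection(p, scale = 1, seed = 6)
    a <- measureSection(ren$nuclei, ren$prolif, species = "x",
                        individual = 1, position = "joint", section = 1)
    b <- measureSection(ren$nuclei, ren$prolif, species = "x",
                        individual = 1, position = "joint", section = 1)
    expect_identical(a, b)
    expect_equal(a$W_max, ren$truth$tissueWidthPx, tolerance = 0.03)
    truth <- entropyPoints(ren$truth$centres, a$W_max)
    expect_lt(abs(a$S_per_pair - truth$SPerPair) / abs(truth$SPerPair),
              0.05)
})

test_that("centroid mode recovers the per-centre statistic closely", {
    skip_if_not_installed("EBImage")
    p <- generatePointPattern("poisson", 30, 160, 100, seed = 16)
    ren <- renderSection(p, scale = 1, noiseSd = 0, seed = 16)
    a <- measureSection(ren$nuclei, ren$prolif, centroidMode = TRUE)
    truth <- entropyPoints(ren$truth$centres, a$W_max)
    # one component per cell, minus the occasional touching pair
    expect_lte(a$N, nrow(ren$truth$centres))
    expect_gte(a$N, ceiling(0.85 * nrow(ren$truth$centres)))
    expect_lt(abs(a$S_per_pair - truth$SPerPair) / abs(truth$SPerPair),
              0.05)
})

test_that("a pointlike two-cell section reproduces the closed form", {
    # pointlike render: each cell thresholds to (nearly) a single pixel,
    # so the measured S must match 2 * ln(d / W_max) up to rasterisation
    pts <- rbind(c(5.5, 35.5), c(115.5, 35.5))   # 110 apart, on centres
    pat <- new("PointPattern", points = pts, width = 120, height = 70,
               kind = "poisson", params = list(), seed = NA_integer_)
    ren <- renderSection(pat, scale = 1, sigma = 0.25, noiseSd = 0,
                         seed = 1)
    ms <- measureSection(ren$nuclei, ren$prolif)
    expect_identical(ms$N, 2L)
    expect_equal(ms$S, 2 * log(110 / ren$truth$tissueWidthPx),
                 tolerance = 0.05)
})

test_that("nested averaging reproduces hand arithmetic", {
    one <- data.frame(species = "s", individual = 1, position = "joint",
                      S = c(1, 2, 3))
    expect_equal(summarizeEntropy(one)$individuals$mean_S, 2)
    df <- expand.grid(species = "s", individual = 1:3,
                      position = c("joint", "phalanx"), section = 1:3,
                      stringsAsFactors = FALSE)
    df$S <- c(outer(1:3 * 2, rep(1, 3)))  # ind means 2,4,6 per position
    sm <- summarizeEntropy(df)
    expect_equal(sm$species$mean_S, c(4, 4))
    expect_equal(sm$ratios$ratio, 1)
    # distinct 3x3 nested fixture against direct computation
    df2 <- df[df$position == "joint", ]
    df2$S <- 1:9
    byInd <- as.numeric(tapply(df2$S, df2$individual, mean))
    sm2 <- summarizeEntropy(df2)
    expect_equal(sort(sm2$individuals$mean_S), sort(byInd))
    expect_equal(sm2$species$mean_S, mean(byInd))
    # permutation within groups changes nothing
    df3 <- df[sample(nrow(df)), ]
    expect_equal(summarizeEntropy(df3)$species,
                 sm$species, ignore_attr = TRUE)
    expect_webfoot_input_error(summarizeEntropy(df[0, ]))
})
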