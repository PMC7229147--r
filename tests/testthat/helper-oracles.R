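# Independent oracles used across the suite. These deliberately share no
# code with the package's likelihood or entropy paths: enumeration sums
# over explicit state assignments, and the entropy oracle is a literal
# double loop over the statistic's defining sum.

# Log-likelihood by exhaustive enumeration over all state assignments to
# internal nodes (and to tips with missing states).
enumLogLik <- function(tree, states, model) {
    k <- stateCount(model)
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    edge <- tree$edge
    P <- lapply(tree$edge.length,
                function(t) transitionMatrix(model, t))
    s <- rep(NA_integer_, nn)
    s[seq_len(ntip)] <- states[tree$tip.label] + 1L
    free <- which(is.na(s))
    combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
    total <- 0
    for (i in seq_len(max(1L, nrow(combos)))) {
        if (length(free)) s[free] <- combos[i, ]
        p <- 1 / k
        for (e in seq_len(nrow(edge)))
            p <- p * P[[e]][s[edge[e, 1]], s[edge[e, 2]]]
        total <- total + p
    }
    log(total)
}

# Marginal internal-node posteriors by the same enumeration (Bayes rule
# over assignments).
enumMarginal <- function(tree, states, model) {
    k <- stateCount(model)
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    edge <- tree$edge
    P <- lapply(tree$edge.length,
                function(t) transitionMatrix(model, t))
    s <- rep(NA_integer_, nn)
    s[seq_len(ntip)] <- states[tree$tip.label] + 1L
    free <- which(is.na(s))
    combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
    acc <- matrix(0, nn, k)
    for (i in seq_len(max(1L, nrow(combos)))) {
        if (length(free)) s[free] <- combos[i, ]
        p <- 1 / k
        for (e in seq_len(nrow(edge)))
            p <- p * P[[e]][s[edge[e, 1]], s[edge[e, 2]]]
        for (v in (ntip + 1L):nn) acc[v, s[v]] <- acc[v, s[v]] + p
    }
    internal <- (ntip + 1L):nn
    out <- acc[internal, , drop = FALSE] / rowSums(acc)[internal]
    dimnames(out) <- list(internal, paste0("state", seq_len(k) - 1L))
    out
}

# Literal ordered-pair double loop of the entropy sum.
naiveEntropy <- function(mask, wMax) {
    idx <- which(mask, arr.ind = TRUE) - 1
    n <- nrow(idx)
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        d <- sqrt(sum((idx[i, ] - idx[j, ])^2))
        s <- s + log(d / wMax)
    }
    s
}

# Exhaustive between-class-variance scan over all 256 thresholds,
# computed from raw pixels (no histogram shortcuts); first maximum wins.
otsuScan <- function(image) {
    v <- as.vector(image)
    best <- -Inf
    bt <- NA_integer_
    for (T in 0:255) {
        g0 <- v[v <= T]
        g1 <- v[v > T]
        if (!length(g0) || !length(g1)) next
        w0 <- length(g0) / length(v)
        sb <- w0 * (1 - w0) * (mean(g0) - mean(g1))^2
        if (sb > best + 1e-12) {
            best <- sb
            bt <- T
        }
    }
    bt
}

# Small random trees (<= 5 tips) spanning cherries, caterpillars,
# balanced shapes and polytomies, with random branch lengths.
smallTreeTemplates <- c(
    "(A,B);",
    "((A,B),C);",
    "(A,B,C);",
    "((A,B),(C,D));",
    "((A,B),C,D);",
    "(((A,B),C),(D,E));",
    "((A,B,C),(D,E));",
    "(A,B,C,D,E);"
)

randomSmallCase <- function(k) {
    tr <- readNewick(text = sample(smallTreeTemplates, 1))
    tr$edge.length <- runif(nrow(tr$edge), 0.2, 2)
    st <- sample(0:(k - 1), length(tr$tip.label), replace = TRUE)
    if (runif(1) < 0.3)
        st[sample(length(st), 1)] <- NA
    names(st) <- tr$tip.label
    list(tree = tr, states = st)
}

expect_webfoot_input_error <- function(expr) {
    testthat::expect_error(expr, class = "webfoot_input_error")
}
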