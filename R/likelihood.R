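# Felsenstein pruning for the symmetric Mk model.
#
# Conditional likelihood vectors are propagated tipward-to-rootward in
# ape's postorder edge ordering; polytomies are handled natively (a node
# simply accumulates one factor per child). Underflow is controlled by
# rescaling each internal node's conditional vector to sum 1 when it is
# consumed, with the log scalers accumulated per character.

.lenKey <- function(t) sprintf("%.17g", t)

.transitionCache <- function(model, lengths) {
    u <- unique(lengths)
    mats <- lapply(u, function(t) transitionMatrix(model, t))
    names(mats) <- vapply(u, .lenKey, character(1))
    mats
}

.lookupP <- function(cache, t) cache[[.lenKey(t)]]

.rootNode <- function(tree) {
    setdiff(tree$edge[, 1], tree$edge[, 2])[1]
}

# Core pruning pass over an Ntip x nChars state matrix (already aligned to
# tree tip order; NA = missing, yielding an all-ones conditional vector).
# Returns per-character log-likelihoods and, if keep = TRUE, the scaled
# conditional vectors of every node (for the marginal up-pass).
.pruneCore <- function(tree, stateMat, model, keep = FALSE) {
    k <- model@k
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    nc <- ncol(stateMat)
    if (any(stateMat < 0L, na.rm = TRUE) ||
        any(stateMat >= k, na.rm = TRUE))
        inputError(sprintf("tip state indices must lie in 0..%d", k - 1L))
    tr <- stats::reorder(tree, "postorder")
    edge <- tr$edge
    elen <- tr$edge.length
    cache <- .transitionCache(model, elen)

    L <- array(1, dim = c(k, nc, nn))
    for (i in seq_len(ntip)) {
        s <- stateMat[i, ]
        obs <- which(!is.na(s))
        if (length(obs)) {
            Li <- L[, , i, drop = FALSE]
            dim(Li) <- c(k, nc)
            Li[, obs] <- 0
            Li[cbind(s[obs] + 1L, obs)] <- 1
            L[, , i] <- Li
        }
    }
    logScale <- numeric(nc)
    scaledChild <- logical(nn)
    for (e in seq_len(nrow(edge))) {
        par <- edge[e, 1]
        ch <- edge[e, 2]
        M <- L[, , ch]
        if (nc == 1L) M <- matrix(M, k, 1)
        if (ch > ntip && !scaledChild[ch]) {
            sc <- colSums(M)
            zero <- sc <= 0
            if (any(zero)) {
                logScale[zero] <- -Inf
                sc[zero] <- 1
            }
            logScale[!zero] <- logScale[!zero] + log(sc[!zero])
            M <- sweep(M, 2, sc, "/")
            L[, , ch] <- M
            scaledChild[ch] <- TRUE
        }
        contrib <- .lookupP(cache, elen[e]) %*% M
        L[, , par] <- L[, , par] * contrib
    }
    root <- .rootNode(tree)
    rootL <- matrix(L[, , root], k, nc)
    lik <- colSums(mkRootPrior(k) * rootL)
    ll <- ifelse(lik > 0, log(lik), -Inf) + logScale
    if (keep)
        list(logLik = ll, L = L, cache = cache, root = root, ntip = ntip)
    else
        list(logLik = ll)
}

#' Log-likelihood of tip states under the symmetric Mk model
#'
#' Computes the phylogenetic likelihood of one or more discrete characters
#' by Felsenstein's pruning recursion, with a uniform `1/k` root prior
#' (the model's stationary distribution). A tip with unknown state (`NA`
#' or `?`) contributes an all-ones conditional vector, the standard
#' ambiguity treatment. Polytomies are evaluated natively. Per-node
#' rescaling guards against underflow on large trees.
#'
#' @param tree a `phylo` tree (see [readNewick()]).
#' @param states a named integer vector (tip label -> state in 0..(k-1),
#'   `NA` = unknown), or an integer matrix with tip labels as rownames and
#'   one column per character.
#' @param model an [MkModel-class].
#' @return A numeric log-likelihood, one value per character.
#' @examples
#' tr <- readNewick(text = "((A:1,B:1):1,C:1);")
#' treeLogLik(tr, c(A = 0, B = 0, C = 1), MkModel(2, 0.3))
#' @export
treeLogLik <- function(tree, states, model) {
    m <- .alignStates(tree, states)
    .pruneCore(tree, m, model)$logLik
}

#' Maximum-likelihood estimate of the Mk rate
#'
#' Maximises the summed log-likelihood of the supplied characters over the
#' single symmetric rate by bounded one-dimensional optimisation on
#' `[0, rMax]` ([stats::optimize()]), the one free parameter of the Mk1
#' model. The boundary `r = 0` is checked explicitly, so constant
#' characters yield exactly 0.
#'
#' @inheritParams treeLogLik
#' @param states named vector or tips x characters matrix of states.
#' @param k state count.
#' @param rMax upper end of the search bracket (default 100 per unit
#'   branch length).
#' @param tol optimiser tolerance on the rate (default 1e-8).
#' @return An [MkFit-class]: the fitted model plus the maximised
#'   log-likelihood.
#' @examples
#' tr <- readNewick(text = "((A,B),(C,D));")
#' fitRate(tr, c(A = 0, B = 0, C = 1, D = 1), k = 2)
#' @export
fitRate <- function(tree, states, k, rMax = 100, tol = 1e-8) {
    m <- .alignStates(tree, states)
    if (all(is.na(m)))
        inputError("cannot estimate a rate: every character is entirely missing")
    k <- as.integer(k)
    f <- function(r) sum(.pruneCore(tree, m, MkModel(k, r))$logLik)
    # The profile log-likelihood flattens once branches saturate, which
    # starves a plain golden-section search of gradient; a coarse
    # log-spaced scan brackets the optimum first, then the 1-D optimiser
    # polishes between the scan neighbours.
    grid <- c(0, 10^seq(-6, log10(rMax), length.out = 49L))
    fg <- vapply(grid, f, numeric(1))
    i <- which.max(fg)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
    r <- opt$maximum
    ll <- opt$objective
    if (fg[i] >= ll) {
        r <- grid[i]
        ll <- fg[i]
    }
    if (f(0) >= ll) {
        r <- 0
        ll <- f(0)
    }
    new("MkFit", k = k, rate = r, logLik = ll, rMax = rMax, tol = tol)
}
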