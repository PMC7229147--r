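#' Marginal ancestral state reconstruction under the Mk model
#'
#' Computes, for every internal node, the marginal posterior probability of
#' each state given the tip data and the model, with a uniform root prior.
#' The computation is the standard two-pass scheme: a rootward pruning pass
#' produces each node's conditional (subtree) likelihoods; a tipward pass
#' then propagates the complementary likelihood of everything outside the
#' node's subtree, so that their normalised product is the exact per-node
#' marginal (equivalently, the result of re-rooting at each node). Under
#' the uniform prior these coincide with the "proportional likelihoods"
#' displayed as node pie charts by Mesquite-style reconstructions.
#'
#' @inheritParams treeLogLik
#' @param states a named integer vector of tip states (single character).
#' @return An [AncestralReconstruction-class].
#' @examples
#' tr <- readNewick(text = "((A:1,B:1):1,C:1);")
#' asr <- marginalAsr(tr, c(A = 0, B = 0, C = 1), MkModel(2, 0.3))
#' nodeProbabilities(asr)
#' @export
marginalAsr <- function(tree, states, model) {
    m <- .alignStates(tree, states)
    if (ncol(m) != 1L)
        inputError("marginalAsr reconstructs a single character")
    pr <- .pruneCore(tree, m, model, keep = TRUE)
    if (!is.finite(pr$logLik[1]))
        numericError("data have zero likelihood under this model")
    k <- model@k
    ntip <- pr$ntip
    root <- pr$root
    nn <- ntip + tree$Nnode
    D <- matrix(pr$L[, 1, ], k, nn)
    edge <- tree$edge
    elen <- tree$edge.length
    cache <- pr$cache
    childEdges <- split(seq_len(nrow(edge)), edge[, 1])

    Cdown <- matrix(0, k, nrow(edge))
    for (e in seq_len(nrow(edge)))
        Cdown[, e] <- .lookupP(cache, elen[e]) %*% D[, edge[e, 2]]

    U <- matrix(0, k, nn)
    U[, root] <- mkRootPrior(k)
    queue <- root
    while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        es <- childEdges[[as.character(v)]]
        Cs <- Cdown[, es, drop = FALSE]
        for (j in seq_along(es)) {
            ch <- edge[es[j], 2]
            if (ch <= ntip) next
            sib <- if (length(es) > 1L)
                apply(Cs[, -j, drop = FALSE], 1, prod)
            else rep(1, k)
            w <- U[, v] * sib
            u <- drop(crossprod(.lookupP(cache, elen[es[j]]), w))
            s <- sum(u)
            if (s > 0) u <- u / s
            U[, ch] <- u
            queue <- c(queue, ch)
        }
    }

    internals <- (ntip + 1L):nn
    post <- D[, internals, drop = FALSE] * U[, internals, drop = FALSE]
    cs <- colSums(post)
    if (any(cs <= 0))
        numericError("zero marginal posterior mass at an internal node")
    probs <- t(sweep(post, 2, cs, "/"))
    rownames(probs) <- internals
    colnames(probs) <- paste0("state", seq_len(k) - 1L)
    new("AncestralReconstruction", tree = tree, probabilities = probs,
        rate = model@rate, logLik = pr$logLik[1], k = k)
}

#' Fit the Mk rate and reconstruct ancestral states
#'
#' The full reconstruction used for the foot-morphology character: the
#' single symmetric rate is estimated by maximum likelihood on the supplied
#' character ([fitRate()]), then marginal per-node state probabilities are
#' computed at that rate ([marginalAsr()]). Pass `rate` to skip estimation
#' and reconstruct at a fixed rate.
#'
#' @inheritParams fitRate
#' @param states named integer vector of tip states (use [readStates()]
#'   for the TSV format); `NA` marks an unknown state.
#' @param k state count; defaults to the `"k"` attribute of `states`, or
#'   `max(states) + 1`.
#' @param rate optional fixed rate; `NULL` (default) estimates it.
#' @return An [AncestralReconstruction-class] carrying the rate used and
#'   the log-likelihood at that rate.
#' @examples
#' tr <- readNewick(text = "((A,B),(C,D));")
#' reconstruct(tr, c(A = 1, B = 1, C = 0, D = 0), k = 2)
#' @export
reconstruct <- function(tree, states, k = NULL, rate = NULL, rMax = 100,
                        tol = 1e-8) {
    if (is.null(k)) k <- attr(states, "k") %||%
            (max(2L, max(states, na.rm = TRUE) + 1L))
    k <- as.integer(k)
    model <- if (is.null(rate))
        fitRate(tree, states, k, rMax = rMax, tol = tol)
    else MkModel(k, rate)
    marginalAsr(tree, states, model)
}

#' Most probable state per internal node
#'
#' The argmax state of each node's marginal probability vector. Ties
#' (probabilities equal within `tieTol`) are broken in favour of the
#' lowest state index and flagged, so the output is deterministic and the
#' ambiguity visible.
#'
#' @param recon an [AncestralReconstruction-class].
#' @param tieTol absolute tolerance for declaring two probabilities tied.
#' @return A data.frame with columns `node` (ape node number), `state`
#'   (0-based index) and `tie` (logical).
#' @export
mostProbableStates <- function(recon, tieTol = 1e-9) {
    p <- recon@probabilities
    state <- max.col(p, ties.method = "first") - 1L
    best <- p[cbind(seq_len(nrow(p)), state + 1L)]
    tie <- rowSums(abs(p - best) <= tieTol) > 1L
    data.frame(node = as.integer(rownames(p)), state = state, tie = tie)
}

#' Assemble a full node-to-state map
#'
#' Combines observed tip states with reconstructed internal-node states
#' (the argmax of each marginal vector) into one vector indexed by ape
#' node number, the input [countIndependentOrigins()] expects.
#'
#' @param tree a `phylo` tree.
#' @param tipStates named integer vector of tip states (`NA` = unknown).
#' @param recon an [AncestralReconstruction-class] for the same tree.
#' @return Integer vector of length `Ntip + Nnode`; element i is node i's
#'   state (`NA` where the tip state is unknown).
#' @export
nodeStateMap <- function(tree, tipStates, recon) {
    m <- .alignStates(tree, tipStates)
    mp <- mostProbableStates(recon)
    out <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
    out[seq_along(tree$tip.label)] <- m[, 1]
    out[mp$node] <- mp$state
    out
}

#' Count independent origins of a set of states
#'
#' An origin is an edge whose child's state belongs to `targetStates`
#' while its parent's state does not (tips count as children), so each
#' independent gain of the target condition along the tree is counted once.
#' Edges whose parent or child state is explicitly unknown (`NA`, e.g. a
#' taxon whose morphology is unrecorded) are excluded from the count; a
#' node absent from the mapping altogether is an error.
#'
#' @param tree a `phylo` tree.
#' @param nodeStates integer vector of length `Ntip + Nnode`, indexed by
#'   ape node number (see [nodeStateMap()]).
#' @param targetStates integer vector of target state indices, e.g.
#'   `c(1, 2, 3, 4)` for "any webbed foot type".
#' @return Nonnegative integer count of origin edges.
#' @export
countIndependentOrigins <- function(tree, nodeStates, targetStates) {
    nn <- length(tree$tip.label) + tree$Nnode
    if (length(nodeStates) != nn)
        inputError(sprintf(
            "nodeStates must cover all %d nodes (got %d entries)",
            nn, length(nodeStates)))
    sp <- nodeStates[tree$edge[, 1]]
    sc <- nodeStates[tree$edge[, 2]]
    ok <- !is.na(sp) & !is.na(sc)
    sum(ok & sc %in% targetStates & !(sp %in% targetStates))
}
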