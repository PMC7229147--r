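setOldClass("phylo")

#' One-parameter symmetric Mk model
#'
#' Continuous-time Markov model for a k-state discrete character with a
#' single symmetric exchange rate: every off-diagonal entry of the rate
#' matrix equals `rate` and each diagonal entry is `-(k-1)*rate`, so rows
#' sum to zero. Its stationary distribution is uniform over the k states.
#'
#' @slot k integer state count, at least 2.
#' @slot rate nonnegative substitution rate per state pair, per unit branch
#'   length.
#'
#' @seealso [transitionMatrix()], [fitRate()]
#' @export
setClass("MkModel", representation(k = "integer", rate = "numeric"))

setValidity("MkModel", function(object) {
    msg <- character()
    if (length(object@k) != 1L || is.na(object@k) || object@k < 2L)
        msg <- c(msg, "'k' must be a single integer >= 2")
    if (length(object@rate) != 1L || is.na(object@rate) || object@rate < 0)
        msg <- c(msg, "'rate' must be a single nonnegative number")
    if (length(msg)) msg else TRUE
})

#' Construct an MkModel
#'
#' @param k integer number of character states (>= 2); 5 for the
#'   foot-morphology coding (non-webbed, palmate, semipalmate, totipalmate,
#'   lobate).
#' @param rate symmetric per-pair substitution rate (>= 0).
#' @return An [MkModel-class] object.
#' @examples
#' m <- MkModel(k = 5, rate = 0.7)
#' transitionMatrix(m, t = 1)
#' @export
MkModel <- function(k, rate) {
    new("MkModel", k = as.integer(k), rate = as.numeric(rate))
}

#' Fitted Mk model
#'
#' An [MkModel-class] whose rate was estimated by maximum likelihood,
#' carrying the maximised log-likelihood and the optimisation settings.
#'
#' @slot logLik maximised summed log-likelihood over the characters fitted.
#' @slot rMax upper end of the search bracket for the rate.
#' @slot tol optimiser tolerance on the rate.
#' @export
setClass("MkFit", contains = "MkModel",
         representation(logLik = "numeric", rMax = "numeric", tol = "numeric"))

#' Marginal ancestral state reconstruction
#'
#' Per-internal-node marginal posterior state probabilities under an Mk
#' model with uniform root prior, together with the rate used and the
#' log-likelihood of the data at that rate. Node numbering follows ape:
#' tips are 1..Ntip and internal nodes (Ntip+1)..(Ntip+Nnode), the root
#' being Ntip+1.
#'
#' @slot tree the `phylo` tree reconstructed on.
#' @slot probabilities numeric matrix, one row per internal node (rownames
#'   are ape node numbers), one column per state; rows sum to 1.
#' @slot rate rate at which the reconstruction was computed.
#' @slot logLik log-likelihood of the tip data at that rate.
#' @slot k state count.
#' @export
setClass("AncestralReconstruction",
         representation(tree = "phylo", probabilities = "matrix",
                        rate = "numeric", logLik = "numeric", k = "integer"))

setValidity("AncestralReconstruction", function(object) {
    p <- object@probabilities
    msg <- character()
    if (nrow(p) != object@tree$Nnode)
        msg <- c(msg, "one probability row per internal node is required")
    if (ncol(p) != object@k)
        msg <- c(msg, "probability matrix must have k columns")
    if (any(p < -1e-12))
        msg <- c(msg, "probabilities must be nonnegative")
    if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-9))
        msg <- c(msg, "each node's probabilities must sum to 1 (tol 1e-9)")
    if (length(msg)) msg else TRUE
})

#' Planar point pattern with known generating law
#'
#' Continuous (x, y) points in a rectangular region, produced by one of
#' three generators: complete spatial randomness (`poisson`), a centred
#' square lattice (`grid`), or a Thomas-type cluster process (`cluster`).
#' Stand-in for proliferating-cell positions in a section.
#'
#' @slot points n x 2 numeric matrix of (x, y) coordinates.
#' @slot width,height region extent; all points lie inside.
#' @slot kind one of "poisson", "grid", "cluster".
#' @slot params generator parameters (e.g. `nParents`, `radius`).
#' @slot seed integer seed the pattern was drawn with (NA if none given).
#' @export
setClass("PointPattern",
         representation(points = "matrix", width = "numeric",
                        height = "numeric", kind = "character",
                        params = "list", seed = "integer"))

setValidity("PointPattern", function(object) {
    p <- object@points
    msg <- character()
    if (ncol(p) != 2L) msg <- c(msg, "'points' must be an n x 2 matrix")
    if (object@width <= 0 || object@height <= 0)
        msg <- c(msg, "region extent must be positive")
    if (nrow(p) && (any(p[, 1] < 0 | p[, 1] > object@width) ||
                    any(p[, 2] < 0 | p[, 2] > object@height)))
        msg <- c(msg, "all points must lie inside the region")
    if (!object@kind %in% c("poisson", "grid", "cluster"))
        msg <- c(msg, "unknown pattern kind")
    if (length(msg)) msg else TRUE
})

#' Simulated Mk character dataset
#'
#' Tip states for one or more characters evolved forward along a tree under
#' a known [MkModel-class], for parameter-recovery and oracle tests.
#'
#' @slot tree the `phylo` tree simulated on.
#' @slot model the generating model (true rate).
#' @slot states integer matrix, tips x characters, entries in 0..(k-1);
#'   rownames are tip labels.
#' @slot seed the seed used (NA if none given).
#' @export
setClass("SimulatedCharacterSet",
         representation(tree = "phylo", model = "MkModel",
                        states = "matrix", seed = "integer"))
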