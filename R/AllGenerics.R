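#' Accessors for Mk models and reconstructions
#'
#' `stateCount()` returns the number of character states k; `substRate()`
#' the symmetric substitution rate; `nodeProbabilities()` the internal-node
#' marginal probability matrix of a reconstruction; `fittedRate()` the rate
#' a reconstruction or fit was computed at.
#'
#' @param object an [MkModel-class], [MkFit-class] or
#'   [AncestralReconstruction-class] object.
#' @return `stateCount()` an integer; `substRate()`/`fittedRate()` a
#'   number; `nodeProbabilities()` a numeric matrix with ape node numbers
#'   as rownames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stateCount", function(object) standardGeneric("stateCount"))

#' @rdname accessors
#' @export
setGeneric("substRate", function(object) standardGeneric("substRate"))

#' @rdname accessors
#' @export
setGeneric("nodeProbabilities",
           function(object) standardGeneric("nodeProbabilities"))

#' @rdname accessors
#' @export
setGeneric("fittedRate", function(object) standardGeneric("fittedRate"))

#' Transition probability matrix of an Mk model
#'
#' Closed form for the symmetric k-state Mk model over a branch of length
#' `t`: diagonal entries `1/k + ((k-1)/k) * exp(-k*r*t)` and off-diagonal
#' entries `1/k - (1/k) * exp(-k*r*t)`. Rows sum to 1; the matrix is
#' invariant under any permutation of states.
#'
#' @param model an [MkModel-class].
#' @param t branch length in expected-substitution units (>= 0).
#' @return A k x k stochastic matrix.
#' @examples
#' transitionMatrix(MkModel(2, 1), 1)[1, 1]  # (1 + exp(-2)) / 2
#' @export
setGeneric("transitionMatrix",
           function(model, t) standardGeneric("transitionMatrix"))

#' @rdname accessors
#' @export
setMethod("stateCount", "MkModel", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("substRate", "MkModel", function(object) object@rate)

#' @rdname accessors
#' @export
setMethod("stateCount", "AncestralReconstruction", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("fittedRate", "AncestralReconstruction",
          function(object) object@rate)

#' @rdname accessors
#' @export
setMethod("fittedRate", "MkFit", function(object) object@rate)

#' @rdname accessors
#' @export
setMethod("nodeProbabilities", "AncestralReconstruction",
          function(object) object@probabilities)

#' @describeIn MkFit maximised log-likelihood of the fit.
#' @param object an [MkFit-class] or [AncestralReconstruction-class].
#' @param ... ignored.
#' @export
setMethod("logLik", "MkFit", function(object, ...) object@logLik)

#' @describeIn AncestralReconstruction log-likelihood of the tip data at
#'   the reconstruction's rate.
#' @param object an [AncestralReconstruction-class].
#' @param ... ignored.
#' @export
setMethod("logLik", "AncestralReconstruction",
          function(object, ...) object@logLik)

setMethod("show", "MkModel", function(object) {
    cat("Symmetric Mk model: k =", object@k,
        " rate =", format(object@rate), "\n")
})

setMethod("show", "MkFit", function(object) {
    cat("Fitted symmetric Mk model (ML)\n")
    cat("  k        :", object@k, "\n")
    cat("  rate     :", format(object@rate), "\n")
    cat("  logLik   :", format(object@logLik), "\n")
    cat("  bracket  : [0,", format(object@rMax), "] tol",
        format(object@tol), "\n")
})

setMethod("show", "AncestralReconstruction", function(object) {
    cat("Marginal ancestral state reconstruction\n")
    cat("  tree     :", length(object@tree$tip.label), "tips,",
        object@tree$Nnode, "internal nodes\n")
    cat("  k        :", object@k, " rate:", format(object@rate),
        " logLik:", format(object@logLik), "\n")
    cat("  root state probabilities:",
        paste(sprintf("%.3f", object@probabilities[1, ]), collapse = " "),
        "\n")
})

setMethod("show", "PointPattern", function(object) {
    cat(sprintf("PointPattern: %d points, kind '%s', region %g x %g\n",
                nrow(object@points), object@kind, object@width,
                object@height))
})

setMethod("show", "SimulatedCharacterSet", function(object) {
    cat(sprintf(
        "SimulatedCharacterSet: %d tips x %d characters, k = %d, rate = %g\n",
        nrow(object@states), ncol(object@states), object@model@k,
        object@model@rate))
})
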