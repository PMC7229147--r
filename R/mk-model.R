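#' @rdname transitionMatrix
#' @aliases transitionMatrix,MkModel-method
setMethod("transitionMatrix", "MkModel", function(model, t) {
    if (length(t) != 1L || is.na(t) || t < 0)
        inputError("branch length 't' must be a single number >= 0")
    k <- model@k
    e <- exp(-k * model@rate * t)
    off <- (1 - e) / k
    P <- matrix(off, k, k)
    diag(P) <- 1 / k + (k - 1) / k * e
    P
})

# Uniform root prior: the stationary distribution of the symmetric Mk model.
mkRootPrior <- function(k) rep(1 / k, k)
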