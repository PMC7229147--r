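#' Read a rooted tree from Newick text
#'
#' Thin validating wrapper around [ape::read.tree()]. Polytomies (including
#' a basal polytomy) are legal. Branch lengths are optional: any absent
#' length is set to `defaultBranchLength`, which realises the "unscaled
#' tree" convention (every branch length 1) when a topology-only Newick
#' string is supplied. Explicit lengths are accepted unchanged, so reruns
#' on alternative calibrated topologies need no special handling.
#'
#' @param file path to a Newick file containing one tree, or `NULL`.
#' @param text a Newick string, used when `file` is `NULL`.
#' @param defaultBranchLength length assigned to branches without one
#'   (default 1).
#' @return A `phylo` tree. Non-root branch lengths are checked to be
#'   strictly positive and tip labels to be unique.
#' @examples
#' tr <- readNewick(text = "((A,B),C);")
#' tr$edge.length  # all 1
#' @export
readNewick <- function(file = NULL, text = NULL, defaultBranchLength = 1) {
    if (is.null(text)) {
        if (is.null(file) || !file.exists(file))
            inputError(sprintf("tree file not found: %s", file %||% "<NULL>"))
        text <- paste(readLines(file, warn = FALSE), collapse = "")
    }
    .checkNewickSyntax(text)
    tree <- tryCatch(ape::read.tree(text = text),
                     error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tree) || !inherits(tree, "phylo"))
        inputError("could not parse Newick string")
    if (anyDuplicated(tree$tip.label))
        inputError(sprintf("duplicate tip labels: %s",
                           paste(unique(tree$tip.label[
                               duplicated(tree$tip.label)]), collapse = ", ")))
    if (is.null(tree$edge.length)) {
        tree$edge.length <- rep(defaultBranchLength, nrow(tree$edge))
    } else {
        tree$edge.length[is.na(tree$edge.length)] <- defaultBranchLength
    }
    if (any(tree$edge.length <= 0))
        inputError("all branch lengths must be > 0")
    tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal syntax pre-check so malformed input fails with a character
# offset rather than with whatever ape returns.
.checkNewickSyntax <- function(text) {
    chars <- strsplit(text, "")[[1]]
    depth <- 0L
    for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        if (chars[i] == ")") {
            depth <- depth - 1L
            if (depth < 0L)
                inputError(sprintf(
                    "malformed Newick: unmatched ')' at character %d", i))
        }
    }
    if (depth > 0L)
        inputError(sprintf(
            "malformed Newick: %d unclosed '(' by character %d",
            depth, length(chars)))
    if (!grepl(";", text, fixed = TRUE))
        inputError(sprintf(
            "malformed Newick: missing ';' terminator by character %d",
            length(chars)))
    invisible(TRUE)
}

#' Read a tip-state table
#'
#' Reads a two-column tab-separated table `tip_label<TAB>state`, where
#' states are integer codes in `0..(k-1)` and `?` (or an empty field) marks
#' a tip whose state is unknown. For the foot-morphology coding, states are
#' 0 non-webbed, 1 palmate, 2 semipalmate, 3 totipalmate, 4 lobate.
#'
#' @param file path to the TSV (no header).
#' @param k state count; if `NULL`, inferred as `max(state) + 1` (at least
#'   2).
#' @return A named integer vector (names are tip labels, `NA` for unknown
#'   states) with attribute `"k"`.
#' @export
readStates <- function(file, k = NULL) {
    if (is.null(file) || !file.exists(file))
        inputError(sprintf("states file not found: %s", file %||% "<NULL>"))
    tab <- read.delim(file, header = FALSE, sep = "\t",
                      colClasses = "character", comment.char = "#",
                      blank.lines.skip = TRUE)
    if (ncol(tab) < 2L)
        inputError("states file must have two tab-separated columns")
    raw <- trimws(tab[[2]])
    states <- suppressWarnings(as.integer(raw))
    states[raw %in% c("?", "", "NA")] <- NA_integer_
    bad <- !is.na(raw) & !(raw %in% c("?", "", "NA")) & is.na(states)
    if (any(bad))
        inputError(sprintf("non-integer state value(s): %s",
                           paste(unique(raw[bad]), collapse = ", ")))
    names(states) <- trimws(tab[[1]])
    if (anyDuplicated(names(states)))
        inputError("duplicate tip labels in states file")
    if (is.null(k)) k <- max(2L, max(states, na.rm = TRUE) + 1L)
    k <- as.integer(k)
    if (any(states >= k, na.rm = TRUE) || any(states < 0L, na.rm = TRUE))
        inputError(sprintf("state indices must lie in 0..%d", k - 1L))
    structure(states, k = k)
}

# Align a named state vector (or tips x chars matrix) with the tree's tips;
# every tip must have an entry. Returns an Ntip x nChars integer matrix in
# tree tip order, NA marking missing states.
.alignStates <- function(tree, states) {
    if (is.matrix(states)) {
        if (is.null(rownames(states)))
            inputError("state matrix must have tip labels as rownames")
        miss <- setdiff(tree$tip.label, rownames(states))
        if (length(miss))
            inputError(sprintf("tips without state entries: %s",
                               paste(miss, collapse = ", ")))
        m <- states[tree$tip.label, , drop = FALSE]
    } else {
        if (is.null(names(states)))
            inputError("state vector must be named by tip label")
        miss <- setdiff(tree$tip.label, names(states))
        if (length(miss))
            inputError(sprintf("tips without state entries: %s",
                               paste(miss, collapse = ", ")))
        m <- matrix(as.integer(states[tree$tip.label]), ncol = 1,
                    dimnames = list(tree$tip.label, NULL))
    }
    storage.mode(m) <- "integer"
    m
}
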