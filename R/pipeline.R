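# Orchestration layer: file-in/file-out runs over the analysis functions,
# with machine-readable reports and a stable status contract
# (0 success, 2 input validation, 3 numerical failure).

#' Read a flat key=value run configuration
#'
#' Parses a minimal TOML-style flat text file: one `key = value` pair per
#' line, `#` comments and blank lines ignored, values kept as strings.
#' Command-line flags are expected to override these values.
#'
#' @param path path to the config file.
#' @return A named list of character values.
#' @export
readRunConfig <- function(path) {
    if (is.null(path) || !file.exists(path))
        inputError(sprintf("config file not found: %s", path %||% "<NULL>"))
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$",
                                    lines))
    bad <- vapply(kv, length, integer(1)) != 3L
    if (any(bad))
        inputError(sprintf("malformed config line: '%s'",
                           lines[which(bad)[1]]))
    stats::setNames(lapply(kv, function(m) trimws(m[3])),
                    vapply(kv, function(m) m[2], character(1)))
}

.statusOf <- function(cond) {
    if (inherits(cond, "webfoot_input_error")) 2L
    else if (inherits(cond, "webfoot_numeric_error")) 3L
    else 3L
}

.writeReport <- function(path, report) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(path)
}

# Newick with per-node probability comments: internal node labels become
# [&p={p0,...,pk-1}]. Written by hand because standard writers quote
# bracketed labels.
.annotatedNewick <- function(tree, probs) {
    ntip <- length(tree$tip.label)
    children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    fmt <- function(v) sprintf("[&p={%s}]",
                               paste(sprintf("%.6f", v), collapse = ","))
    rec <- function(node) {
        if (node <= ntip) return(tree$tip.label[node])
        es <- children[[as.character(node)]]
        parts <- vapply(es, function(e) {
            paste0(rec(tree$edge[e, 2]), ":",
                   format(tree$edge.length[e], digits = 15))
        }, character(1))
        paste0("(", paste(parts, collapse = ","), ")",
               fmt(probs[as.character(node), ]))
    }
    paste0(rec(.rootNode(tree)), ";")
}

#' Run the ancestral-state-reconstruction pipeline on files
#'
#' Reads a Newick tree and a tip-state TSV, fits the Mk rate (unless
#' `rate` is given), computes marginal ancestral states, and writes into
#' `out`: `node_probabilities.tsv` (node id, label, per-state
#' probabilities, most-probable state, tie flag), `annotated.nwk` (node
#' comments `[&p={...}]`) and `report.json` (rate, log-likelihood, origin
#' count if requested, seed, package version). Failures are reported with
#' status 2 (input validation) or 3 (numerical), matching the CLI exit
#' codes.
#'
#' @param treeFile Newick file with one tree.
#' @param statesFile two-column TSV `tip_label<TAB>state`, `?` = unknown.
#' @param k state count; `NULL` infers it from the states.
#' @param rate optional fixed rate (skips estimation).
#' @param origins optional integer vector of target states; if given, the
#'   number of independent origins of that state set is reported.
#' @param out output directory (created if needed).
#' @param seed recorded in the report (the computation itself is
#'   deterministic).
#' @return Invisibly, a list with `status` (0 on success), the output
#'   `files`, and the `reconstruction`; on failure `status` and `error`.
#' @export
runAsr <- function(treeFile, statesFile, k = NULL, rate = NULL,
                   origins = NULL, out = ".", seed = NULL) {
    res <- tryCatch({
        tree <- readNewick(treeFile)
        states <- readStates(statesFile, k = k)
        k <- attr(states, "k")
        recon <- reconstruct(tree, states, k = k, rate = rate)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)

        probs <- nodeProbabilities(recon)
        mp <- mostProbableStates(recon)
        labels <- if (!is.null(tree$node.label)) tree$node.label
                  else rep("", tree$Nnode)
        tab <- data.frame(node_id = mp$node, label = labels,
                          round(probs, 10), map_state = mp$state,
                          tie_flag = mp$tie, stringsAsFactors = FALSE)
        names(tab)[3:(2 + k)] <- paste0("p_state", seq_len(k) - 1L)
        probFile <- file.path(out, "node_probabilities.tsv")
        write.table(tab, probFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)

        nwkFile <- file.path(out, "annotated.nwk")
        writeLines(.annotatedNewick(tree, probs), nwkFile)

        report <- list(tool = "webfoot asr",
                       version = as.character(packageVersion("webfoot")),
                       tree = treeFile, states = statesFile, k = k,
                       rate = fittedRate(recon),
                       rate_fixed = !is.null(rate),
                       logLik = logLik(recon), seed = seed)
        if (!is.null(origins)) {
            nsm <- nodeStateMap(tree, states, recon)
            report$origin_states <- as.integer(origins)
            report$independent_origins <-
                countIndependentOrigins(tree, nsm, as.integer(origins))
        }
        repFile <- file.path(out, "report.json")
        .writeReport(repFile, report)
        list(status = 0L, files = c(probFile, nwkFile, repFile),
             reconstruction = recon, report = report)
    }, webfoot_input_error = function(e)
        list(status = 2L, error = conditionMessage(e), code = "E_INPUT"),
       webfoot_numeric_error = function(e)
        list(status = 3L, error = conditionMessage(e), code = "E_NUMERIC"))
    invisible(res)
}

#' Run the section-entropy pipeline on a manifest of images
#'
#' Reads a manifest TSV (columns `species`, `individual`, `position`,
#' `section`, `nuclei_path`, `prolif_path`; paths relative to the
#' manifest's directory or absolute), measures every section with
#' [measureSection()], aggregates with [summarizeEntropy()], and writes
#' `sections.tsv`, `summary.tsv` (per species: joint mean, phalanx mean,
#' ratio) and `report.json` into `out`.
#'
#' @param manifest path to the manifest TSV.
#' @param out output directory (created if needed).
#' @param centroidMode reduce each proliferation blob to its centroid
#'   before the entropy sum (default `FALSE`: raw pixels).
#' @param thresholdOverride optional fixed threshold for both channels.
#' @param seed recorded in the report.
#' @return Invisibly, a list with `status`, output `files`, the
#'   per-section data.frame and the summary; on failure `status` and
#'   `error` (naming the offending manifest row where applicable).
#' @export
runEntropy <- function(manifest, out = ".", centroidMode = FALSE,
                       thresholdOverride = NULL, seed = NULL) {
    res <- tryCatch({
        if (is.null(manifest) || !file.exists(manifest))
            inputError(sprintf("manifest not found: %s",
                               manifest %||% "<NULL>"))
        tab <- read.delim(manifest, sep = "\t", stringsAsFactors = FALSE)
        req <- c("species", "individual", "position", "section",
                 "nuclei_path", "prolif_path")
        missing <- setdiff(req, names(tab))
        if (length(missing))
            inputError(sprintf("manifest lacks column(s): %s",
                               paste(missing, collapse = ", ")))
        if (!all(tab$position %in% c("joint", "phalanx")))
            inputError("manifest 'position' must be 'joint' or 'phalanx'")
        base <- dirname(manifest)
        resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
        sections <- lapply(seq_len(nrow(tab)), function(i) {
            row <- tab[i, ]
            tryCatch({
                nuc <- readSectionImage(resolve(row$nuclei_path), "nuclei")
                pro <- readSectionImage(resolve(row$prolif_path), "prolif")
                measureSection(nuc, pro, species = row$species,
                               individual = row$individual,
                               position = row$position,
                               section = row$section,
                               thresholdOverride = thresholdOverride,
                               centroidMode = centroidMode)
            }, webfoot_input_error = function(e)
                inputError(sprintf("manifest row %d: %s", i,
                                   conditionMessage(e))))
        })
        sections <- do.call(rbind, sections)
        summary <- summarizeEntropy(sections)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        secFile <- file.path(out, "sections.tsv")
        write.table(sections, secFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        sumFile <- file.path(out, "summary.tsv")
        write.table(summary$ratios, sumFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        repFile <- file.path(out, "report.json")
        .writeReport(repFile, list(
            tool = "webfoot entropy",
            version = as.character(packageVersion("webfoot")),
            manifest = manifest, n_sections = nrow(sections),
            centroid_mode = centroidMode,
            threshold_override = thresholdOverride,
            thresholds_nuclei = sections$thr_nuclei,
            thresholds_prolif = sections$thr_prolif, seed = seed))
        list(status = 0L, files = c(secFile, sumFile, repFile),
             sections = sections, summary = summary)
    }, webfoot_input_error = function(e)
        list(status = 2L, error = conditionMessage(e), code = "E_INPUT"),
       webfoot_numeric_error = function(e)
        list(status = 3L, error = conditionMessage(e), code = "E_NUMERIC"))
    invisible(res)
}
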