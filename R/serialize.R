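#' PDAG serialization
#'
#' PDAGs round-trip through a small JSON document
#' `{"nodes": [...], "directed": [[from, to], ...],
#'   "undirected": [[a, b], ...]}` and export to Graphviz DOT, where
#' undirected edges are rendered with `dir=none`.  When a confidence table
#' is supplied, each DOT edge carries its bootstrap confidence as a
#' `confidence` attribute and a proportional `penwidth`, so line thickness
#' reflects relative edge strength.
#'
#' @param p a `"pdag"`.
#' @param path file path; for the `to_` functions, `NULL` returns the text.
#' @param confidences optional `"edge_confidence"` table (see
#'   [edge_confidences()]).
#' @return `pdag_to_json()`/`pdag_to_dot()` return the serialized text
#'   invisibly when writing to a file, visibly otherwise;
#'   `pdag_from_json()` returns a `"pdag"`.
#' @export
pdag_to_json <- function(p, path = NULL) {
  doc <- list(nodes = p$nodes,
              directed = unname(apply(p$directed, 1, c, simplify = FALSE)),
              undirected = unname(apply(p$undirected, 1, c, simplify = FALSE)))
  txt <- jsonlite::toJSON(doc, auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname pdag_to_json
#' @param json JSON text or a path to a JSON file.
#' @export
pdag_from_json <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json)) json <- readLines(json)
  doc <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                            simplifyMatrix = TRUE)
  as_mat <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    if (is.matrix(x)) x else do.call(rbind, x)
  }
  pdag(doc$nodes, directed = as_mat(doc$directed),
       undirected = as_mat(doc$undirected))
}

#' @rdname pdag_to_json
#' @param name graph name used in the DOT header.
#' @export
pdag_to_dot <- function(p, path = NULL, confidences = NULL, name = "pdag") {
  q <- function(x) paste0("\"", x, "\"")
  conf_attr <- function(x, y) {
    if (is.null(confidences)) return("")
    cf <- max(confidences$counts[x, y], confidences$counts[y, x]) /
      confidences$n_replicates
    sprintf(", confidence=%.4f, penwidth=%.2f", cf, 0.5 + 3 * cf)
  }
  lines <- c(sprintf("digraph %s {", q(name)), paste0("  ", q(p$nodes), ";"))
  for (r in seq_len(nrow(p$directed))) {
    e <- p$directed[r, ]
    lines <- c(lines, sprintf("  %s -> %s [dir=forward%s];",
                              q(e[1]), q(e[2]), conf_attr(e[1], e[2])))
  }
  for (r in seq_len(nrow(p$undirected))) {
    e <- p$undirected[r, ]
    lines <- c(lines, sprintf("  %s -> %s [dir=none%s];",
                              q(e[1]), q(e[2]), conf_attr(e[1], e[2])))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
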