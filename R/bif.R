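#' Read and write discrete Bayesian networks in BIF format
#'
#' A reader/writer for the Bayesian Interchange Format used by the standard
#' benchmark-network repositories: `variable` blocks declare discrete
#' states, `probability` blocks hold either a `table` line (root nodes) or
#' one parenthesised parent-configuration row per line.  The reader covers
#' that common subset; properties and comments are ignored.
#'
#' @param path file path.
#' @return `read_bif()` returns a [bayes_net()] (state labels are kept as
#'   the `states` attribute on each CPT).
#' @export
read_bif <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("//[^\n]*", "", txt)
  states <- list()
  # variable blocks
  var_pat <- "variable\\s+([^\\s{]+)\\s*\\{[^}]*type\\s+discrete\\s*\\[\\s*\\d+\\s*\\]\\s*\\{([^}]*)\\}"
  m <- gregexpr(var_pat, txt, perl = TRUE)
  starts <- m[[1]]
  if (starts[1] == -1) stop_input("no variable blocks found in ", path)
  for (blk in regmatches(txt, m)[[1]]) {
    name <- sub(var_pat, "\\1", blk, perl = TRUE)
    st <- sub(var_pat, "\\2", blk, perl = TRUE)
    states[[name]] <- trimws(strsplit(st, ",")[[1]])
  }
  nodes <- names(states)
  arities <- setNames(vapply(states, length, 0L), nodes)
  # probability blocks
  prob_pat <- "probability\\s*\\(([^)]*)\\)\\s*\\{([^}]*)\\}"
  pm <- gregexpr(prob_pat, txt, perl = TRUE)
  cpts <- list()
  cpt_parents <- list()
  edges <- NULL
  for (blk in regmatches(txt, pm)[[1]]) {
    head <- sub(prob_pat, "\\1", blk, perl = TRUE)
    body <- sub(prob_pat, "\\2", blk, perl = TRUE)
    parts <- strsplit(head, "\\|")[[1]]
    child <- trimws(parts[1])
    pa <- if (length(parts) > 1) trimws(strsplit(parts[2], ",")[[1]]) else character(0)
    if (!child %in% nodes) stop_input("probability block for unknown node ", child)
    if (length(pa)) edges <- rbind(edges, cbind(pa, child))
    nrows <- if (length(pa)) prod(arities[pa]) else 1L
    cpt <- matrix(NA_real_, nrows, arities[[child]])
    if (!length(pa)) {
      tb <- regmatches(body, regexpr("table[^;]*;", body, perl = TRUE))
      if (!length(tb)) stop_input("missing table line for root node ", child)
      vals <- as.numeric(strsplit(gsub("table|;", "", tb), ",")[[1]])
      cpt[1, ] <- vals
    } else {
      rows <- regmatches(body,
                         gregexpr("\\(([^)]*)\\)\\s*([^;]*);", body, perl = TRUE))[[1]]
      for (rw in rows) {
        cfg <- trimws(strsplit(sub(".*\\(([^)]*)\\).*", "\\1", rw), ",")[[1]])
        vals <- as.numeric(strsplit(sub(".*\\)\\s*([^;]*);.*", "\\1", rw), ",")[[1]])
        idx <- 1L
        stride <- 1L
        for (j in seq_along(pa)) {
          code <- match(cfg[j], states[[pa[j]]])
          if (is.na(code)) stop_input("unknown state ", cfg[j], " for ", pa[j])
          idx <- idx + (code - 1L) * stride
          stride <- stride * arities[[pa[j]]]
        }
        cpt[idx, ] <- vals
      }
    }
    if (anyNA(cpt)) stop_input("incomplete CPT for node ", child)
    attr(cpt, "states") <- states[[child]]
    cpts[[child]] <- cpt
    cpt_parents[[child]] <- pa
  }
  missing <- setdiff(nodes, names(cpts))
  if (length(missing))
    stop_input("no probability block for node(s): ", paste(missing, collapse = ", "))
  g <- dag(nodes, edges)
  bayes_net(g, arities, cpts, cpt_parents = cpt_parents)
}

#' @rdname read_bif
#' @param bn a [bayes_net()].
#' @export
write_bif <- function(bn, path) {
  nodes <- bn$graph$nodes
  state_names <- lapply(nodes, function(v) {
    st <- attr(bn$cpts[[v]], "states")
    st %||% paste0("s", seq_len(bn$arities[[v]]))
  })
  names(state_names) <- nodes
  out <- c("network unknown {", "}")
  for (v in nodes) {
    out <- c(out,
             sprintf("variable %s {", v),
             sprintf("  type discrete [ %d ] { %s };", bn$arities[[v]],
                     paste(state_names[[v]], collapse = ", ")),
             "}")
  }
  fmt <- function(x) paste(format(x, digits = 10, scientific = FALSE,
                                  trim = TRUE), collapse = ", ")
  for (v in nodes) {
    pa <- bn$cpt_parents[[v]]
    cpt <- bn$cpts[[v]]
    if (!length(pa)) {
      out <- c(out,
               sprintf("probability ( %s ) {", v),
               sprintf("  table %s;", fmt(cpt[1, ])),
               "}")
    } else {
      out <- c(out, sprintf("probability ( %s | %s ) {", v,
                            paste(pa, collapse = ", ")))
      nrows <- nrow(cpt)
      for (r in seq_len(nrows)) {
        idx <- r - 1L
        cfg <- character(length(pa))
        for (j in seq_along(pa)) {
          ar <- bn$arities[[pa[j]]]
          cfg[j] <- state_names[[pa[j]]][idx %% ar + 1L]
          idx <- idx %/% ar
        }
        out <- c(out, sprintf("  (%s) %s;", paste(cfg, collapse = ", "),
                              fmt(cpt[r, ])))
      }
      out <- c(out, "}")
    }
  }
  writeLines(out, path)
  invisible(path)
}
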