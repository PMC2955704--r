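#' Separating-set cache
#'
#' Maps unordered node pairs to a conditioning set that rendered them
#' independent (their `dSep`).  Every independence declared by a test during
#' learning is recorded here (first finding wins), so that the v-structure
#' orientation phase can retrieve a separating set for any pair that was
#' split apart.
#'
#' @return `sepset_cache()` returns an empty cache (class
#'   `"sepset_cache"`).
#' @export
sepset_cache <- function() {
  structure(new.env(parent = emptyenv(), hash = TRUE),
            class = "sepset_cache")
}

#' @rdname sepset_cache
#' @param cache a `"sepset_cache"`.
#' @param x,y node names (unordered pair).
#' @export
sepset_has <- function(cache, x, y) {
  !is.null(cache[[pair_key(x, y)]])
}

#' @rdname sepset_cache
#' @export
sepset_get <- function(cache, x, y) {
  v <- cache[[pair_key(x, y)]]
  if (is.null(v)) stop("no cached separating set for pair ", x, ", ", y,
                       call. = FALSE)
  v
}

#' @rdname sepset_cache
#' @param z the separating set to record.
#' @export
sepset_set <- function(cache, x, y, z) {
  z <- sort(as.character(z))
  if (x %in% z || y %in% z)
    stop_input("separating set must not contain the pair")
  cache[[pair_key(x, y)]] <- z
  invisible(cache)
}

#' @rdname sepset_cache
#' @export
sepset_pairs <- function(cache) {
  ks <- ls(cache)
  if (!length(ks)) return(matrix(character(0), ncol = 2,
                                 dimnames = list(NULL, c("x", "y"))))
  m <- do.call(rbind, strsplit(ks, "\r", fixed = TRUE))
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

#' @export
print.sepset_cache <- function(x, ...) {
  cat("sepset cache:", length(ls(x)), "pairs\n")
  invisible(x)
}

# Wrap a tester so every declared independence is recorded in the cache.
cached_test <- function(test, cache) {
  if (is.null(cache)) return(test)
  function(x, y, z = character(0)) {
    r <- test(x, y, z)
    if (r$independent && !sepset_has(cache, x, y))
      sepset_set(cache, x, y, z)
    r
  }
}
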