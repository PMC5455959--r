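# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Read / write tab-separated tables
#'
#' Thin wrappers with the conventions used throughout the package: header
#' line, tab separator, no quoting, no row names.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `readTsv` returns a data.frame.
#' @export
readTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
}

#' @rdname readTsv
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
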