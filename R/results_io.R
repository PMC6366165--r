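#' Tidy results I/O
#'
#' CSV with header, UTF-8, '.' decimal; doubles are written with 17
#' significant digits so a write/read round trip is lossless.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a data frame.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  num <- vapply(table, is.numeric, logical(1))
  if (any(vapply(table[num], function(x) any(!is.finite(x)), logical(1))))
    stop("refusing to write non-finite values", call. = FALSE)
  out <- table
  dbl <- vapply(out, is.double, logical(1))
  out[dbl] <- lapply(out[dbl], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tryCatch(
    suppressWarnings(
      utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
}
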