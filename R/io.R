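#' Write and read observation tables at full precision
#'
#' CSV with a header row, UTF-8, numeric columns formatted with 17
#' significant digits so that values (and per-field provenance columns)
#' round-trip exactly through [read_observations()].
#'
#' @param obs observation table.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  out <- obs
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), NA, format(v, digits = 17, trim = TRUE,
                                scientific = TRUE)))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  na.strings = "")
}
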