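# Minimal loop-format STAR reader/writer. One data block per table;
# columns are written as _name #i; values at full double precision so a
# write/read round trip is lossless to 1e-10 and a re-write is
# byte-identical. Angles are stored in degrees, shifts and coordinates in
# pixels (0-based), defoci in Angstrom.

#' Write a data frame as a loop-format STAR file
#'
#' @param table A data frame.
#' @param path Output path.
#' @param block Data block name (`data_<block>`).
#' @return `path`, invisibly.
#' @export
write_star <- function(table, path, block = "particles") {
  stopifnot(is.data.frame(table))
  con <- file(path, "wb")  # binary mode: fixed LF line endings
  on.exit(close(con))
  out <- c(sprintf("data_%s", block), "", "loop_",
           sprintf("_%s #%d", names(table), seq_along(table)))
  fmt <- function(col) {
    if (is.numeric(col)) formatC(col, format = "g", digits = 15) else
      as.character(col)
  }
  cols <- lapply(table, fmt)
  if (nrow(table) > 0)
    out <- c(out, do.call(paste, c(cols, sep = "  ")))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read a loop-format STAR file
#'
#' Reads one data block (the named one, or the first) and returns its
#' loop as a data frame. Columns that parse fully as numbers become
#' numeric; all other columns stay character. Unknown columns are
#' preserved as-is.
#'
#' @param path Input path.
#' @param block Optional data block name to select.
#' @param required Character vector of required column names.
#' @return A data frame.
#' @export
read_star <- function(path, block = NULL, required = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^data_", lines)
  if (length(starts) == 0) stop_invalid("no data block in %s", path)
  if (!is.null(block)) {
    hit <- which(lines[starts] == sprintf("data_%s", block))
    if (length(hit) == 0)
      stop_invalid("data block '%s' not found in %s", block, path)
    s0 <- starts[hit[1]]
  } else s0 <- starts[1]
  s1 <- c(starts, length(lines) + 1)
  s1 <- min(s1[s1 > s0]) - 1
  chunk <- lines[s0:s1]
  li <- grep("^loop_", chunk)
  if (length(li) == 0) stop_invalid("no loop_ in data block of %s", path)
  rest <- chunk[(li[1] + 1):length(chunk)]
  colidx <- grep("^_", rest)
  cols <- sub("^_([^ #]+).*$", "\\1", rest[colidx])
  body <- rest[setdiff(seq_along(rest), colidx)]
  body <- trimws(body)
  body <- body[nzchar(body) & !grepl("^#", body)]
  if (!is.null(required)) {
    miss <- setdiff(required, cols)
    if (length(miss) > 0)
      stop_invalid("missing required STAR column(s): %s",
                   paste(miss, collapse = ", "))
  }
  if (length(body) == 0) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  fields <- strsplit(body, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != length(cols)))
    stop_invalid("malformed STAR row: expected %d fields, found %d",
                 length(cols), nf[which(nf != length(cols))[1]])
  m <- do.call(rbind, fields)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in seq_along(df)) {
    suppressWarnings(num <- as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
    else if (all(df[[j]] %in% c("TRUE", "FALSE")))
      df[[j]] <- as.logical(df[[j]])
  }
  df
}
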