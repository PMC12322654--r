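#' Read a (multi-frame) XYZ trajectory
#'
#' Parses the standard XYZ format: an atom-count line, a comment line,
#' then one `symbol x y z` line per atom, with frames concatenated.
#' Coordinates are in Angstrom.
#'
#' @param path file path
#' @return list of frames; each frame is a list with `symbols`
#'   (character), `coords` (n x 3 numeric matrix, Angstrom), `comment`,
#'   and `frame_index` (1-based file order). An empty file yields an
#'   empty list with a warning.
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L) {
    warning("empty XYZ file: ", path)
    return(list())
  }
  frames <- list()
  i <- 1L
  fi <- 0L
  while (i <= length(lines)) {
    fi <- fi + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("frame ", fi, ": malformed atom-count line ", sQuote(lines[i]))
    if (i + 1L + n > length(lines))
      stop("frame ", fi, ": truncated (expected ", n, " atom lines)")
    comment <- lines[i + 1L]
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    if (any(vapply(toks, length, 1L) < 4L))
      stop("frame ", fi, ": atom line with fewer than 4 fields")
    symbols <- vapply(toks, `[[`, "", 1L)
    coords <- matrix(suppressWarnings(
      as.numeric(vapply(toks, function(x) x[2:4], character(3)))),
      ncol = 3L, byrow = TRUE)
    if (any(!is.finite(coords)))
      stop("frame ", fi, ": non-numeric or non-finite coordinate")
    frames[[fi]] <- list(symbols = symbols, coords = coords,
                         comment = comment, frame_index = fi)
    i <- i + 2L + n
  }
  frames
}

#' Write frames to a multi-frame XYZ file
#'
#' @param frames list of frames as returned by [read_xyz_trajectory()]
#'   (or a single frame)
#' @param path output file path
#' @param digits coordinate decimals (default 8)
#' @export
write_xyz_trajectory <- function(frames, path, digits = 8) {
  if (!is.null(frames$coords)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%-3s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (fr in frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(if (is.null(fr$comment)) "" else fr$comment, con)
    writeLines(sprintf(fmt, fr$symbols, fr$coords[, 1], fr$coords[, 2],
                       fr$coords[, 3]), con)
  }
  invisible(path)
}
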