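#' Read a nucleotide frequency matrix file
#'
#' Parses TRANSFAC-like matrices (a `P0`/`PO` header line with A C G T
#' columns followed by numbered position rows, terminated by `//`) and
#' JASPAR PFM files (optional `>name` header, then four rows in A/C/G/T
#' order, with or without the `A [ ... ]` bracket dialect). Values may be
#' counts or relative frequencies; counts are normalized per position.
#'
#' @param path matrix file.
#' @param format `"auto"` (detect TRANSFAC by its P0 header), `"transfac"`
#'   or `"jaspar"`. Whether values are counts or frequencies is immaterial:
#'   rows are always renormalized.
#' @param name matrix identifier; defaults to an ID found in the file, else
#'   the file name.
#' @param ... passed to [pwm()] (e.g. `civ_min`).
#' @return an `ci_pwm` object.
#' @export
read_pwm <- function(path, format = c("auto", "transfac", "jaspar"),
                     name = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (!length(lines[nzchar(lines)])) stop("empty matrix file: ", path)
  if (format == "auto") {
    format <- if (any(grepl("^P[0O]\\b", lines))) "transfac" else "jaspar"
  }
  parsed <- switch(format,
    transfac = parse_transfac(lines, path),
    jaspar = parse_jaspar(lines, path)
  )
  pwm(parsed$mat, name = name %||% parsed$name %||% basename(path), ...)
}

parse_transfac <- function(lines, path) {
  hdr <- grep("^P[0O]\\b", lines)
  if (!length(hdr)) stop("no P0 header line in TRANSFAC matrix: ", path)
  hdr <- hdr[1L]
  cols <- strsplit(lines[hdr], "\\s+")[[1L]][-1L]
  base_order <- match(DNA_BASES, toupper(substr(cols, 1L, 1L)))
  if (anyNA(base_order[1:4]))
    stop("TRANSFAC header must list A C G T columns (line ", hdr, "): ", path)
  id_line <- grep("^(ID|NA)\\s", lines, value = TRUE)
  nm <- if (length(id_line))
    sub("^(ID|NA)\\s+", "", id_line[1L]) else NULL

  rows <- list()
  for (i in seq(hdr + 1L, length(lines))) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (grepl("^//", ln) || grepl("^XX", ln)) break
    if (!grepl("^[0-9]+\\s", ln)) break
    f <- strsplit(ln, "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(f[2:5]))
    if (anyNA(vals))
      stop("malformed TRANSFAC matrix row at line ", i, ": '", ln, "'")
    rows[[length(rows) + 1L]] <- vals[base_order]
  }
  if (!length(rows)) stop("no position rows found in TRANSFAC matrix: ", path)
  list(mat = do.call(rbind, rows), name = nm)
}

parse_jaspar <- function(lines, path) {
  nm <- NULL
  if (grepl("^>", lines[1L])) {
    nm <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 4L)
    stop("JASPAR matrix needs 4 base rows; found ", length(lines), ": ", path)
  rows <- lapply(lines[1:4], function(ln) {
    ln2 <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", ln)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln2), "\\s+")[[1L]]))
    if (anyNA(vals) || !length(vals))
      stop("malformed JASPAR matrix row: '", ln, "' in ", path)
    vals
  })
  # explicit base labels may appear in any order
  labs <- toupper(substr(lines[1:4], 1L, 1L))
  if (all(labs %in% DNA_BASES) && !anyNA(match(DNA_BASES, labs))) {
    rows <- rows[match(DNA_BASES, labs)]
  }
  if (length(unique(lengths(rows))) != 1L)
    stop("JASPAR base rows have differing lengths in ", path)
  list(mat = t(do.call(rbind, rows)), name = nm)
}

#' Write a PWM in TRANSFAC-like format
#'
#' @param pwm an `ci_pwm`.
#' @param path output file.
#' @param digits decimal places for frequencies.
#' @export
write_pwm <- function(pwm, path, digits = 4L) {
  stopifnot(inherits(pwm, "ci_pwm"))
  rows <- apply(pwm$freq, 1L, function(f)
    paste(formatC(f, digits = digits, format = "f"), collapse = "\t"))
  full_cons <- paste(DNA_BASES[max.col(pwm$freq, ties.method = "first")],
                     collapse = "")
  lines <- c(paste("NA", pwm$name),
             "P0\tA\tC\tG\tT",
             sprintf("%02d\t%s\t%s", seq_len(nrow(pwm$freq)), rows,
                     strsplit(full_cons, "")[[1L]]),
             "//")
  writeLines(lines, path)
  invisible(path)
}
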