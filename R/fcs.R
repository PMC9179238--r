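#' Write an event matrix to an FCS 3.1 file
#'
#' Minimal list-mode FCS 3.1 writer. Values are stored as doubles
#' (`$DATATYPE D`) so the round trip is exact to numerical precision.
#' Truth labels, if present, are written to a `*_truth.csv` sidecar
#' (`event_index`, `label`) and never into the FCS itself.
#'
#' @param events Event matrix tibble (channels in columns; optional
#'   `.label` column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  chans <- event_channels(events)
  n <- nrow(events)
  p <- length(chans)
  if (n == 0 || p == 0) abort("cannot write an empty event matrix")
  dat <- as.matrix(events[chans])
  if (any(!is.finite(dat))) abort("event values must be finite")

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "D", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$TOT" = as.character(n), "$PAR" = as.character(p)
  )
  for (i in seq_len(p)) {
    kw[sprintf("$P%dN", i)] <- gsub("/", "_", chans[i])
    kw[sprintf("$P%dB", i)] <- "64"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(ceiling(max(dat[, i], 1)),
                                      scientific = FALSE)
  }
  # fixed-width data offsets so TEXT length is stable while we fill them in
  kw["$BEGINDATA"] <- "0000000000"
  kw["$ENDDATA"] <- "0000000000"

  build_text <- function(kw) {
    paste0("/", paste0(names(kw), "/", unname(kw), "/", collapse = ""))
  }
  text_start <- 256L
  txt <- build_text(kw)
  data_start <- text_start + nchar(txt, type = "bytes")
  data_end <- data_start + 8L * n * p - 1L
  kw["$BEGINDATA"] <- sprintf("%010d", data_start)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  txt <- build_text(kw)
  text_end <- text_start + nchar(txt, type = "bytes") - 1L

  hdr_off <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ",
                   hdr_off(text_start), hdr_off(text_end),
                   if (data_end <= 99999999) {
                     paste0(hdr_off(data_start), hdr_off(data_end))
                   } else {
                     paste0(hdr_off(0), hdr_off(0))
                   },
                   hdr_off(0), hdr_off(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(strrep(" ", text_start - nchar(header)), con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.vector(t(dat)), con, size = 8, endian = "little")

  if (".label" %in% names(events)) {
    side <- fcs_sidecar_path(path)
    readr::write_csv(tibble::tibble(event_index = seq_len(n),
                                    label = events$.label), side,
                     progress = FALSE)
  }
  invisible(path)
}

fcs_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_truth.csv")
}

#' Read an FCS file written by [write_fcs()]
#'
#' Supports list-mode FCS 3.0/3.1 with `$DATATYPE` D or F. If a
#' `*_truth.csv` sidecar is found next to the file, labels are re-attached
#' by event index.
#'
#' @param path FCS file path.
#' @param attach_truth Re-attach sidecar labels when available.
#' @return An event matrix tibble.
#' @export
read_fcs <- function(path, attach_truth = TRUE) {
  size <- file.info(path)$size
  if (is.na(size) || size < 58) {
    abort(sprintf("unreadable FCS file (size %s bytes): %s",
                  size %na% "NA", path))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (!grepl("^FCS3", header)) abort("not an FCS 3.x file")
  offs <- suppressWarnings(as.integer(substring(header,
                                                seq(11, 51, by = 8),
                                                seq(18, 58, by = 8))))
  text_start <- offs[1]; text_end <- offs[2]
  if (is.na(text_start) || is.na(text_end) || text_end > size) {
    abort(sprintf("truncated FCS file: TEXT segment ends at byte %s but file has %d bytes",
                  text_end %na% "NA", size))
  }
  seek(con, text_start)
  txt <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  kw <- setNames(vals, keys)

  n <- as.integer(kw["$TOT"])
  p <- as.integer(kw["$PAR"])
  type <- kw["$DATATYPE"]
  bytes <- if (identical(unname(type), "D")) 8L else 4L
  endian <- if (grepl("^1", kw["$BYTEORD"])) "little" else "big"
  data_start <- as.integer(kw["$BEGINDATA"])
  if (is.na(data_start) || data_start == 0) data_start <- offs[3]
  data_end <- as.integer(kw["$ENDDATA"])
  if (is.na(data_end) || data_end == 0) data_end <- offs[4]
  need <- as.numeric(n) * p * bytes
  if (is.na(data_end) || data_end + 1 - data_start < need ||
      data_end > size) {
    abort(sprintf(
      "truncated FCS file: need %d data bytes at offset %d but file has %d bytes",
      need, data_start, size))
  }
  seek(con, data_start)
  vec <- readBin(con, "numeric", n = n * p, size = bytes, endian = endian)
  m <- matrix(vec, nrow = n, ncol = p, byrow = TRUE)
  chans <- vapply(seq_len(p), function(i) kw[[sprintf("$P%dN", i)]], "")
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- chans

  side <- fcs_sidecar_path(path)
  if (attach_truth && file.exists(side)) {
    truth <- readr::read_csv(side, show_col_types = FALSE, progress = FALSE)
    out$.label <- truth$label[match(seq_len(n), truth$event_index)]
  }
  attr(out, "sample_id") <- tools::file_path_sans_ext(basename(path))
  attr(out, "transformed") <- FALSE
  class(out) <- c("event_matrix", class(out))
  out
}
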