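#' Write a singles stream to a list-mode file
#'
#' Two equivalent on-disk layouts are supported. The text format is
#' tab-separated with one record per single (columns `time_ps`, `block_id`,
#' `photon_kind`, `energy_kev`, `decay_id`) preceded by `#`-prefixed header
#' lines carrying the acquisition metadata. The binary format stores the
#' same records fixed-width little-endian: time_ps as unsigned 64-bit,
#' block_id and energy_kev as unsigned 16-bit, photon_kind as unsigned
#' 8-bit and decay_id as signed 64-bit (-1 when ground truth is absent).
#'
#' @param stream a `singles_stream`.
#' @param path output file path.
#' @param format `"text"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_listmode <- function(stream, path, format = c("text", "binary")) {
  format <- match.arg(format)
  validate_singles_stream(stream)
  iso <- stream$isotope
  det <- stream$detector
  hdr <- c(
    "petrand-listmode v1",
    sprintf("duration_ps=%.0f", stream$duration_ps),
    sprintf("activity_bq=%.10g", stream$activity_bq),
    sprintf("seed=%s", ifelse(is.na(stream$seed), "NA", stream$seed)),
    sprintf("isotope=%s", iso$name),
    sprintf("eps1=%.10g", iso$eps1),
    sprintf("eps2=%.10g", iso$eps2),
    sprintf("eps_gamma=%.10g", iso$eps_gamma),
    sprintf("n_blocks=%d", det$n_blocks),
    sprintf("ctr_fwhm_ps=%.10g", det$ctr_fwhm_ps),
    sprintf("dead_time_ps=%.10g", det$dead_time_ps),
    sprintf("n_records=%d", nrow(stream$events))
  )
  ev <- stream$events
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    if (nrow(ev)) {
      recs <- sprintf("%.0f\t%d\t%d\t%.0f\t%.0f", ev$time_ps, ev$block_id,
                      ev$kind, ev$energy_kev, ev$decay_id)
      writeLines(recs, con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hblob <- charToRaw(paste(hdr, collapse = "\n"))
    writeBin(c("PETRANDLM"), con)
    writeBin(length(hblob), con, size = 4L, endian = "little")
    writeBin(hblob, con)
    if (nrow(ev)) {
      .write_u64(con, ev$time_ps)
      writeBin(as.integer(ev$block_id), con, size = 2L, endian = "little")
      writeBin(as.integer(ev$kind), con, size = 1L)
      writeBin(as.integer(ev$energy_kev), con, size = 2L, endian = "little")
      .write_u64(con, ifelse(ev$decay_id < 0, 2^64 + ev$decay_id, ev$decay_id))
    }
  }
  invisible(path)
}

# little-endian u64 written as two u32 words; exact for values < 2^53
.write_u64 <- function(con, x) {
  lo <- x %% 2^32
  hi <- (x - lo) / 2^32
  m <- rbind(.as_u32(lo), .as_u32(hi))
  writeBin(as.vector(m), con, size = 4L, endian = "little")
}

.as_u32 <- function(x) as.integer(ifelse(x >= 2^31, x - 2^32, x))

.from_u32 <- function(x) ifelse(x < 0, x + 2^32, as.numeric(x))

#' Read a list-mode file
#'
#' Inverse of [write_listmode()]; the round trip reproduces all event
#' fields and acquisition metadata bit-exactly. Records must be sorted by
#' timestamp; a file with decreasing timestamps is rejected.
#'
#' @param path file path (text or binary layout, auto-detected).
#' @return A `singles_stream`.
#' @export
read_listmode <- function(path) {
  con <- file(path, "rb")
  magic <- tryCatch(readBin(con, "raw", 9L), error = function(e) raw(0))
  close(con)
  if (length(magic) == 9L && rawToChar(magic) == "PETRANDLM")
    .read_listmode_binary(path)
  else
    .read_listmode_text(path)
}

.parse_header <- function(lines) {
  kv <- strsplit(lines[grepl("=", lines, fixed = TRUE)], "=", fixed = TRUE)
  vals <- vapply(kv, `[`, "", 2L)
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

.stream_from_parts <- function(h, ev, path) {
  if (nrow(ev) && is.unsorted(ev$time_ps))
    stop("list-mode records in ", path, " are not sorted by time_ps")
  iso <- isotope_model(unname(h["isotope"]),
                       eps1 = as.numeric(h["eps1"]),
                       eps2 = as.numeric(h["eps2"]),
                       eps_gamma = as.numeric(h["eps_gamma"]))
  det <- detector_model(n_blocks = as.integer(h["n_blocks"]),
                        ctr_fwhm_ps = as.numeric(h["ctr_fwhm_ps"]),
                        dead_time_ps = as.numeric(h["dead_time_ps"]))
  new_singles_stream(ev,
                     duration_ps = as.numeric(h["duration_ps"]),
                     activity_bq = as.numeric(h["activity_bq"]),
                     isotope = iso, detector = det,
                     seed = if (h["seed"] == "NA") NULL else as.integer(h["seed"]))
}

.read_listmode_text <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  h <- .parse_header(sub("^#\\s*", "", lines[is_hdr]))
  body <- lines[!is_hdr & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 5L)
    if (length(bad))
      stop("malformed list-mode record at line ",
           which(!is_hdr & nzchar(lines))[bad[1L]], " of ", path)
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 5L, byrow = TRUE)
    if (anyNA(m))
      stop("non-numeric field in list-mode record of ", path)
    ev <- data.frame(time_ps = m[, 1L], decay_id = m[, 5L],
                     kind = as.integer(m[, 3L]),
                     block_id = as.integer(m[, 2L]),
                     energy_kev = m[, 4L])
  } else {
    ev <- data.frame(time_ps = numeric(), decay_id = numeric(),
                     kind = integer(), block_id = integer(),
                     energy_kev = numeric())
  }
  .stream_from_parts(h, ev, path)
}

.read_listmode_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "character")  # magic
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  h <- .parse_header(strsplit(rawToChar(readBin(con, "raw", hlen)), "\n")[[1L]])
  n <- as.integer(h["n_records"])
  if (is.na(n)) stop("binary list-mode header of ", path, " lacks n_records")
  rd_u64 <- function(k) {
    w <- readBin(con, "integer", 2L * k, size = 4L, endian = "little")
    .from_u32(w[c(TRUE, FALSE)]) + .from_u32(w[c(FALSE, TRUE)]) * 2^32
  }
  if (n > 0L) {
    time_ps <- rd_u64(n)
    block <- readBin(con, "integer", n, size = 2L, endian = "little", signed = FALSE)
    kind <- readBin(con, "integer", n, size = 1L, signed = FALSE)
    energy <- readBin(con, "integer", n, size = 2L, endian = "little", signed = FALSE)
    decay <- rd_u64(n)
    decay <- ifelse(decay > 2^63, decay - 2^64, decay)
    ev <- data.frame(time_ps = time_ps, decay_id = decay,
                     kind = as.integer(kind), block_id = as.integer(block),
                     energy_kev = as.numeric(energy))
  } else {
    ev <- data.frame(time_ps = numeric(), decay_id = numeric(),
                     kind = integer(), block_id = integer(),
                     energy_kev = numeric())
  }
  .stream_from_parts(h, ev, path)
}
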