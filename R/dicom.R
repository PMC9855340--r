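# Minimal DICOM reader, explicit-VR little-endian only, scoped to what an
# RT Plan brachy module needs (element stream, defined- and undefined-length
# sequences, string/number VRs). Written in-package because no DICOM reader
# is among the package's dependencies; it is a file-format parser, not a
# dosimetry component.

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_RTPLAN_SOP <- "1.2.840.10008.5.1.4.1.1.481.5"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
.dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                     "PN", "SH", "ST", "TM", "UC", "UI", "UR", "UT")

dcm_tag <- function(group, elem) sprintf("%04X%04X", group, elem)

.u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
.u32 <- function(raw, pos) {
  # as double: lengths can exceed .Machine$integer range in theory
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

.dcm_decode_value <- function(vr, bytes) {
  if (vr %in% .dcm_string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    s <- sub("[ ]+$", "", s)
    if (vr %in% c("DS", "IS")) {
      if (!nzchar(s)) return(numeric(0))
      return(as.numeric(trimws(strsplit(s, "\\\\")[[1]])))
    }
    return(s)
  }
  switch(vr,
    US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    SS = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = TRUE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    SL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FL = readBin(bytes, "numeric", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FD = readBin(bytes, "numeric", n = length(bytes) / 8, size = 8,
                 endian = "little"),
    bytes)  # unknown/other VR: keep raw
}

# Parses one dataset (sequence of elements) from raw, starting at pos
# (1-based), stopping at 'end' or at an item-delimitation tag. Returns
# list(data = named list by "GGGGEEEE", pos = next position).
.dcm_parse_dataset <- function(raw, pos, end) {
  out <- list()
  while (pos <= end) {
    if (pos + 7L > length(raw) + 1L) break
    group <- .u16(raw, pos); elem <- .u16(raw, pos + 2L)
    if (group == 0xFFFEL && elem == 0xE00DL) {  # item delimitation
      pos <- pos + 8L
      return(list(data = out, pos = pos, delimited = TRUE))
    }
    if (group == 0xFFFEL && elem == 0xE0DDL) {  # sequence delimitation
      return(list(data = out, pos = pos, delimited = FALSE))
    }
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      bc_format_error(sprintf(
        "not an explicit-VR little-endian DICOM element at byte %d (VR '%s')",
        pos, vr))
    if (vr %in% .dcm_long_vrs) {
      len <- .u32(raw, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- .u16(raw, pos + 6L)
      pos <- pos + 8L
    }
    tag <- dcm_tag(group, elem)
    if (vr == "SQ") {
      sq_end <- if (len == 4294967295) length(raw) else pos + len - 1L
      items <- list()
      while (pos <= sq_end) {
        ig <- .u16(raw, pos); ie <- .u16(raw, pos + 2L)
        if (ig == 0xFFFEL && ie == 0xE0DDL) { pos <- pos + 8L; break }
        if (!(ig == 0xFFFEL && ie == 0xE000L))
          bc_format_error(sprintf("malformed sequence %s: expected item tag", tag))
        ilen <- .u32(raw, pos + 4L)
        pos <- pos + 8L
        item_end <- if (ilen == 4294967295) length(raw) else pos + ilen - 1L
        parsed <- .dcm_parse_dataset(raw, pos, item_end)
        items[[length(items) + 1L]] <- parsed$data
        pos <- parsed$pos
      }
      out[[tag]] <- items
    } else {
      bytes <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
      out[[tag]] <- .dcm_decode_value(vr, bytes)
    }
  }
  list(data = out, pos = pos, delimited = FALSE)
}

# Reads a DICOM Part-10 file into a flat named list of elements
# (tag "GGGGEEEE" -> decoded value; SQ -> list of item datasets).
read_dicom <- function(path) {
  if (!file.exists(path)) bc_format_error(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    bc_format_error(sprintf("'%s' is not a DICOM Part-10 file (no DICM magic)", path))
  parsed <- .dcm_parse_dataset(raw, 133L, length(raw))
  ds <- parsed$data
  ts <- ds[["00020010"]]
  if (!is.null(ts) && !identical(ts, DCM_EXPLICIT_LE))
    bc_format_error(sprintf(
      "unsupported transfer syntax '%s' (only explicit VR little endian is supported)", ts))
  ds
}

dcm_get <- function(ds, tag, default = NULL) {
  v <- ds[[tag]]
  if (is.null(v) || (is.character(v) && length(v) == 1L && !nzchar(v))) default else v
}

dcm_date <- function(s) {
  # DICOM DA: YYYYMMDD
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.Date(s, format = "%Y%m%d")
}
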