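# Minimal DICOM codec: explicit VR little endian only, the transfer syntax
# this package both writes (synthetic RT objects) and reads. No general DICOM
# toolkit is available in this R stack, so the subset needed for RTPLAN /
# RTSTRUCT / RTDOSE is implemented here. Datasets are represented as named
# lists keyed by lowercase 8-hex-digit tags ("ggggeeee"); sequence (SQ)
# values are lists of such datasets.

DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs using the 4-byte length form (2-byte VR + 2 reserved + uint32 length)
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH",
                     "ST", "TM", "UI")

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.read_u16 <- function(bytes, at) {
  readBin(bytes[at:(at + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
.read_u32 <- function(bytes, at) {
  v <- readBin(bytes[at:(at + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

dcm_tag <- function(group, element) sprintf("%04x%04x", group, element)

## ---- writer ---------------------------------------------------------------

# Encode one data element; `value` type depends on vr.
dcm_element <- function(group, element, vr, value) {
  body <- switch(vr,
    DS = charToRaw(paste(vapply(value, function(v) sprintf("%.10g", v),
                                character(1)), collapse = "\\")),
    IS = charToRaw(paste(format(as.integer(value), trim = TRUE,
                                scientific = FALSE), collapse = "\\")),
    US = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
    SQ = {
      items <- lapply(value, function(item) {
        content <- do.call(c, c(list(raw(0)), unname(item)))
        c(.u16(0xFFFE), .u16(0xE000), .u32(length(content)), content)
      })
      do.call(c, c(list(raw(0)), items))
    },
    OW = ,
    OB = value,
    {
      if (!vr %in% .dcm_string_vrs)
        stop("unsupported VR for writing: ", vr)
      charToRaw(paste(value, collapse = "\\"))
    }
  )
  if (length(body) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    body <- c(body, pad)
  }
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    head <- c(head, as.raw(c(0L, 0L)), .u32(length(body)))
  } else {
    head <- c(head, .u16(length(body)))
  }
  c(head, body)
}

# Items for SQ elements: a list of already-encoded element raw vectors,
# supplied in ascending tag order by the caller.
dcm_item <- function(...) list(...)

# Write a DICOM Part-10 file: preamble, "DICM", file-meta group, dataset.
# `elements` is a list of encoded element raw vectors in ascending tag order.
dcm_write_file <- function(path, sop_class_uid, sop_instance_uid, elements) {
  meta_body <- c(
    dcm_element(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_element(0x0002, 0x0010, "UI", DCM_TS_EXPLICIT_LE)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)
  dataset <- do.call(c, c(list(raw(0)), elements))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

## ---- reader ---------------------------------------------------------------

.dcm_decode_value <- function(vr, body) {
  switch(vr,
    DS = ,
    FD = ,
    FL = {
      s <- trimws(rawToChar(body))
      if (!nzchar(s)) numeric(0) else as.numeric(strsplit(s, "\\\\")[[1]])
    },
    IS = {
      s <- trimws(rawToChar(body))
      if (!nzchar(s)) integer(0) else as.integer(strsplit(s, "\\\\")[[1]])
    },
    US = readBin(body, "integer", n = length(body) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    UL = readBin(body, "integer", n = length(body) / 4L, size = 4L,
                 endian = "little"),
    OB = ,
    OW = body,
    {
      s <- rawToChar(body[body != as.raw(0L)])
      sub("[ ]+$", "", s)
    }
  )
}

# Parse a dataset between byte offsets [at, end]; returns list(ds, at).
.dcm_parse_dataset <- function(bytes, at, end, stop_tag = NULL) {
  ds <- list()
  while (at <= end) {
    group <- .read_u16(bytes, at)
    element <- .read_u16(bytes, at + 2L)
    if (!is.null(stop_tag) && group == 0xFFFE && element == stop_tag) {
      at <- at + 8L  # delimiter has a 4-byte (zero) length
      return(list(ds = ds, at = at, delimited = TRUE))
    }
    vr <- rawToChar(bytes[(at + 4L):(at + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("not explicit-VR little-endian DICOM (tag ",
           dcm_tag(group, element), ")")
    if (vr %in% .dcm_long_vrs) {
      len <- .read_u32(bytes, at + 8L)
      at <- at + 12L
    } else {
      len <- .read_u16(bytes, at + 6L)
      at <- at + 8L
    }
    tag <- dcm_tag(group, element)
    if (vr == "SQ") {
      parsed <- .dcm_parse_sequence(bytes, at, len)
      ds[[tag]] <- parsed$items
      at <- parsed$at
    } else if (len == 4294967295) {
      stop("undefined length only supported for SQ (tag ", tag, ")")
    } else {
      body <- if (len > 0L) bytes[at:(at + len - 1L)] else raw(0)
      ds[[tag]] <- .dcm_decode_value(vr, body)
      at <- at + len
    }
  }
  list(ds = ds, at = at, delimited = FALSE)
}

.dcm_parse_sequence <- function(bytes, at, len) {
  undefined <- len == 4294967295
  seq_end <- if (undefined) length(bytes) else at + len - 1L
  items <- list()
  while (at <= seq_end) {
    group <- .read_u16(bytes, at)
    element <- .read_u16(bytes, at + 2L)
    if (group != 0xFFFE)
      stop("malformed sequence: expected item tag, got ",
           dcm_tag(group, element))
    if (element == 0xE0DD) {  # sequence delimiter
      at <- at + 8L
      break
    }
    if (element != 0xE000) stop("malformed sequence item")
    item_len <- .read_u32(bytes, at + 4L)
    at <- at + 8L
    if (item_len == 4294967295) {
      parsed <- .dcm_parse_dataset(bytes, at, seq_end, stop_tag = 0xE00D)
      items[[length(items) + 1L]] <- parsed$ds
      at <- parsed$at
    } else {
      parsed <- .dcm_parse_dataset(bytes, at, at + item_len - 1L)
      items[[length(items) + 1L]] <- parsed$ds
      at <- at + item_len
    }
    if (!undefined && at > seq_end) break
  }
  list(items = items, at = at)
}

# Read a Part-10 DICOM file into a tag-keyed dataset list.
dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  meta_end <- 132L
  # parse file meta (group 0002) to find transfer syntax, then the dataset
  at <- 133L
  meta <- list()
  while (at <= length(bytes)) {
    group <- .read_u16(bytes, at)
    if (group != 0x0002) break
    parsed1 <- .dcm_parse_dataset(bytes, at, at)  # parse exactly one element
    meta <- c(meta, parsed1$ds)
    at <- parsed1$at
  }
  ts <- meta[["00020010"]]
  if (!is.null(ts) && ts != DCM_TS_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  .dcm_parse_dataset(bytes, at, length(bytes))$ds
}

dcm_get <- function(ds, tag, default = NULL) {
  v <- ds[[tag]]
  if (is.null(v)) default else v
}

dcm_require <- function(ds, tag, what) {
  v <- ds[[tag]]
  if (is.null(v)) stop("required DICOM element missing: ", what,
                       " (", tag, ")")
  v
}
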