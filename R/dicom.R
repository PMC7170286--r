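# Minimal DICOM reader/writer, explicit VR little endian only.
#
# Scope: the RT Plan / RT Dose / RT Structure Set subsets this package emits
# and consumes. A dataset is an ordered named list keyed by 8-hex-digit tag
# ("GGGGEEEE"); each element is list(vr = <2-char VR>, value = ...). SQ values
# are lists of item datasets. All multi-valued string VRs are character
# vectors; DS/IS are numeric/integer on read and formatted on write.

DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"

# VRs using the 4-byte length form (2 reserved bytes + uint32)
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                     "PN", "SH", "ST", "TM", "UI", "UC", "UR")

#' Build one DICOM data element
#'
#' @param vr Two-letter DICOM value representation, e.g. `"DS"`.
#' @param value Element value: character vector for string VRs, numeric for
#'   binary VRs, a list of item datasets for `"SQ"`, or a raw vector for
#'   `"OB"`/`"OW"`.
#' @return A list with components `vr` and `value`.
#' @keywords internal
dcm_el <- function(vr, value) list(vr = vr, value = value)

dcm_tag <- function(group, element) sprintf("%04X%04X", group, element)

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.dcm_format_number <- function(x) {
  # DS: <= 16 bytes per value; %.8g keeps micrometre precision for plan geometry
  s <- vapply(x, function(v) {
    if (is.na(v)) "" else sub("e([+-])0(\\d)$", "e\\1\\2", sprintf("%.8g", v))
  }, character(1))
  s
}

.dcm_value_bytes <- function(vr, value) {
  if (vr %in% .dcm_string_vrs) {
    if (vr == "DS") value <- .dcm_format_number(as.numeric(value))
    if (vr == "IS") value <- sprintf("%d", as.integer(value))
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(enc2utf8(s))
    if (length(b) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      b <- c(b, pad)
    }
    b
  } else if (vr == "US") {
    writeBin(as.integer(value), raw(), size = 2L, endian = "little")
  } else if (vr == "UL") {
    writeBin(as.integer(value), raw(), size = 4L, endian = "little")
  } else if (vr == "FL") {
    writeBin(as.numeric(value), raw(), size = 4L, endian = "little")
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8L, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    b <- as.raw(value)
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0L))
    b
  } else if (vr == "SQ") {
    items <- lapply(value, function(item) {
      content <- .dcm_dataset_bytes(item)
      c(.u16(0xFFFE), .u16(0xE000), .u32(length(content)), content)
    })
    do.call(c, c(items, list(raw(0))))
  } else {
    stop("unsupported VR for writing: ", vr, call. = FALSE)
  }
}

.dcm_element_bytes <- function(tag, el) {
  grp <- strtoi(substr(tag, 1L, 4L), 16L)
  ele <- strtoi(substr(tag, 5L, 8L), 16L)
  body <- .dcm_value_bytes(el$vr, el$value)
  head <- c(.u16(grp), .u16(ele), charToRaw(el$vr))
  if (el$vr %in% .dcm_long_vrs) {
    c(head, as.raw(c(0L, 0L)), .u32(length(body)), body)
  } else {
    if (length(body) > 65534L) stop("element ", tag, " too long for short VR form")
    c(head, .u16(length(body)), body)
  }
}

.dcm_dataset_bytes <- function(ds) {
  tags <- names(ds)
  tags <- tags[order(tags)]
  parts <- lapply(tags, function(tg) .dcm_element_bytes(tg, ds[[tg]]))
  do.call(c, c(parts, list(raw(0))))
}

#' Write a DICOM Part-10 file (explicit VR little endian)
#'
#' @param ds Dataset: ordered named list of elements keyed by `"GGGGEEEE"`
#'   tags, as built by [dcm_el()].
#' @param path Output file path.
#' @param sop_class,sop_instance UIDs for the file-meta group; defaulted from
#'   the dataset's `(0008,0016)`/`(0008,0018)` elements.
#' @return `path`, invisibly.
#' @export
dcm_write <- function(ds, path, sop_class = NULL, sop_instance = NULL) {
  sop_class <- sop_class %||% ds[["00080016"]]$value
  sop_instance <- sop_instance %||% ds[["00080018"]]$value
  meta <- list(
    "00020001" = dcm_el("OB", as.raw(c(0L, 1L))),
    "00020002" = dcm_el("UI", sop_class),
    "00020003" = dcm_el("UI", sop_instance),
    "00020010" = dcm_el("UI", DCM_TS_EXPLICIT_LE)
  )
  meta_bytes <- .dcm_dataset_bytes(meta)
  group_len <- .dcm_element_bytes("00020000", dcm_el("UL", length(meta_bytes)))
  body <- .dcm_dataset_bytes(ds)
  out <- c(raw(128L), charToRaw("DICM"), group_len, meta_bytes, body)
  writeBin(out, path)
  invisible(path)
}

.dcm_parse_value <- function(vr, bytes) {
  if (vr %in% .dcm_string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0L)])
    Encoding(s) <- "UTF-8"
    s <- sub("[ ]+$", "", s)
    vals <- if (nzchar(s)) strsplit(s, "\\", fixed = TRUE)[[1]] else character(0)
    vals <- sub("^ +| +$", "", vals)
    if (vr == "DS") return(as.numeric(vals))
    if (vr == "IS") return(as.integer(vals))
    return(vals)
  }
  switch(vr,
    US = readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                 endian = "little", signed = FALSE),
    UL = readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    FL = readBin(bytes, "numeric", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    FD = readBin(bytes, "numeric", n = length(bytes) / 8L, size = 8L,
                 endian = "little"),
    OB = bytes, OW = bytes, UN = bytes,
    stop("unsupported VR for reading: ", vr, call. = FALSE)
  )
}

.rd_u16 <- function(b, i) {
  as.integer(b[i]) + 256L * as.integer(b[i + 1L])
}
.rd_u32 <- function(b, i) {
  as.integer(b[i]) + 256 * as.integer(b[i + 1L]) +
    65536 * as.integer(b[i + 2L]) + 16777216 * as.integer(b[i + 3L])
}

# Parse explicit-VR elements in b[start..end]; returns list(ds=, pos=).
# stop_at_delim: stop (consuming the delimiter) on an item/sequence delimiter.
.dcm_parse_elements <- function(b, start, end, stop_at_delim = FALSE) {
  ds <- list()
  i <- start
  while (i <= end) {
    grp <- .rd_u16(b, i); ele <- .rd_u16(b, i + 2L)
    if (grp == 0xFFFE) {
      # delimitation items inside undefined-length constructs
      i <- i + 8L
      if (stop_at_delim && ele %in% c(0xE00D, 0xE0DD)) break
      next
    }
    vr <- rawToChar(b[(i + 4L):(i + 5L)])
    if (vr %in% .dcm_long_vrs) {
      len <- .rd_u32(b, i + 8L)
      i <- i + 12L
    } else {
      len <- .rd_u16(b, i + 6L)
      i <- i + 8L
    }
    tag <- dcm_tag(grp, ele)
    if (vr == "SQ") {
      undef <- len == 4294967295
      sq_end <- if (undef) end else i + len - 1L
      items <- list()
      while (i <= sq_end) {
        igrp <- .rd_u16(b, i); iele <- .rd_u16(b, i + 2L)
        ilen <- .rd_u32(b, i + 4L)
        i <- i + 8L
        if (igrp == 0xFFFE && iele == 0xE0DD) break
        if (!(igrp == 0xFFFE && iele == 0xE000)) {
          stop("malformed sequence item at offset ", i - 8L, call. = FALSE)
        }
        if (ilen == 4294967295) {
          parsed <- .dcm_parse_elements(b, i, sq_end, stop_at_delim = TRUE)
        } else {
          parsed <- .dcm_parse_elements(b, i, i + ilen - 1L)
        }
        items[[length(items) + 1L]] <- parsed$ds
        i <- parsed$pos
      }
      ds[[tag]] <- dcm_el("SQ", items)
    } else {
      val <- if (len > 0L) .dcm_parse_value(vr, b[i:(i + len - 1L)]) else
        .dcm_parse_value(vr, raw(0))
      ds[[tag]] <- dcm_el(vr, val)
      i <- i + len
    }
  }
  list(ds = ds, pos = i)
}

#' Read a DICOM Part-10 file written in explicit VR little endian
#'
#' @param path File path.
#' @return The dataset as an ordered named list of elements (file-meta group
#'   excluded), with attribute `"transfer_syntax"`.
#' @export
dcm_read <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  b <- readBin(path, "raw", n = file.size(path))
  if (length(b) < 140L || rawToChar(b[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  i <- 133L
  # file meta group (always explicit LE)
  ts <- DCM_TS_EXPLICIT_LE
  repeat {
    if (i + 7L > length(b)) break
    grp <- .rd_u16(b, i)
    if (grp != 2L) break
    ele <- .rd_u16(b, i + 2L)
    vr <- rawToChar(b[(i + 4L):(i + 5L)])
    if (vr %in% .dcm_long_vrs) {
      len <- .rd_u32(b, i + 8L); i <- i + 12L
    } else {
      len <- .rd_u16(b, i + 6L); i <- i + 8L
    }
    if (ele == 0x0010) ts <- .dcm_parse_value("UI", b[i:(i + len - 1L)])
    i <- i + len
  }
  if (!identical(ts, DCM_TS_EXPLICIT_LE)) {
    stop("unsupported transfer syntax: ", ts, call. = FALSE)
  }
  out <- .dcm_parse_elements(b, i, length(b))$ds
  attr(out, "transfer_syntax") <- ts
  out
}

# Convenience accessors ------------------------------------------------------

dcm_get <- function(ds, tag, default = NULL) {
  el <- ds[[tag]]
  if (is.null(el)) default else el$value
}

dcm_seq <- function(ds, tag) {
  el <- ds[[tag]]
  if (is.null(el)) list() else el$value
}

`%||%` <- function(a, b) if (is.null(a)) b else a
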