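# Minimal DICOM codec: Explicit VR Little Endian only, defined-length
# writing, defined- and undefined-length sequence reading. Covers just the
# elements the RT readers/writers need. Datasets are represented as named
# lists keyed "GGGGEEEE" -> list(vr, value); SQ values are lists of nested
# datasets.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.1437."

new_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0(UID_ROOT, format(as.integer(Sys.time()) %% 1e8), ".", counter)
  }
})

tag_key <- function(group, element) sprintf("%04X%04X", group, element)

u16_raw <- function(x) {
  x <- as.integer(x) %% 65536L
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}

u32_raw <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(as.vector(rbind(x %% 256, (x %/% 256) %% 256,
                         (x %/% 65536) %% 256, (x %/% 16777216) %% 256)))
}

int16_raw <- function(x) {
  x <- as.integer(round(x))
  u16_raw(ifelse(x < 0, x + 65536L, x))
}

raw_u16 <- function(r, at) {
  as.integer(r[at]) + 256L * as.integer(r[at + 1L])
}

raw_u32 <- function(r, at) {
  as.integer(r[at]) + 256 * as.integer(r[at + 1L]) +
    65536 * as.integer(r[at + 2L]) + 16777216 * as.integer(r[at + 3L])
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
STR_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
             "SH", "ST", "TM", "UI", "UC", "UR", "UT")

encode_value <- function(vr, value) {
  if (vr %in% STR_VRS) {
    s <- paste(as.character(value), collapse = "\\")
    r <- charToRaw(s)
    if (length(r) %% 2L == 1L)
      r <- c(r, if (vr == "UI") as.raw(0) else charToRaw(" "))
    return(r)
  }
  switch(vr,
    US = u16_raw(value),
    UL = u32_raw(value),
    FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
    OW = ,
    OB = {
      r <- as.raw(value)
      if (length(r) %% 2L == 1L) r <- c(r, as.raw(0))
      r
    },
    stop("unsupported VR for writing: ", vr))
}

# format numerics for DS elements
ds_str <- function(x) sprintf("%.9g", x)

encode_element <- function(group, element, vr, value) {
  if (vr == "SQ") {
    items <- lapply(value, encode_dataset)
    body <- raw(0)
    for (it in items)
      body <- c(body, u16_raw(0xFFFE), u16_raw(0xE000),
                u32_raw(length(it)), it)
    return(c(u16_raw(group), u16_raw(element), charToRaw("SQ"),
             as.raw(c(0, 0)), u32_raw(length(body)), body))
  }
  body <- encode_value(vr, value)
  if (vr %in% LONG_VRS) {
    c(u16_raw(group), u16_raw(element), charToRaw(vr), as.raw(c(0, 0)),
      u32_raw(length(body)), body)
  } else {
    if (length(body) > 65534) stop("value too long for short-form VR ", vr)
    c(u16_raw(group), u16_raw(element), charToRaw(vr),
      u16_raw(length(body)), body)
  }
}

# dataset: named list key -> list(vr, value); encoded in ascending tag order
encode_dataset <- function(ds) {
  keys <- names(ds)
  keys <- keys[order(keys)]
  out <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    g <- strtoi(substr(k, 1, 4), 16L)
    e <- strtoi(substr(k, 5, 8), 16L)
    out[[i]] <- encode_element(g, e, ds[[k]]$vr, ds[[k]]$value)
  }
  do.call(c, out)
}

dcm_el <- function(vr, value) list(vr = vr, value = value)

#' @keywords internal
dcm_write_file <- function(path, ds, sop_class, sop_instance) {
  meta <- list()
  meta[[tag_key(0x0002, 0x0002)]] <- dcm_el("UI", sop_class)
  meta[[tag_key(0x0002, 0x0003)]] <- dcm_el("UI", sop_instance)
  meta[[tag_key(0x0002, 0x0010)]] <- dcm_el("UI", UID_EXPLICIT_LE)
  meta[[tag_key(0x0002, 0x0012)]] <- dcm_el("UI", paste0(UID_ROOT, "1"))
  meta_raw <- encode_dataset(meta)
  grplen <- encode_element(0x0002, 0x0000, "UL", length(meta_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grplen, meta_raw, encode_dataset(ds)), con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

decode_value <- function(vr, body) {
  if (vr %in% STR_VRS) {
    s <- rawToChar(body[body != as.raw(0)])
    s <- sub("[ ]+$", "", s)
    parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
    if (vr %in% c("DS", "IS")) return(as.numeric(parts))
    return(parts)
  }
  switch(vr,
    US = readBin(body, "integer", n = length(body) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    UL = readBin(body, "integer", n = length(body) / 4, size = 4,
                 endian = "little"),
    FD = readBin(body, "double", n = length(body) / 8, size = 8,
                 endian = "little"),
    FL = readBin(body, "double", n = length(body) / 4, size = 4,
                 endian = "little"),
    body)  # OW/OB/unknown: keep raw
}

# parse a dataset from raw r, positions [from, to]; returns named list
parse_dataset <- function(r, from, to) {
  ds <- list()
  pos <- from
  while (pos <= to) {
    g <- raw_u16(r, pos); e <- raw_u16(r, pos + 2L); pos <- pos + 4L
    if (g == 0xFFFE) { # delimiter items inside undefined-length sequences
      len <- raw_u32(r, pos); pos <- pos + 4L
      if (e %in% c(0xE00D, 0xE0DD)) next
      stop("unexpected item tag outside sequence")
    }
    vr <- rawToChar(r[pos:(pos + 1L)]); pos <- pos + 2L
    if (vr %in% LONG_VRS) {
      pos <- pos + 2L
      len <- raw_u32(r, pos); pos <- pos + 4L
    } else {
      len <- raw_u16(r, pos); pos <- pos + 2L
    }
    key <- tag_key(g, e)
    if (vr == "SQ") {
      if (len == 4294967295) { # undefined length: scan to sequence delimiter
        res <- parse_sq(r, pos, NA)
      } else {
        res <- parse_sq(r, pos, pos + len - 1L)
      }
      ds[[key]] <- dcm_el("SQ", res$items)
      pos <- res$end + 1L
    } else {
      if (len == 4294967295) stop("undefined length on non-SQ element")
      body <- if (len > 0) r[pos:(pos + len - 1L)] else raw(0)
      ds[[key]] <- dcm_el(vr, decode_value(vr, body))
      pos <- pos + len
    }
  }
  ds
}

# parse sequence items from pos; `to` NA means undefined length (scan for
# the FFFE,E0DD delimiter). Returns list(items, end = last consumed pos)
parse_sq <- function(r, pos, to) {
  items <- list()
  repeat {
    if (!is.na(to) && pos > to) return(list(items = items, end = to))
    g <- raw_u16(r, pos); e <- raw_u16(r, pos + 2L)
    len <- raw_u32(r, pos + 4L)
    pos <- pos + 8L
    if (g == 0xFFFE && e == 0xE0DD)
      return(list(items = items, end = pos - 1L))
    if (!(g == 0xFFFE && e == 0xE000))
      stop("malformed sequence item tag")
    if (len == 4294967295) {
      # undefined-length item: parse until the item delimiter
      depth_end <- find_item_end(r, pos)
      items[[length(items) + 1L]] <- parse_dataset(r, pos, depth_end$content_end)
      pos <- depth_end$next_pos
    } else {
      if (len > 0)
        items[[length(items) + 1L]] <- parse_dataset(r, pos, pos + len - 1L)
      else
        items[[length(items) + 1L]] <- list()
      pos <- pos + len
    }
  }
}

# locate the FFFE,E00D delimiter ending an undefined-length item (no
# support for nested undefined-length sequences inside such items)
find_item_end <- function(r, pos) {
  p <- pos
  repeat {
    g <- raw_u16(r, p); e <- raw_u16(r, p + 2L)
    if (g == 0xFFFE && e == 0xE00D)
      return(list(content_end = p - 1L, next_pos = p + 8L))
    vr <- rawToChar(r[(p + 4L):(p + 5L)])
    if (vr %in% LONG_VRS) {
      len <- raw_u32(r, p + 8L)
      p <- p + 12L + len
    } else {
      len <- raw_u16(r, p + 6L)
      p <- p + 8L + len
    }
  }
}

#' @keywords internal
dcm_read_file <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  # file meta group (always explicit LE); read elements while group == 0002
  meta <- list()
  while (pos <= length(r) && raw_u16(r, pos) == 0x0002) {
    g <- raw_u16(r, pos); e <- raw_u16(r, pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- raw_u32(r, pos + 8L); hdr <- 12L
    } else {
      len <- raw_u16(r, pos + 6L); hdr <- 8L
    }
    body <- if (len > 0) r[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    meta[[tag_key(g, e)]] <- dcm_el(vr, decode_value(vr, body))
    pos <- pos + hdr + len
  }
  ts <- meta[[tag_key(0x0002, 0x0010)]]$value
  if (!is.null(ts) && !identical(ts, UID_EXPLICIT_LE))
    stop("unsupported transfer syntax: ", ts,
         " (only Explicit VR Little Endian is supported)")
  ds <- parse_dataset(r, pos, length(r))
  attr(ds, "file_meta") <- meta
  ds
}

dcm_get <- function(ds, group, element, default = NULL) {
  el <- ds[[tag_key(group, element)]]
  if (is.null(el)) default else el$value
}
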