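# Minimal DICOM codec for RT Plan files: little-endian, explicit or implicit
# VR on read, explicit VR on write.  Covers the Beam Sequence / Control Point
# Sequence subset a VMAT complexity analysis needs; it is not a general DICOM
# toolkit and writes files for fixtures and interchange, not for treatment.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_RTPLAN      <- "1.2.840.10008.5.1.4.1.1.481.5"

# VRs with the 4-byte length form in explicit encoding
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# tag dictionary: only what the reader/writer touches; VR needed for implicit
DICOM_DICT <- local({
  d <- rbind(
    c("0008,0016", "UI"), c("0008,0018", "UI"), c("0008,0060", "CS"),
    c("0010,0010", "PN"), c("0010,0020", "LO"),
    c("300a,0002", "SH"),
    c("300a,0070", "SQ"), c("300c,0004", "SQ"), c("300c,0006", "IS"),
    c("300a,0086", "DS"),
    c("300a,00b0", "SQ"), c("300a,00c0", "IS"), c("300a,00c2", "LO"),
    c("300a,00c4", "CS"), c("300a,00ce", "CS"),
    c("300a,00b6", "SQ"), c("300a,00b8", "CS"), c("300a,00bc", "IS"),
    c("300a,00be", "DS"),
    c("300a,010e", "DS"), c("300a,0110", "IS"),
    c("300a,0111", "SQ"), c("300a,0112", "IS"), c("300a,0114", "DS"),
    c("300a,011a", "SQ"), c("300a,011c", "DS"), c("300a,011e", "DS"),
    c("300a,011f", "CS"), c("300a,0134", "DS")
  )
  stats::setNames(d[, 2], d[, 1])
})

tag_key <- function(group, elem) sprintf("%04x,%04x", group, elem)

uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32 <- function(x) {
  # avoid 32-bit signed overflow for 0xFFFFFFFF
  x <- as.numeric(x)
  bytes <- integer(4)
  for (i in 1:4) { bytes[i] <- x %% 256; x <- x %/% 256 }
  as.raw(bytes)
}

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

dcm_format_ds <- function(x) {
  # DS values are <= 16 bytes each; trim trailing zeros for compactness
  s <- sprintf("%.8f", x)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", ".0", s)
  s
}

# Encode one data element (explicit VR little endian)
dcm_element <- function(group, elem, vr, value) {
  bytes <- switch(vr,
    UI = pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0)),
    SQ = value,  # already-encoded item stream
    OB = pad_even(value, as.raw(0)),
    UL = uint32(value),
    pad_even(charToRaw(paste(value, collapse = "\\")))  # string VRs
  )
  hdr <- c(uint16(group), uint16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), uint32(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534) stop("element too long for short VR form")
    c(hdr, uint16(length(bytes)), bytes)
  }
}

# Encode a sequence item (defined length)
dcm_item <- function(content)
  c(uint16(0xFFFE), uint16(0xE000), uint32(length(content)), content)

#' Write a plan as a DICOM-RT Plan file
#'
#' Emits an explicit-VR little-endian RT Plan with Beam Sequence, Beam
#' Limiting Device Sequence (MLCX leaf boundaries), Control Point Sequence
#' (gantry angle, cumulative meterset weight, ASYMX/ASYMY jaws when present,
#' MLCX leaf positions with bank A followed by bank B), and a Fraction Group
#' Sequence carrying each beam's meterset.  Intended for fixtures and data
#' interchange; it carries no dose or prescription content.
#'
#' @param plan a `vmat_plan`.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_dicom_plan <- function(plan, path) {
  beams <- raw(0)
  refbeams <- raw(0)
  for (bi in seq_along(plan$arcs)) {
    a <- plan$arcs[[bi]]
    npairs <- length(a$leaf_widths)
    bounds <- cumsum(c(0, a$leaf_widths)) - sum(a$leaf_widths) / 2
    bld <- dcm_item(c(
      dcm_element(0x300A, 0x00B8, "CS", "MLCX"),
      dcm_element(0x300A, 0x00BC, "IS", as.character(npairs)),
      dcm_element(0x300A, 0x00BE, "DS", dcm_format_ds(bounds))
    ))
    cps <- raw(0)
    for (cp in a$control_points) {
      blp <- raw(0)
      if (!is.null(cp$jaw_x))
        blp <- c(blp, dcm_item(c(
          dcm_element(0x300A, 0x00B8, "CS", "ASYMX"),
          dcm_element(0x300A, 0x011C, "DS", dcm_format_ds(cp$jaw_x)))))
      if (!is.null(cp$jaw_y))
        blp <- c(blp, dcm_item(c(
          dcm_element(0x300A, 0x00B8, "CS", "ASYMY"),
          dcm_element(0x300A, 0x011C, "DS", dcm_format_ds(cp$jaw_y)))))
      blp <- c(blp, dcm_item(c(
        dcm_element(0x300A, 0x00B8, "CS", "MLCX"),
        dcm_element(0x300A, 0x011C, "DS",
                    dcm_format_ds(c(cp$bankA, cp$bankB))))))
      cps <- c(cps, dcm_item(c(
        dcm_element(0x300A, 0x0112, "IS", as.character(cp$index)),
        dcm_element(0x300A, 0x011E, "DS", dcm_format_ds(cp$gantry_angle)),
        dcm_element(0x300A, 0x011A, "SQ", blp),
        dcm_element(0x300A, 0x0134, "DS", dcm_format_ds(cp$mu_fraction))
      )))
    }
    beams <- c(beams, dcm_item(c(
      dcm_element(0x300A, 0x00B6, "SQ", bld),
      dcm_element(0x300A, 0x00C0, "IS", as.character(bi)),
      dcm_element(0x300A, 0x00C2, "LO", a$arc_id),
      dcm_element(0x300A, 0x00C4, "CS", "DYNAMIC"),
      dcm_element(0x300A, 0x010E, "DS", "1.0"),
      dcm_element(0x300A, 0x0110, "IS",
                  as.character(length(a$control_points))),
      dcm_element(0x300A, 0x0111, "SQ", cps)
    )))
    refbeams <- c(refbeams, dcm_item(c(
      dcm_element(0x300A, 0x0086, "DS", dcm_format_ds(a$arc_mu)),
      dcm_element(0x300C, 0x0006, "IS", as.character(bi))
    )))
  }
  sop_uid <- paste0("1.2.826.0.1.3680043.9999.", abs(sum(utf8ToInt(plan$plan_id))),
                    ".", length(plan$arcs))
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_RTPLAN),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_element(0x0010, 0x0010, "PN", "Synthetic^Fixture"),
    dcm_element(0x0010, 0x0020, "LO", plan$plan_id),
    dcm_element(0x300A, 0x0002, "SH", substr(plan$plan_id, 1, 16)),
    dcm_element(0x300A, 0x0070, "SQ",
                dcm_item(dcm_element(0x300C, 0x0004, "SQ", refbeams))),
    dcm_element(0x300A, 0x00B0, "SQ", beams)
  )
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", UID_RTPLAN),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9999.1")
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)
  out <- c(raw(128), charToRaw("DICM"), meta, dataset)
  writeBin(out, path)
  invisible(path)
}

# --- reader ----------------------------------------------------------------

read_u16 <- function(buf, pos) readBin(buf[pos:(pos + 1)], "integer",
                                       size = 2, signed = FALSE,
                                       endian = "little")
read_u32 <- function(buf, pos) {
  b <- as.integer(buf[pos:(pos + 3)])
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

# Parse a contiguous element stream into a list keyed by "gggg,eeee".
# Repeated tags (sequence items hold their own scope) do not occur at one
# level in the subset we read.
parse_elements <- function(buf, pos, end, explicit) {
  out <- list()
  while (pos < end) {
    group <- read_u16(buf, pos); elem <- read_u16(buf, pos + 2)
    key <- tag_key(group, elem)
    if (group == 0xFFFE) {  # delimiters at this level: stop
      break
    }
    if (explicit) {
      vr <- rawToChar(buf[(pos + 4):(pos + 5)])
      if (vr %in% LONG_VRS) {
        len <- read_u32(buf, pos + 8); body <- pos + 12
      } else {
        len <- read_u16(buf, pos + 6); body <- pos + 8
      }
    } else {
      vr <- if (!is.na(DICOM_DICT[key])) unname(DICOM_DICT[key]) else "UN"
      len <- read_u32(buf, pos + 4); body <- pos + 8
      if (vr == "UN" && len == 4294967295) vr <- "SQ"
    }
    if (vr == "SQ") {
      parsed <- parse_sequence(buf, body, len, explicit)
      out[[key]] <- parsed$items
      pos <- parsed$pos
    } else if (len == 4294967295) {
      stop("undefined length on non-sequence element ", key)
    } else {
      val <- buf[body + seq_len(len) - 1]
      out[[key]] <- decode_value(val, vr)
      pos <- body + len
    }
  }
  list(values = out, pos = pos)
}

parse_sequence <- function(buf, pos, len, explicit) {
  items <- list()
  end <- if (len == 4294967295) length(buf) + 1 else pos + len
  while (pos < end) {
    group <- read_u16(buf, pos); elem <- read_u16(buf, pos + 2)
    ilen <- read_u32(buf, pos + 4)
    pos <- pos + 8
    if (group == 0xFFFE && elem == 0xE0DD) break        # sequence delimiter
    if (!(group == 0xFFFE && elem == 0xE000))
      stop("malformed sequence: expected item tag, got ", tag_key(group, elem))
    iend <- if (ilen == 4294967295) end else pos + ilen
    parsed <- parse_elements(buf, pos, iend, explicit)
    items[[length(items) + 1]] <- parsed$values
    pos <- parsed$pos
    if (ilen == 4294967295) {
      # expect item delimiter
      if (read_u16(buf, pos) == 0xFFFE && read_u16(buf, pos + 2) == 0xE00D)
        pos <- pos + 8
    }
  }
  list(items = items, pos = pos)
}

decode_value <- function(bytes, vr) {
  if (vr %in% c("OB", "OW", "UN")) return(bytes)
  if (vr == "UL") return(read_u32(bytes, 1))
  s <- rawToChar(bytes[bytes != as.raw(0)])
  s <- trimws(s)
  if (vr %in% c("DS", "IS")) {
    v <- as.numeric(strsplit(s, "\\\\")[[1]])
    if (vr == "IS") v <- as.integer(v)
    return(v)
  }
  strsplit(s, "\\\\")[[1]]
}

#' Read a DICOM-RT Plan file
#'
#' Parses little-endian DICOM (explicit or implicit VR) and returns the
#' dynamic (VMAT) beams as a [vmat_plan()].  Leaf positions are mapped to the
#' two-bank convention: bank A is the first half of the MLCX
#' `LeafJawPositions` vector (the X1/negative-travel bank), bank B the second
#' half.  Cumulative meterset weights are normalised to `[0, 1]` by the
#' beam's final cumulative meterset weight.  Static/setup beams are skipped
#' with a message.  Control points that omit the MLCX positions inherit them
#' from the previous control point (DICOM allows unchanged values to be
#' elided); the first control point must carry them.
#'
#' @param path path to the DICOM file.
#' @return A validated [vmat_plan()].
#' @export
read_dicom_plan <- function(path) {
  buf <- readBin(path, raw(), file.info(path)$size)
  if (length(buf) < 132 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133
  # file meta group is always explicit VR LE; (0002,0000) gives its length
  meta0 <- parse_elements(buf, pos, pos + 12, explicit = TRUE)
  glen <- meta0$values[["0002,0000"]]
  if (is.null(glen)) stop("missing file meta group length")
  meta <- parse_elements(buf, meta0$pos, meta0$pos + glen, explicit = TRUE)
  ts <- meta$values[["0002,0010"]]
  explicit <- if (is.null(ts) || ts == UID_EXPLICIT_LE) TRUE
    else if (ts == UID_IMPLICIT_LE) FALSE
    else stop("unsupported transfer syntax: ", ts)
  ds <- parse_elements(buf, meta$pos, length(buf) + 1, explicit)$values

  plan_id <- ds[["0010,0020"]] %||% ds[["300a,0002"]] %||% "dicom-plan"
  beams <- ds[["300a,00b0"]]
  if (is.null(beams)) stop("no Beam Sequence (300A,00B0) in ", path)

  # beam number -> meterset from the fraction group
  metersets <- list()
  fg <- ds[["300a,0070"]]
  if (!is.null(fg)) for (g in fg) for (rb in g[["300c,0004"]] %||% list()) {
    bn <- rb[["300c,0006"]]; ms <- rb[["300a,0086"]]
    if (!is.null(bn) && !is.null(ms)) metersets[[as.character(bn)]] <- ms
  }

  arcs <- list()
  for (beam in beams) {
    bname <- beam[["300a,00c2"]] %||% paste0("beam", beam[["300a,00c0"]] %||% "?")
    btype <- beam[["300a,00c4"]] %||% "STATIC"
    if (!identical(toupper(btype), "DYNAMIC")) {
      message("skipping non-dynamic beam '", bname, "' (type ", btype, ")")
      next
    }
    npairs <- NA_integer_; widths <- NULL
    for (bld in beam[["300a,00b6"]] %||% list()) {
      if (identical(bld[["300a,00b8"]], "MLCX")) {
        npairs <- bld[["300a,00bc"]]
        bounds <- bld[["300a,00be"]]
        if (!is.null(bounds)) widths <- diff(bounds)
      }
    }
    cps_raw <- beam[["300a,0111"]]
    if (is.null(cps_raw))
      stop("beam '", bname, "': no Control Point Sequence")
    final_w <- beam[["300a,010e"]] %||% {
      last <- cps_raw[[length(cps_raw)]][["300a,0134"]]
      if (is.null(last)) 1 else last
    }
    if (final_w <= 0) final_w <- 1
    prev_mlc <- NULL; prev_jx <- NULL; prev_jy <- NULL; prev_ang <- NA_real_
    cps <- vector("list", length(cps_raw))
    for (ci in seq_along(cps_raw)) {
      cp <- cps_raw[[ci]]
      mlc <- NULL; jx <- prev_jx; jy <- prev_jy
      for (bp in cp[["300a,011a"]] %||% list()) {
        ty <- toupper(bp[["300a,00b8"]] %||% "")
        v <- bp[["300a,011c"]]
        if (ty == "MLCX") mlc <- v
        else if (ty %in% c("X", "ASYMX")) jx <- v
        else if (ty %in% c("Y", "ASYMY")) jy <- v
      }
      if (is.null(mlc)) mlc <- prev_mlc
      if (is.null(mlc))
        stop("beam '", bname, "': control point ", ci - 1,
             " has no MLCX positions and none precede it (format error)")
      n2 <- length(mlc)
      if (n2 %% 2 != 0)
        stop("beam '", bname, "': odd MLCX position count ", n2)
      if (is.na(npairs)) npairs <- n2 / 2
      ang <- cp[["300a,011e"]] %||% prev_ang
      cps[[ci]] <- control_point(
        index = cp[["300a,0112"]] %||% (ci - 1L),
        gantry_angle = ang,
        mu_fraction = (cp[["300a,0134"]] %||% 0) / final_w,
        bankA = mlc[seq_len(npairs)],
        bankB = mlc[npairs + seq_len(npairs)],
        jaw_x = jx, jaw_y = jy
      )
      prev_mlc <- mlc; prev_jx <- jx; prev_jy <- jy; prev_ang <- ang
    }
    if (is.null(widths)) widths <- rep(5, npairs)  # boundaries absent: assume 5 mm
    bn <- as.character(beam[["300a,00c0"]] %||% (length(arcs) + 1))
    arcs[[length(arcs) + 1]] <- vmat_arc(
      arc_id = bname,
      control_points = cps,
      arc_mu = metersets[[bn]] %||% NA_real_,
      leaf_widths = widths
    )
  }
  if (!length(arcs))
    stop("no dynamic (VMAT) beams found in ", path)
  vmat_plan(plan_id, arcs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
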