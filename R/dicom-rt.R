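# Minimal DICOM Part-10 reader/writer for RT Plan objects, explicit VR
# little endian only.  Covers exactly the attribute subset the plan model
# needs: BeamSequence / ControlPointSequence / MLCX positions / cumulative
# meterset weights / FractionGroup metersets.  Not a general DICOM toolkit.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_IMPL <- "1.2.826.0.1.3680043.10.1462.1"
UID_ROOT <- "1.2.826.0.1.3680043.10.1462.2"

VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                              endian = "little")
u32le <- function(x) {
  # R integers are signed 32-bit; lengths here never exceed 2^31 - 1
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

dcm_pad <- function(payload, pad = as.raw(0x20)) {
  if (length(payload) %% 2L == 1L) c(payload, pad) else payload
}

dcm_element <- function(group, elem, vr, payload) {
  payload <- dcm_pad(payload, if (vr %in% c("UI", "OB")) as.raw(0) else
    as.raw(0x20))
  head <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% VR_LONG) {
    c(head, as.raw(c(0, 0)), u32le(length(payload)), payload)
  } else {
    stop_if(length(payload) > 65535L, "element payload too long for short VR")
    c(head, u16le(length(payload)), payload)
  }
}

dcm_str <- function(group, elem, vr, s) {
  dcm_element(group, elem, vr, charToRaw(paste(s, collapse = "\\")))
}

# DS: decimal strings, max 16 bytes per value
fmt_ds <- function(x) {
  s <- formatC(x, digits = 10, format = "g", flag = "")
  s <- trimws(s)
  stop_if(any(nchar(s) > 16L), "DS value exceeds 16 characters")
  s
}

dcm_ds <- function(group, elem, x) dcm_str(group, elem, "DS", fmt_ds(x))
dcm_is <- function(group, elem, x) dcm_str(group, elem, "IS",
                                           as.character(as.integer(x)))

dcm_item <- function(payload) {
  c(u16le(0xFFFE), u16le(0xE000), u32le(length(payload)), payload)
}

dcm_sq <- function(group, elem, items) {
  payload <- do.call(c, c(lapply(items, dcm_item), list(raw(0))))
  dcm_element(group, elem, "SQ", payload)
}

new_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste(UID_ROOT, format(as.numeric(Sys.time()) * 1000, scientific = FALSE,
                           trim = TRUE, digits = 13),
          Sys.getpid() %% 10000L, counter, sep = ".")
  }
})

#' Write a plan as a DICOM-RT Plan file
#'
#' Serializes a [vmat_plan] as an RT Plan Storage object (explicit VR
#' little endian): beam sequence with per-control-point MLCX leaf
#' positions, gantry angles and cumulative meterset weights, plus fraction
#' group metersets and the target prescription dose. The arc increment,
#' which has no standard DICOM attribute, is carried in BeamDescription as
#' `increment=<deg>` so that [load_rtplan()] round-trips the full model.
#'
#' @param plan a [vmat_plan].
#' @param path output path (conventionally `.dcm`).
#' @return `path`, invisibly.
#' @seealso [load_rtplan()]
#' @export
write_rtplan <- function(plan, path) {
  stopifnot(inherits(plan, "vmat_plan"))
  sop_uid <- new_uid()
  pid <- if (is.na(plan$patient_id)) "" else plan$patient_id
  label <- if (is.na(plan$group)) "plan" else sprintf("group %s", plan$group)

  beam_items <- lapply(seq_along(plan$arcs), function(k) {
    arc <- plan$arcs[[k]]
    n_pairs <- length(arc$control_points[[1]]$mlc$left)
    t <- arc$control_points[[1]]$mlc$leaf_width
    bounds <- seq(-n_pairs * t / 2, n_pairs * t / 2, by = t)
    cp_items <- lapply(seq_along(arc$control_points), function(i) {
      cp <- arc$control_points[[i]]
      c(
        dcm_is(0x300A, 0x0112, i - 1L),
        if (i == 1L) dcm_ds(0x300A, 0x0114, 6) else raw(0),
        dcm_sq(0x300A, 0x011A, list(c(
          dcm_str(0x300A, 0x00B8, "CS", "MLCX"),
          dcm_ds(0x300A, 0x011C, c(cp$mlc$left, cp$mlc$right))
        ))),
        dcm_ds(0x300A, 0x011E, cp$gantry_deg),
        dcm_str(0x300A, 0x011F, "CS",
                if (arc$direction == "CW") "CW" else "CC"),
        dcm_ds(0x300A, 0x0120, cp$collimator_deg),
        dcm_ds(0x300A, 0x0134, cp$cum_weight)
      )
    })
    c(
      dcm_sq(0x300A, 0x00B6, list(c(
        dcm_str(0x300A, 0x00B8, "CS", "MLCX"),
        dcm_is(0x300A, 0x00BC, n_pairs),
        dcm_ds(0x300A, 0x00BE, bounds)
      ))),
      dcm_is(0x300A, 0x00C0, k),
      dcm_str(0x300A, 0x00C2, "LO", sprintf("Arc%d", k)),
      dcm_str(0x300A, 0x00C3, "ST",
              sprintf("increment=%g", arc$increment_deg)),
      dcm_str(0x300A, 0x00C4, "CS", "DYNAMIC"),
      dcm_str(0x300A, 0x00CE, "CS", "TREATMENT"),
      dcm_ds(0x300A, 0x010E, 1),
      dcm_is(0x300A, 0x0110, length(arc$control_points)),
      dcm_sq(0x300A, 0x0111, cp_items)
    )
  })

  ref_beam_items <- lapply(seq_along(plan$arcs), function(k) c(
    dcm_ds(0x300A, 0x0086, plan$arcs[[k]]$arc_mu),
    dcm_is(0x300C, 0x0006, k)
  ))

  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_RTPLAN),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_str(0x0010, 0x0010, "PN", pid),
    dcm_str(0x0010, 0x0020, "LO", pid),
    dcm_str(0x300A, 0x0002, "SH", label),
    dcm_sq(0x300A, 0x0010, list(c(
      dcm_is(0x300A, 0x0012, 1L),
      dcm_str(0x300A, 0x0014, "CS", "SITE"),
      dcm_str(0x300A, 0x0020, "CS", "TARGET"),
      dcm_ds(0x300A, 0x0026, plan$prescription_gy)
    ))),
    dcm_sq(0x300A, 0x0070, list(c(
      dcm_is(0x300A, 0x0071, 1L),
      dcm_is(0x300A, 0x0078, plan$fractions),
      dcm_is(0x300A, 0x0080, length(plan$arcs)),
      dcm_sq(0x300C, 0x0004, ref_beam_items)
    ))),
    dcm_sq(0x300A, 0x00B0, beam_items)
  )

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", UID_RTPLAN),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_str(0x0002, 0x0012, "UI", UID_IMPL)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", u32le(length(meta_body))),
            meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(rep(as.raw(0), 128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

# --- reader -----------------------------------------------------------

tag_key <- function(group, elem) sprintf("%04X%04X", group, elem)

read_u16 <- function(bytes, pos) {
  sum(as.integer(bytes[pos:(pos + 1L)]) * c(1L, 256L))
}
read_u32 <- function(bytes, pos) {
  sum(as.numeric(bytes[pos:(pos + 3L)]) * c(1, 256, 65536, 16777216))
}

# parse explicit-VR-LE elements in bytes[start..end]; returns a named list
# keyed by GGGGEEEE with parsed values (SQ -> list of item lists)
parse_elements <- function(bytes, start, end) {
  out <- list()
  pos <- start
  while (pos <= end - 7L) {
    group <- read_u16(bytes, pos)
    elem <- read_u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    stop_if(!grepl("^[A-Z]{2}$", vr),
            "not an explicit-VR element stream at byte ", pos)
    if (vr %in% VR_LONG) {
      len <- read_u32(bytes, pos + 8L)
      body_start <- pos + 12L
    } else {
      len <- read_u16(bytes, pos + 6L)
      body_start <- pos + 8L
    }
    if (vr == "SQ") {
      if (len == 4294967295) {
        parsed <- parse_sq_undefined(bytes, body_start)
        value <- parsed$items
        pos <- parsed$next_pos
      } else {
        value <- parse_sq_items(bytes, body_start, body_start + len - 1L)
        pos <- body_start + len
      }
    } else {
      body <- if (len > 0) bytes[body_start:(body_start + len - 1L)] else
        raw(0)
      value <- parse_value(vr, body)
      pos <- body_start + len
    }
    out[[tag_key(group, elem)]] <- value
  }
  out
}

parse_sq_items <- function(bytes, start, end) {
  items <- list()
  pos <- start
  while (pos <= end - 7L) {
    g <- read_u16(bytes, pos); e <- read_u16(bytes, pos + 2L)
    len <- read_u32(bytes, pos + 4L)
    stop_if(g != 0xFFFE || e != 0xE000, "malformed sequence item tag")
    stop_if(len == 4294967295,
            "undefined-length items inside defined-length sequence unsupported")
    items[[length(items) + 1L]] <-
      parse_elements(bytes, pos + 8L, pos + 7L + len)
    pos <- pos + 8L + len
  }
  items
}

parse_sq_undefined <- function(bytes, start) {
  items <- list()
  pos <- start
  repeat {
    g <- read_u16(bytes, pos); e <- read_u16(bytes, pos + 2L)
    len <- read_u32(bytes, pos + 4L)
    if (g == 0xFFFE && e == 0xE0DD) {
      pos <- pos + 8L
      break
    }
    stop_if(g != 0xFFFE || e != 0xE000, "malformed sequence item tag")
    stop_if(len == 4294967295, "nested undefined-length items unsupported")
    items[[length(items) + 1L]] <-
      parse_elements(bytes, pos + 8L, pos + 7L + len)
    pos <- pos + 8L + len
  }
  list(items = items, next_pos = pos)
}

parse_value <- function(vr, body) {
  if (vr %in% c("DS", "IS")) {
    s <- strsplit(trimws(rawToChar(body)), "\\", fixed = TRUE)[[1]]
    as.numeric(s)
  } else if (vr %in% c("UI", "CS", "SH", "LO", "ST", "LT", "PN", "AE",
                       "DA", "TM", "DT", "AS", "UT")) {
    sub(" +$", "", rawToChar(body[body != as.raw(0)]))
  } else if (vr == "UL") {
    read_u32(body, 1L)
  } else if (vr == "US") {
    read_u16(body, 1L)
  } else {
    body
  }
}

#' Read a DICOM-RT Plan file into the plan model
#'
#' Parses an RT Plan Storage file (explicit VR little endian) and builds a
#' [vmat_plan]. Cumulative meterset weights are normalized by the beam's
#' final cumulative weight; per-arc metersets come from the fraction
#' group's ReferencedBeamSequence. Beams without an MLCX
#' BeamLimitingDevicePositionSequence raise a format error; non-monotone
#' cumulative weights raise a validation error naming the beam and control
#' point.
#'
#' @param path path to the DICOM file.
#' @return a [vmat_plan].
#' @export
load_rtplan <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  stop_if(length(bytes) < 140 ||
            rawToChar(bytes[129:132]) != "DICM",
          "not a DICOM Part-10 file (missing DICM magic): ", path)
  # file meta group: (0002,0000) UL group length
  stop_if(read_u16(bytes, 133L) != 2L, "missing file meta group")
  meta_len <- read_u32(bytes, 141L)
  meta <- parse_elements(bytes, 133L, 144L + meta_len)
  ts <- meta[["00020010"]]
  stop_if(!identical(ts, UID_EXPLICIT_LE),
          "unsupported transfer syntax: ", ts,
          " (only explicit VR little endian is supported)")
  ds <- parse_elements(bytes, 145L + meta_len, length(bytes))

  stop_if(is.null(ds[["300A00B0"]]), "format error: no BeamSequence in ", path)
  beams <- ds[["300A00B0"]]
  stop_if(length(beams) < 1L, "format error: empty BeamSequence")

  # arc metersets, indexed by beam number
  fg <- ds[["300A0070"]]
  stop_if(is.null(fg) || length(fg) < 1L,
          "format error: no FractionGroupSequence")
  refs <- fg[[1]][["300C0004"]]
  mu_by_beam <- stats::setNames(
    vapply(refs, function(r) r[["300A0086"]], numeric(1)),
    vapply(refs, function(r) as.character(r[["300C0006"]]), character(1)))
  fractions <- fg[[1]][["300A0078"]] %||% 35

  rx <- 70
  dr <- ds[["300A0010"]]
  if (!is.null(dr) && length(dr) >= 1L && !is.null(dr[[1]][["300A0026"]]))
    rx <- dr[[1]][["300A0026"]]

  arcs <- lapply(seq_along(beams), function(k) {
    b <- beams[[k]]
    beam_no <- b[["300A00C0"]] %||% k
    cps_raw <- b[["300A0111"]]
    stop_if(is.null(cps_raw) || length(cps_raw) < 2L,
            sprintf("format error: beam %d has < 2 control points", k))
    final_w <- b[["300A010E"]] %||% 1
    desc <- b[["300A00C3"]] %||% ""
    inc <- if (grepl("increment=", desc, fixed = TRUE))
      as.numeric(sub(".*increment=([0-9.]+).*", "\\1", desc)) else 30
    lw <- 5
    bld <- b[["300A00B6"]]
    if (!is.null(bld)) {
      for (d in bld) {
        if (identical(d[["300A00B8"]], "MLCX") && !is.null(d[["300A00BE"]]))
          lw <- diff(d[["300A00BE"]])[1]
      }
    }
    direction <- "CW"
    gantry <- numeric(length(cps_raw))
    weights <- numeric(length(cps_raw))
    mlcs <- vector("list", length(cps_raw))
    for (i in seq_along(cps_raw)) {
      cp <- cps_raw[[i]]
      if (!is.null(cp[["300A011F"]]) && cp[["300A011F"]] != "NONE")
        direction <- if (cp[["300A011F"]] == "CC") "CCW" else "CW"
      gantry[i] <- if (!is.null(cp[["300A011E"]])) cp[["300A011E"]] else
        gantry[max(i - 1, 1)]
      weights[i] <- cp[["300A0134"]] / final_w
      bl <- cp[["300A011A"]]
      stop_if(is.null(bl),
              sprintf(paste0("format error: beam %d CP %d has no ",
                             "BeamLimitingDevicePositionSequence"), k, i))
      mlc_pos <- NULL
      for (d in bl) {
        if (identical(d[["300A00B8"]], "MLCX")) mlc_pos <- d[["300A011C"]]
      }
      stop_if(is.null(mlc_pos),
              sprintf("format error: beam %d CP %d has no MLCX positions",
                      k, i))
      np <- length(mlc_pos) / 2
      stop_if(np != floor(np),
              sprintf("format error: odd MLCX position count at beam %d CP %d",
                      k, i))
      mlcs[[i]] <- mlc_positions(mlc_pos[1:np], mlc_pos[(np + 1):(2 * np)],
                                 leaf_width = lw)
    }
    bad <- which(diff(weights) < -1e-9)
    stop_if(length(bad) > 0,
            sprintf(paste0("validation error: non-monotone cumulative ",
                           "meterset weight at beam %d, control point %d"),
                    k, bad[1] + 1L))
    coll <- vapply(cps_raw, function(cp) cp[["300A0120"]] %||% 0, numeric(1))
    cps <- lapply(seq_along(cps_raw), function(i)
      control_point(gantry[i], mlcs[[i]], weights[i], coll[i]))
    vmat_arc(cps, arc_mu = mu_by_beam[[as.character(beam_no)]],
             increment_deg = inc, direction = direction)
  })

  group <- infer_group(vapply(arcs, `[[`, numeric(1), "increment_deg"))
  label <- ds[["300A0002"]] %||% ""
  if (grepl("^group ", label)) group <- sub("^group ", "", label)
  pid <- ds[["00100020"]] %||% ""
  vmat_plan(arcs, prescription_gy = rx, fractions = fractions,
            group = group,
            patient_id = if (nzchar(pid)) pid else NA_character_)
}
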