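# Minimal DICOM reader for RT Dose and RT Structure Set objects.
#
# Scope: explicit-VR little-endian transfer syntax only (the syntax plan
# export interfaces produce), axis-aligned dose grids
# (ImageOrientationPatient = 1\0\0\0\1\0), uncompressed integer pixel data.
# Only the data elements needed to reconstruct the dose lattice and the
# contour sets are interpreted; everything else is carried transparently.

dcm_uint <- function(raw, signed = FALSE) {
    sum(as.numeric(raw) * 256^(seq_along(raw) - 1))
}

dcm_tag <- function(raw4) {
    g <- dcm_uint(raw4[1:2]); e <- dcm_uint(raw4[3:4])
    sprintf("%04X,%04X", g, e)
}

VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")
VR_STR <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
            "SH", "ST", "TM", "UI", "UT")

# parse one element sequence from `raw` between byte offsets [pos, end];
# returns a named list tag -> value (SQ values are lists of item datasets)
dcm_parse <- function(raw, pos, end) {
    out <- list()
    while (pos + 7 <= end) {
        tag <- dcm_tag(raw[pos:(pos + 3)])
        if (tag == "FFFE,E0DD" || tag == "FFFE,E00D") {   # sequence/item end
            pos <- pos + 8
            break
        }
        vr <- rawToChar(raw[(pos + 4):(pos + 5)])
        if (vr %in% VR_LONG) {
            len <- dcm_uint(raw[(pos + 8):(pos + 11)])
            hdr <- 12L
        } else {
            len <- dcm_uint(raw[(pos + 6):(pos + 7)])
            hdr <- 8L
        }
        body <- pos + hdr
        if (vr == "SQ") {
            if (len == 4294967295) {                      # undefined length
                parsed <- dcm_parse_items(raw, body, end)
            } else {
                parsed <- dcm_parse_items(raw, body, body + len - 1)
                parsed$next_pos <- body + len
            }
            out[[tag]] <- parsed$items
            pos <- parsed$next_pos
            next
        }
        if (len == 4294967295)
            stop_parse("undefined length outside a sequence at tag ", tag)
        val_raw <- if (len > 0) raw[body:(body + len - 1)] else raw(0)
        out[[tag]] <- list(vr = vr, raw = val_raw)
        pos <- body + len
    }
    list(data = out, next_pos = pos)
}

# parse sequence items (FFFE,E000 ...) until sequence delimiter or `end`
dcm_parse_items <- function(raw, pos, end) {
    items <- list()
    while (pos + 7 <= end) {
        tag <- dcm_tag(raw[pos:(pos + 3)])
        if (tag == "FFFE,E0DD") { pos <- pos + 8; break }
        if (tag != "FFFE,E000")
            stop_parse("expected sequence item, found tag ", tag)
        len <- dcm_uint(raw[(pos + 4):(pos + 7)])
        body <- pos + 8
        if (len == 4294967295) {
            parsed <- dcm_parse(raw, body, end)   # stops at FFFE,E00D
        } else {
            parsed <- dcm_parse(raw, body, body + len - 1)
            parsed$next_pos <- body + len
        }
        items[[length(items) + 1L]] <- parsed$data
        pos <- parsed$next_pos
    }
    list(items = items, next_pos = pos)
}

dcm_read_file <- function(path) {
    if (!file.exists(path)) stop_parse("no such file: ", path)
    raw <- readBin(path, "raw", n = file.size(path))
    if (length(raw) < 140 ||
        !identical(rawToChar(raw[129:132]), "DICM"))
        stop_parse(path, " is not a DICOM part-10 file (missing DICM marker)")
    ds <- dcm_parse(raw, 133, length(raw))$data
    ts <- dcm_string(ds, "0002,0010")
    if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
        stop_parse("unsupported transfer syntax ", ts,
                   " (only explicit VR little endian is supported)")
    ds
}

dcm_string <- function(ds, tag) {
    el <- ds[[tag]]
    if (is.null(el)) return(NULL)
    trimws(rawToChar(el$raw[el$raw != as.raw(0)]))
}

dcm_numeric <- function(ds, tag) {
    s <- dcm_string(ds, tag)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_int_bin <- function(ds, tag, size) {
    el <- ds[[tag]]
    if (is.null(el)) return(NULL)
    readBin(el$raw, "integer", n = length(el$raw) / size, size = size,
            endian = "little", signed = size > 2)
}

dcm_required <- function(x, what) {
    if (is.null(x)) stop_parse("required DICOM element missing: ", what)
    x
}

#' Default structure-name to role mapping
#'
#' Institutional structure naming varies, so role assignment is driven by
#' a configurable table of case-insensitive regular expressions, tried in
#' order. This default covers common German/English naming; load a custom
#' table with [read_role_map()].
#'
#' @return named character vector: role -> regex.
#' @export
default_role_map <- function() {
    c(ITV = "^itv", PTV = "^ptv",
      LUNG_IPSI = "lung.*(ipsi|links|left|l)|(ipsi).*lung",
      LUNG_CONTRA = "lung.*(contra|rechts|right|r)|(contra).*lung",
      CHEST_WALL = "chest|thorax.*wall|rib",
      SPINAL_CANAL = "spinal|myelon|cord|canal",
      ESOPHAGUS = "eso|oeso")
}

#' Load a structure-role mapping from YAML or JSON
#'
#' The file holds a mapping `role: regex` (YAML) or the equivalent JSON
#' object; roles must be from [STRUCTURE_ROLES].
#'
#' @param path YAML or JSON file.
#' @return named character vector usable as `role_map`.
#' @export
read_role_map <- function(path) {
    m <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
    out <- unlist(m)
    bad <- setdiff(names(out), STRUCTURE_ROLES)
    if (length(bad)) stop("unknown roles in mapping: ",
                          paste(bad, collapse = ", "))
    out
}

map_role <- function(name, role_map) {
    for (role in names(role_map))
        if (grepl(role_map[[role]], name, ignore.case = TRUE)) return(role)
    "OTHER"
}

read_rt_dose <- function(path) {
    ds <- dcm_read_file(path)
    modality <- dcm_string(ds, "0008,0060")
    if (!identical(modality, "RTDOSE"))
        stop_parse("expected an RT Dose object, found modality ", modality)
    units <- dcm_required(dcm_string(ds, "3004,0002"), "DoseUnits")
    if (toupper(units) != "GY")
        stop_parse("unsupported dose units '", units, "' (need GY)")
    iop <- dcm_required(dcm_numeric(ds, "0020,0037"),
                        "ImageOrientationPatient")
    if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
        stop_parse("only axis-aligned dose grids are supported")
    rows <- dcm_required(dcm_int_bin(ds, "0028,0010", 2), "Rows")
    cols <- dcm_required(dcm_int_bin(ds, "0028,0011", 2), "Columns")
    nframes <- as.integer(dcm_required(dcm_string(ds, "0028,0008"),
                                       "NumberOfFrames"))
    bits <- dcm_required(dcm_int_bin(ds, "0028,0100", 2), "BitsAllocated")
    ipp <- dcm_required(dcm_numeric(ds, "0020,0032"), "ImagePositionPatient")
    ps <- dcm_required(dcm_numeric(ds, "0028,0030"), "PixelSpacing")
    gfov <- dcm_required(dcm_numeric(ds, "3004,000C"),
                         "GridFrameOffsetVector")
    scaling <- dcm_required(dcm_numeric(ds, "3004,000E"), "DoseGridScaling")
    for_uid <- dcm_required(dcm_string(ds, "0020,0052"),
                            "FrameOfReferenceUID")
    dz <- diff(gfov)
    if (length(dz) == 0 || max(abs(dz - dz[1])) > 1e-6)
        stop_parse("dose grid frames are not uniformly spaced")
    px <- dcm_required(ds[["7FE0,0010"]], "PixelData")$raw
    nvox <- as.numeric(rows) * cols * nframes
    vals <- if (bits == 32) {
        lo <- readBin(px, "integer", n = nvox * 2, size = 2,
                      endian = "little", signed = FALSE)
        # assemble unsigned 32-bit values from two unsigned 16-bit halves
        as.numeric(lo[seq(1, length(lo), 2)]) +
            65536 * as.numeric(lo[seq(2, length(lo), 2)])
    } else if (bits == 16) {
        readBin(px, "integer", n = nvox, size = 2, endian = "little",
                signed = FALSE)
    } else stop_parse("unsupported BitsAllocated: ", bits)
    if (length(vals) < nvox) stop_parse("truncated PixelData")
    # pixel order: column (x) fastest, then row (y), then frame (z);
    # PixelSpacing is row spacing (y) first, column spacing (x) second
    grid <- dose_grid(origin = ipp, spacing = c(ps[2], ps[1], dz[1]),
                      dims = c(cols, rows, nframes),
                      dose = vals * scaling)
    list(grid = grid, frame_of_reference = for_uid)
}

read_rt_struct <- function(path) {
    ds <- dcm_read_file(path)
    modality <- dcm_string(ds, "0008,0060")
    if (!identical(modality, "RTSTRUCT"))
        stop_parse("expected an RT Structure Set, found modality ", modality)
    for_uid <- NULL
    ref <- ds[["3006,0010"]]
    if (!is.null(ref) && length(ref))
        for_uid <- dcm_string(ref[[1]], "0020,0052")
    rois <- dcm_required(ds[["3006,0020"]], "StructureSetROISequence")
    names_by_num <- list()
    for (item in rois) {
        num <- dcm_string(item, "3006,0022")
        names_by_num[[num]] <- dcm_string(item, "3006,0026")
    }
    contours <- dcm_required(ds[["3006,0039"]], "ROIContourSequence")
    structures <- list()
    for (item in contours) {
        num <- dcm_string(item, "3006,0084")
        nm <- names_by_num[[num]] %||% paste0("ROI", num)
        cs <- item[["3006,0040"]]
        polys <- list()
        for (ct in cs %||% list()) {
            gtype <- dcm_string(ct, "3006,0042")
            if (!is.null(gtype) && gtype != "CLOSED_PLANAR") next
            pts <- dcm_numeric(ct, "3006,0050")
            if (is.null(pts)) next
            polys[[length(polys) + 1L]] <-
                matrix(pts, ncol = 3, byrow = TRUE)
        }
        if (length(polys) == 0L)
            stop_parse("structure '", nm, "' has no contours")
        structures[[nm]] <- polys
    }
    list(structures = structures, frame_of_reference = for_uid)
}

#' Read a plan from DICOM RT Dose + RT Structure Set
#'
#' Reads the dose grid (rescaled by the dose-grid scaling attribute to Gy)
#' and rasterizes every contoured structure onto the dose lattice with the
#' configured rasterization policy. The two objects must reference the
#' same DICOM frame of reference. Structure roles are assigned by the
#' (configurable) name mapping; unmatched structures become `OTHER` and
#' are dropped unless `keep_other`.
#'
#' @param dose_path RT Dose file.
#' @param struct_path RT Structure Set file.
#' @param role_map named character vector role -> regex, see
#'   [default_role_map()].
#' @param mode rasterization policy, `"fractional"` (3^2 in-plane
#'   supersampling) or `"binary"` (voxel centres only).
#' @param meta a [plan_meta()] for the resulting plan.
#' @param keep_other keep unmapped structures under role `OTHER`?
#' @return an [sbrt_plan()].
#' @export
read_dicom_rt <- function(dose_path, struct_path,
                          role_map = default_role_map(),
                          mode = c("fractional", "binary"),
                          meta = plan_meta("dicom", "MOD", "MC"),
                          keep_other = FALSE) {
    mode <- match.arg(mode)
    dose <- read_rt_dose(dose_path)
    ss <- read_rt_struct(struct_path)
    if (is.null(dose$frame_of_reference) || is.null(ss$frame_of_reference))
        stop_parse("missing frame-of-reference linkage")
    if (!identical(dose$frame_of_reference, ss$frame_of_reference))
        stop_parse("RT Dose and RT Structure Set reference different frames",
                   " of reference (", dose$frame_of_reference, " vs ",
                   ss$frame_of_reference, ")")
    g <- dose$grid
    masks <- list()
    for (nm in names(ss$structures)) {
        role <- map_role(nm, role_map)
        if (role == "OTHER" && !keep_other) next
        occ <- rasterize_contours(ss$structures[[nm]], g$origin, g$spacing,
                                  g$dims, mode = mode)
        masks[[role]] <- structure_mask(nm, role, occ, g$origin, g$spacing,
                                       g$dims)
    }
    sbrt_plan(g, masks, meta)
}
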