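# Stand-alone DICOM writer used to build synthetic RT Dose / RT Structure
# Set fixtures at test time (explicit VR little endian). Written directly
# from the encoding rules, independent of the package's reader, so the two
# cross-validate each other; the rasterized volumes are additionally
# checked against analytic phantom volumes.

r_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
r_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                              endian = "little")

dcm_el <- function(group, elem, vr, value) {
    if (is.character(value)) {
        value <- charToRaw(value)
        if (length(value) %% 2 == 1)
            value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
    }
    stopifnot(is.raw(value))
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT"))
        c(r_u16(group), r_u16(elem), charToRaw(vr), as.raw(c(0, 0)),
          r_u32(length(value)), value)
    else
        c(r_u16(group), r_u16(elem), charToRaw(vr), r_u16(length(value)),
          value)
}

dcm_item <- function(content) {
    c(r_u16(0xFFFE), r_u16(0xE000), r_u32(length(content)), content)
}

dcm_file <- function(elements, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(rep(as.raw(0), 128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(do.call(c, elements), con)
    invisible(path)
}

ds_str <- function(x) paste(formatC(x, format = "fg", digits = 10),
                            collapse = "\\")

write_rt_dose <- function(path, dose, origin, spacing, dims,
                          for_uid = "1.2.3.4", scaling = 1e-4) {
    ints <- as.integer(round(dose / scaling))
    px <- writeBin(ints, raw(), size = 4, endian = "little")
    dcm_file(list(
        dcm_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
        dcm_el(0x0008, 0x0060, "CS", "RTDOSE"),
        dcm_el(0x0020, 0x0032, "DS", ds_str(origin)),
        dcm_el(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
        dcm_el(0x0020, 0x0052, "UI", for_uid),
        dcm_el(0x0028, 0x0002, "US", r_u16(1)),
        dcm_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
        dcm_el(0x0028, 0x0008, "IS", as.character(dims[3])),
        dcm_el(0x0028, 0x0010, "US", r_u16(dims[2])),
        dcm_el(0x0028, 0x0011, "US", r_u16(dims[1])),
        dcm_el(0x0028, 0x0030, "DS", ds_str(c(spacing[2], spacing[1]))),
        dcm_el(0x0028, 0x0100, "US", r_u16(32)),
        dcm_el(0x0028, 0x0101, "US", r_u16(32)),
        dcm_el(0x0028, 0x0102, "US", r_u16(31)),
        dcm_el(0x0028, 0x0103, "US", r_u16(0)),
        dcm_el(0x3004, 0x0002, "CS", "GY"),
        dcm_el(0x3004, 0x000C, "DS",
               ds_str((seq_len(dims[3]) - 1) * spacing[3])),
        dcm_el(0x3004, 0x000E, "DS", ds_str(scaling)),
        dcm_el(0x7FE0, 0x0010, "OW", px)), path)
}

# contours: named list; each element a list of n x 3 vertex matrices
write_rt_struct <- function(path, contours, for_uid = "1.2.3.4") {
    roi_items <- list(); con_items <- list()
    for (i in seq_along(contours)) {
        nm <- names(contours)[i]
        roi_items[[i]] <- dcm_item(c(
            dcm_el(0x3006, 0x0022, "IS", as.character(i)),
            dcm_el(0x3006, 0x0026, "LO", nm)))
        polys <- lapply(contours[[i]], function(m) dcm_item(c(
            dcm_el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
            dcm_el(0x3006, 0x0046, "IS", as.character(nrow(m))),
            dcm_el(0x3006, 0x0050, "DS", ds_str(as.vector(t(m)))))))
        con_items[[i]] <- dcm_item(c(
            dcm_el(0x3006, 0x0040, "SQ",
                   if (length(polys)) do.call(c, polys) else raw(0)),
            dcm_el(0x3006, 0x0084, "IS", as.character(i))))
    }
    dcm_file(list(
        dcm_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
        dcm_el(0x0008, 0x0060, "CS", "RTSTRUCT"),
        dcm_el(0x3006, 0x0010, "SQ",
               dcm_item(dcm_el(0x0020, 0x0052, "UI", for_uid))),
        dcm_el(0x3006, 0x0020, "SQ", do.call(c, roi_items)),
        dcm_el(0x3006, 0x0039, "SQ", do.call(c, con_items))), path)
}

# polygonal approximation of an axis-aligned ellipsoid: one closed contour
# per lattice slice the ellipsoid crosses
ellipsoid_contours <- function(center, semi, spacing_z, z_range,
                               n_vertices = 48) {
    zs <- seq(z_range[1], z_range[2], by = spacing_z)
    out <- list()
    for (z in zs) {
        t <- (z - center[3]) / semi[3]
        if (abs(t) >= 0.999) next
        f <- sqrt(1 - t^2)
        th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
        out[[length(out) + 1L]] <- cbind(center[1] + semi[1] * f * cos(th),
                                         center[2] + semi[2] * f * sin(th),
                                         z)
    }
    out
}
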