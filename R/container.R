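# Single-file plan container: a self-describing text header followed by raw
# little-endian float64 arrays (dose first, then one occupancy array per
# structure, in header order). Layout:
#
#   SBRTBENCH-PLAN v1\n
#   origin: <x> <y> <z>\n          (mm, full precision)
#   spacing: <x> <y> <z>\n
#   dims: <nx> <ny> <nz>\n
#   institution_id: ...\n
#   technique: ...\n
#   algorithm: ...\n
#   calc_grid_mm: ...\n
#   mlc_width_mm: ...\n            ("NA" for cone-based delivery)
#   energy_label: ...\n
#   structures: <n>\n
#   structure: <role>\t<name>\n    (n lines)
#   END-HEADER\n
#   <prod(dims) float64 dose values, little endian>
#   <prod(dims) float64 occupancy values per structure>

fmt_num <- function(x) paste(formatC(x, format = "g", digits = 17),
                             collapse = " ")

#' Write a plan to the internal single-file container
#'
#' @param plan an [sbrt_plan()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_plan()]
#' @export
write_plan <- function(plan, path) {
    stopifnot(inherits(plan, "sbrt_plan"))
    m <- plan$meta
    hdr <- c("SBRTBENCH-PLAN v1",
             paste("origin:", fmt_num(plan$grid$origin)),
             paste("spacing:", fmt_num(plan$grid$spacing)),
             paste("dims:", paste(plan$grid$dims, collapse = " ")),
             paste("institution_id:", m$institution_id),
             paste("technique:", m$technique),
             paste("algorithm:", m$algorithm),
             paste("calc_grid_mm:", fmt_num(m$calc_grid_mm)),
             paste("mlc_width_mm:",
                   if (is.na(m$mlc_width_mm)) "NA" else fmt_num(m$mlc_width_mm)),
             paste("energy_label:", m$energy_label),
             paste("structures:", length(plan$structures)),
             vapply(plan$structures, function(s)
                 paste0("structure: ", s$role, "\t", s$name), ""),
             "END-HEADER")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.numeric(plan$grid$dose), con, size = 8, endian = "little")
    for (s in plan$structures)
        writeBin(as.numeric(s$occupancy), con, size = 8, endian = "little")
    invisible(path)
}

hdr_field <- function(lines, key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (length(hit) != 1L) stop_parse("missing or duplicated header field '",
                                      key, "'")
    sub(paste0("^", key, ": "), "", hit)
}

#' Read a plan from the internal single-file container
#'
#' `read_plan()` and [write_plan()] round-trip every field exactly (metadata
#' bit-level, arrays to full float64 precision). Files violating the
#' container invariants (occupancy outside `[0, 1]`, truncated payload,
#' malformed header) are rejected.
#'
#' @param path file written by [write_plan()].
#' @return an [sbrt_plan()].
#' @export
read_plan <- function(path) {
    if (!file.exists(path)) stop_parse("no such file: ", path)
    raw <- readBin(path, "raw", n = file.size(path))
    marker <- charToRaw("END-HEADER\n")
    pos <- find_raw(raw, marker)
    if (is.na(pos)) stop_parse("malformed header: END-HEADER marker missing")
    hdr <- strsplit(rawToChar(raw[seq_len(pos - 1L)]), "\n", fixed = TRUE)[[1]]
    if (!identical(hdr[1], "SBRTBENCH-PLAN v1"))
        stop_parse("not an sbrtbench plan container")
    origin <- scan(text = hdr_field(hdr, "origin"), quiet = TRUE)
    spacing <- scan(text = hdr_field(hdr, "spacing"), quiet = TRUE)
    dims <- as.integer(scan(text = hdr_field(hdr, "dims"), quiet = TRUE))
    nstr <- as.integer(hdr_field(hdr, "structures"))
    strl <- grep("^structure: ", hdr, value = TRUE)
    if (length(strl) != nstr) stop_parse("structure table length mismatch")
    mlc <- hdr_field(hdr, "mlc_width_mm")
    meta <- plan_meta(hdr_field(hdr, "institution_id"),
                      hdr_field(hdr, "technique"),
                      hdr_field(hdr, "algorithm"),
                      as.numeric(hdr_field(hdr, "calc_grid_mm")),
                      if (mlc == "NA") NA_real_ else as.numeric(mlc),
                      hdr_field(hdr, "energy_label"))
    nvox <- prod(dims)
    need <- 8 * nvox * (1 + nstr)
    payload <- raw[(pos + length(marker)):length(raw)]
    if (length(payload) < need)
        stop_parse("truncated array payload: expected ", need, " bytes, got ",
                   length(payload))
    vals <- readBin(payload, "numeric", n = nvox * (1 + nstr), size = 8,
                    endian = "little")
    grid <- dose_grid(origin, spacing, dims, vals[seq_len(nvox)])
    structures <- list()
    for (i in seq_len(nstr)) {
        parts <- strsplit(sub("^structure: ", "", strl[i]), "\t",
                          fixed = TRUE)[[1]]
        occ <- vals[nvox * i + seq_len(nvox)]
        structures[[parts[1]]] <- structure_mask(parts[2], parts[1], occ,
                                                 origin, spacing, dims)
    }
    sbrt_plan(grid, structures, meta)
}

# position of the first occurrence of `pattern` in raw vector `x`, or NA
find_raw <- function(x, pattern) {
    hits <- which(x == pattern[1])
    for (p in hits) {
        if (p + length(pattern) - 1L > length(x)) next
        if (identical(x[p:(p + length(pattern) - 1L)], pattern)) return(p)
    }
    NA_integer_
}
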