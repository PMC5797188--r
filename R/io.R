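# I/O for the standard formats the pipeline touches.  No TIFF/NRRD package
# exists in the supported R stack, so both formats are implemented here at
# the minimal level the pipeline needs: baseline TIFF (uncompressed,
# grayscale, 8-bit unsigned or 32-bit float, multi-page) and NRRD with raw
# little-endian encoding.

# ---- NRRD -----------------------------------------------------------------

nrrd_type <- function(data) {
  if (is.integer(data) || (is.numeric(data) &&
                           all(data == round(data)) &&
                           min(data) >= 0 && max(data) <= 255)) "uint8"
  else "double"
}

#' Write a volume or displacement field as NRRD
#'
#' Scalar volumes are written as 3D NRRD, 3-vector fields as 4D NRRD with a
#' leading vector axis.  Encoding is raw, little-endian.
#'
#' @param data 3D array (scalar volume) or 4D array with last axis length 3
#'   (a vector field sampled on a grid; it is stored vector-axis-first).
#' @param path output path.
#' @param spacing,origin grid geometry in micron.
#' @param type `"uint8"`, `"float"` or `"double"`; default inferred.
#' @export
write_nrrd <- function(data, path, spacing, origin = c(0, 0, 0),
                       type = NULL) {
  d <- dim(data)
  vector_field <- length(d) == 4L
  if (vector_field && d[4] != 3L) stop("vector field must have 3 components")
  if (is.null(type)) type <- if (vector_field) "double" else nrrd_type(data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste("type:", type),
           paste("dimension:", if (vector_field) 4 else 3),
           paste("sizes:", if (vector_field)
             paste(3, d[1], d[2], d[3]) else paste(d[1], d[2], d[3])),
           "encoding: raw",
           "endian: little",
           "space dimension: 3",
           paste0("space directions: ", if (vector_field) "none " else "",
                  sprintf("(%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
                          spacing[1], spacing[2], spacing[3])),
           sprintf("space origin: (%.10g,%.10g,%.10g)",
                   origin[1], origin[2], origin[3]),
           paste("kinds:", if (vector_field) "vector domain domain domain"
                 else "domain domain domain"),
           "")
  writeLines(hdr, con, sep = "\n")
  vals <- if (vector_field) as.numeric(aperm(data, c(4, 1, 2, 3)))
          else as.numeric(data)
  if (type == "uint8") {
    writeBin(as.integer(round(vals)), con, size = 1)
  } else if (type == "float") {
    writeBin(vals, con, size = 4, endian = "little")
  } else {
    writeBin(vals, con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a NRRD volume or displacement field
#'
#' @param path NRRD file written by [write_nrrd()] or a compatible tool
#'   (raw encoding, little endian).
#' @return list with `data` (3D array, or 4D array with trailing vector
#'   axis), `spacing`, `origin`.
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop(path, " is not a NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  ndim <- as.integer(fields$dimension)
  type <- fields$type
  enc <- fields$encoding
  if (!identical(enc, "raw")) stop("unsupported NRRD encoding: ", enc)
  n <- prod(sizes)
  vals <- switch(type,
    uint8 = , uchar = as.numeric(readBin(con, "integer", n = n, size = 1,
                                         signed = FALSE)),
    float = readBin(con, "double", n = n, size = 4, endian = "little"),
    double = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NRRD type: ", type))
  if (length(vals) < n)
    stop("truncated NRRD data in ", path, ": expected ", n, " values, got ",
         length(vals))
  dirs <- regmatches(fields[["space directions"]],
                     gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
  mats <- lapply(dirs, function(s)
    as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]))
  spacing <- vapply(seq_along(mats), function(i) mats[[i]][i], 0)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  if (ndim == 3L) {
    data <- array(vals, dim = sizes)
  } else if (ndim == 4L && sizes[1] == 3L) {
    data <- aperm(array(vals, dim = sizes), c(2, 3, 4, 1))
  } else stop("unsupported NRRD dimension layout")
  list(data = data, spacing = spacing, origin = origin)
}

# ---- minimal baseline TIFF ------------------------------------------------

tiff_pack_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                      endian = "little")
tiff_pack_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                      endian = "little")

tiff_entry <- function(tag, type, count, value_raw) {
  # value_raw must already be exactly 4 bytes (inline) -- offsets included
  c(tiff_pack_u16(tag), tiff_pack_u16(type), tiff_pack_u32(count), value_raw)
}

#' Write a volume as a multi-page grayscale TIFF
#'
#' Baseline TIFF, uncompressed, one page per z slice; 8-bit data written as
#' unsigned bytes, everything else as 32-bit float.  In-plane spacing is
#' stored in the X/Y resolution tags and the slice spacing in an
#' ImageJ-style description, so [read_stack()] can recover the full voxel
#' geometry.
#'
#' @param img a `volumetric_image`.
#' @param path output path (.tif / .tiff).
#' @export
write_tiff_stack <- function(img, path) {
  d <- dim(img$data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  eight_bit <- all(img$data == round(img$data)) && min(img$data) >= 0 &&
    max(img$data) <= 255
  bps <- if (eight_bit) 8L else 32L
  fmt <- if (eight_bit) 1L else 3L
  page_bytes <- nx * ny * (bps / 8L)

  desc <- sprintf("ImageJ=1.53\nimages=%d\nslices=%d\nunit=micron\nspacing=%.9g\n",
                  nz, nz, img$spacing[3])
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  rational <- function(res) {
    # pixels per micron = 1 / spacing, as num/denom
    c(tiff_pack_u32(round(res * 1e6)), tiff_pack_u32(1e6))
  }

  data_off <- 8L
  desc_off <- data_off + nz * page_bytes
  xres_off <- desc_off + length(desc_raw)
  yres_off <- xres_off + 8L
  ifd0_off <- yres_off + 8L

  n_entries <- function(first) if (first) 13L else 12L
  ifd_size <- function(first) 2L + n_entries(first) * 12L + 4L
  ifd_offsets <- integer(nz)
  off <- ifd0_off
  for (k in seq_len(nz)) {
    ifd_offsets[k] <- off
    off <- off + ifd_size(k == 1L)
  }

  short_val <- function(v) c(tiff_pack_u16(v), tiff_pack_u16(0))
  make_ifd <- function(k) {
    first <- k == 1L
    strip_off <- data_off + (k - 1L) * page_bytes
    e <- list(
      tiff_entry(256, 4, 1, tiff_pack_u32(nx)),
      tiff_entry(257, 4, 1, tiff_pack_u32(ny)),
      tiff_entry(258, 3, 1, short_val(bps)),
      tiff_entry(259, 3, 1, short_val(1)),
      tiff_entry(262, 3, 1, short_val(1)))
    if (first)
      e <- c(e, list(tiff_entry(270, 2, length(desc_raw),
                                tiff_pack_u32(desc_off))))
    e <- c(e, list(
      tiff_entry(273, 4, 1, tiff_pack_u32(strip_off)),
      tiff_entry(277, 3, 1, short_val(1)),
      tiff_entry(278, 4, 1, tiff_pack_u32(ny)),
      tiff_entry(279, 4, 1, tiff_pack_u32(page_bytes)),
      tiff_entry(282, 5, 1, tiff_pack_u32(xres_off)),
      tiff_entry(283, 5, 1, tiff_pack_u32(yres_off)),
      tiff_entry(339, 3, 1, short_val(fmt))))
    nxt <- if (k < nz) ifd_offsets[k + 1L] else 0L
    c(tiff_pack_u16(length(e)), do.call(c, e), tiff_pack_u32(nxt))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42, 0))), con)
  writeBin(tiff_pack_u32(ifd_offsets[1]), con)
  vals <- as.numeric(img$data)
  if (eight_bit) writeBin(as.integer(vals), con, size = 1)
  else writeBin(vals, con, size = 4, endian = "little")
  writeBin(desc_raw, con)
  writeBin(rational(1 / img$spacing[1]), con)
  writeBin(rational(1 / img$spacing[2]), con)
  for (k in seq_len(nz)) writeBin(make_ifd(k), con)
  invisible(path)
}

read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw_all[off + 1:4]) *
                             c(1, 256, 65536, 16777216))
  if (rawToChar(raw_all[1:2]) != "II")
    stop("only little-endian TIFF is supported: ", path)
  if (u16(2) != 42) stop(path, " is not a TIFF file")
  ifd_off <- u32(4)
  pages <- list()
  xres <- yres <- NA_real_
  zspacing <- NA_real_
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (t in seq_len(n)) {
      base <- ifd_off + 2 + (t - 1) * 12
      tag <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
      val <- if (type == 3 && count == 1) u16(base + 8) else u32(base + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count, val = val)
    }
    g <- function(tag, default = NULL) {
      e <- tags[[as.character(tag)]]
      if (is.null(e)) default else e$val
    }
    if (g(259, 1) != 1) stop("compressed TIFF is not supported: ", path)
    nx <- g(256); ny <- g(257); bps <- g(258, 8); fmt <- g(339, 1)
    # strip offsets / byte counts (possibly arrays)
    read_longs <- function(tag) {
      e <- tags[[as.character(tag)]]
      if (is.null(e)) stop("TIFF missing tag ", tag, " in ", path)
      if (e$count == 1) return(e$val)
      sz <- if (e$type == 3) 2 else 4
      off <- e$val
      vapply(seq_len(e$count), function(i)
        if (sz == 2) u16(off + (i - 1) * 2) else u32(off + (i - 1) * 4), 0)
    }
    offs <- read_longs(273)
    cnts <- read_longs(279)
    if (max(offs + cnts) > length(raw_all))
      stop("truncated TIFF data in ", path)
    bytes <- unlist(lapply(seq_along(offs), function(i)
      raw_all[(offs[i] + 1):(offs[i] + cnts[i])]), use.names = FALSE)
    vals <- if (bps == 8 && fmt == 1) {
      as.numeric(as.integer(bytes))
    } else if (bps == 32 && fmt == 3) {
      readBin(as.raw(bytes), "double", n = length(bytes) / 4, size = 4,
              endian = "little")
    } else stop("unsupported TIFF pixel type (bits ", bps, ", format ",
                fmt, ") in ", path)
    if (length(vals) != nx * ny) stop("short page data in ", path)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = nx, ncol = ny)
    rat <- function(tag) {
      e <- tags[[as.character(tag)]]
      if (is.null(e)) return(NA_real_)
      u32(e$val) / u32(e$val + 4)
    }
    if (is.na(xres)) { xres <- rat(282); yres <- rat(283) }
    e <- tags[["270"]]
    if (!is.null(e) && is.na(zspacing)) {
      txt <- rawToChar(raw_all[(e$val + 1):(e$val + e$count - 1)])
      m <- regmatches(txt, regexec("spacing=([0-9.eE+-]+)", txt))[[1]]
      if (length(m) == 2) zspacing <- as.numeric(m[2])
    }
    ifd_off <- u32(ifd_off + 2 + n * 12)
  }
  if (length(pages) < 2L)
    stop("2D-only TIFF (", length(pages),
         " page): a volume needs at least 2 slices: ", path)
  data <- array(unlist(pages, use.names = FALSE),
                dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  spacing <- c(if (is.finite(xres) && xres > 0) 1 / xres else NA_real_,
               if (is.finite(yres) && yres > 0) 1 / yres else NA_real_,
               zspacing)
  list(data = data, spacing = spacing)
}

# ---- read_stack / write_stack --------------------------------------------

#' Read a 3D image stack
#'
#' Dispatches on extension: `.tif`/`.tiff` (multi-page grayscale TIFF) or
#' `.nrrd`.  Voxel spacing comes from file metadata; if the file carries
#' none it must be supplied, otherwise an error is raised.
#'
#' @param path input file.
#' @param spacing optional numeric length-3 spacing (micron) overriding /
#'   supplying file metadata.
#' @param channel_label channel tag for the returned image.
#' @param origin physical origin, micron.
#' @return a `volumetric_image`.
#' @export
read_stack <- function(path, spacing = NULL, channel_label = "other",
                       origin = c(0, 0, 0)) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    r <- read_tiff_stack(path)
    if (is.null(spacing)) spacing <- r$spacing
    if (any(!is.finite(spacing)))
      stop("no voxel spacing in TIFF metadata of ", path,
           "; pass spacing = c(sx, sy, sz)")
    volumetric_image(r$data, spacing, origin, channel_label)
  } else if (ext == "nrrd") {
    r <- read_nrrd(path)
    if (length(dim(r$data)) != 3L)
      stop(path, " is not a scalar volume")
    volumetric_image(r$data, if (is.null(spacing)) r$spacing else spacing,
                     r$origin, channel_label)
  } else stop("unsupported image format: .", ext)
}

#' Write a 3D image stack
#'
#' Counterpart of [read_stack()]; 8-bit data stays 8-bit (no silent cast).
#' @param img a `volumetric_image`.
#' @param path output file, `.tif`/`.tiff` or `.nrrd`.
#' @export
write_stack <- function(img, path) {
  stopifnot(is_volumetric_image(img))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) write_tiff_stack(img, path)
  else if (ext == "nrrd") write_nrrd(img$data, path, img$spacing, img$origin)
  else stop("unsupported image format: .", ext)
  invisible(path)
}

# ---- landmarks ------------------------------------------------------------

#' Read a landmark table
#'
#' Comma-separated `label,x_um,y_um,z_um` with one header line; order is
#' preserved.  An empty table (header only) yields an empty set.
#' @param path CSV file.
#' @param frame_id frame the points live in.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path, frame_id = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "x_um", "y_um", "z_um") %in% names(df)))
    stop("landmark file must have columns label,x_um,y_um,z_um: ", path)
  if (nrow(df) == 0L) return(landmark_set(character(0),
                                          matrix(numeric(0), 0, 3), frame_id))
  coords <- as.matrix(df[, c("x_um", "y_um", "z_um")])
  if (!is.numeric(coords) || any(!is.finite(coords)))
    stop("non-numeric landmark coordinates in ", path)
  landmark_set(df$label, coords, frame_id)
}

#' Write a landmark table
#' @param set a `landmark_set`.
#' @param path output CSV.
#' @export
write_landmarks <- function(set, path) {
  df <- data.frame(label = set$label, x_um = set$x, y_um = set$y,
                   z_um = set$z)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Import a Fiji point-list text file
#'
#' Accepts the plain-text point lists exported by Fiji landmark tools:
#' whitespace- or tab-separated rows of either `label x y z` or `x y z`
#' (auto-labelled `P1`, `P2`, ...).  Lines starting with `#` and a
#' non-numeric header row are skipped.  Coordinates are taken as micron.
#'
#' @param path text file.
#' @param frame_id frame the points live in.
#' @return a `landmark_set`.
#' @export
import_fiji_points <- function(path, frame_id = "unknown") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  labels <- character(0)
  coords <- NULL
  auto <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "[,\t ]+")[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    if (length(parts) >= 4 && all(!is.na(nums[(length(parts) - 2):length(parts)]))) {
      xyz <- nums[(length(parts) - 2):length(parts)]
      lab <- paste(parts[seq_len(length(parts) - 3)], collapse = " ")
      if (is.na(suppressWarnings(as.numeric(lab))) == FALSE) lab <- NA
    } else if (length(parts) == 3 && all(!is.na(nums))) {
      xyz <- nums
      lab <- NA
    } else next  # header / junk line
    if (is.na(lab) || !nzchar(lab)) {
      auto <- auto + 1L
      lab <- paste0("P", auto)
    }
    labels <- c(labels, lab)
    coords <- rbind(coords, xyz)
  }
  if (is.null(coords)) coords <- matrix(numeric(0), 0, 3)
  landmark_set(labels, coords, frame_id)
}

# ---- QA report JSON -------------------------------------------------------

#' Write a QA report as JSON
#' @param report a `qa_report`.
#' @param path output path.
#' @export
write_qa_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a QA report from JSON
#' @param path JSON written by [write_qa_report()].
#' @return a `qa_report`.
#' @export
read_qa_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  qa_report(x$scan_id, x$vi, x$ti, x$m_score, x$s_score, x$threshold)
}
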