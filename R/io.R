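# Frame and mask I/O. Frames are plain numeric matrices (H x W) with
# intensities in [0, 1]; masks are integer label matrices with
# 0 = background, 1 = LV, 2 = RV, 3 = RA. Frames are stored as 8-bit
# grayscale PNG, masks as 8-bit PNG carrying the label values directly.

MASK_LABELS <- c(LV = 1L, RV = 2L, RA = 3L)

#' Read a grayscale frame from PNG or DICOM
#'
#' PNG pixel values are rescaled by the file's bit depth (255 or 65535) to
#' `[0, 1]`. DICOM frames (uncompressed little-endian, monochrome) are
#' rescaled per image from their stored min/max, which accommodates
#' heterogeneous multi-center acquisitions. Multi-frame DICOM cine loops
#' require an explicit `frame_index`; there is no silent first-frame default.
#'
#' @param path Path to a `.png` or `.dcm` file.
#' @param frame_index 1-based frame number for multi-frame DICOM.
#' @param convert_rgb If `TRUE`, RGB PNGs are converted to luminance;
#'   otherwise an RGB input is an error.
#' @return Numeric matrix in `[0, 1]` with attributes `source_path`,
#'   `bit_depth` and `original_size`.
#' @export
read_frame <- function(path, frame_index = NULL, convert_rgb = FALSE) {
  if (!file.exists(path)) cs_abort(paste0("file not found: ", path), "cs_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    bit_depth <- 8L
    if (length(dim(px)) == 3L) {
      if (dim(px)[3] >= 3L && !convert_rgb)
        cs_abort("RGB PNG: pass convert_rgb = TRUE to convert to luminance",
                 "cs_io_error")
      if (dim(px)[3] >= 3L)
        px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
      else px <- px[, , 1]
    }
    frame <- as.matrix(px)
  } else if (ext %in% c("dcm", "dicom", "ima") || is_dicom_file(path)) {
    d <- read_dicom_minimal(path)
    if (d$n_frames > 1L && is.null(frame_index))
      cs_abort("multi-frame DICOM: an explicit frame_index is required",
               "cs_io_error")
    idx <- frame_index %||% 1L
    if (idx < 1L || idx > d$n_frames)
      cs_abort("frame_index out of range", "cs_io_error")
    frame <- d$frames[[idx]]
    rng <- range(frame)
    frame <- if (rng[2] > rng[1]) (frame - rng[1]) / (rng[2] - rng[1]) else frame * 0
    bit_depth <- d$bits
  } else {
    cs_abort(paste0("unsupported image format: ", path), "cs_io_error")
  }
  attr(frame, "source_path") <- path
  attr(frame, "bit_depth") <- bit_depth
  attr(frame, "original_size") <- dim(frame)
  frame
}

#' Write a frame as 8-bit grayscale PNG
#'
#' Intensities are clipped to `[0, 1]` and quantized to 8 bits.
#' @param frame Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  x <- pmin(pmax(unclass(frame), 0), 1)
  attributes(x) <- list(dim = dim(frame))
  png::writePNG(round(x * 255) / 255, path)
  invisible(path)
}

#' Read / write a chamber label mask
#'
#' Masks are 8-bit PNGs whose pixel values are the label codes
#' 0 = background, 1 = LV, 2 = RV, 3 = RA.
#' @param path PNG path.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  m <- matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
  if (any(m > 3L)) cs_abort("mask PNG contains values outside labels 0..3",
                            "cs_io_error")
  m
}

#' @rdname read_mask
#' @param mask Integer label matrix with values in 0..3.
#' @export
write_mask <- function(mask, path) {
  stopifnot(all(mask %in% 0:3))
  png::writePNG(matrix(mask / 255, nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Extract per-chamber binary masks from a label matrix
#'
#' @param mask Integer label matrix.
#' @param view `"SAX"` (chambers LV, RV) or `"LAX"` (LV, RV, RA).
#' @return Named list of logical matrices, one per chamber of the view.
#' @export
chamber_masks <- function(mask, view) {
  ch <- chambers_for_view(view)
  out <- lapply(ch, function(nm) mask == MASK_LABELS[[nm]])
  names(out) <- ch
  out
}

chambers_for_view <- function(view) {
  view <- toupper(view)
  if (view == "SAX") c("LV", "RV")
  else if (view == "LAX") c("LV", "RV", "RA")
  else cs_abort(paste0("unknown view: ", view), "cs_view_error")
}

# ---- resampling --------------------------------------------------------------

# Bilinear sample of img at continuous (row, col) positions (0-based pixel
# centers); out-of-range coordinates clamp to the border.
sample_bilinear <- function(img, rr, cc) {
  h <- nrow(img); w <- ncol(img)
  rr <- pmin(pmax(rr, 0), h - 1)
  cc <- pmin(pmax(cc, 0), w - 1)
  r0 <- floor(rr); c0 <- floor(cc)
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- rr - r0; fc <- cc - c0
  idx <- function(r, c) img[cbind(r + 1, c + 1)]
  (1 - fr) * (1 - fc) * idx(r0, c0) + fr * (1 - fc) * idx(r1, c0) +
    (1 - fr) * fc * idx(r0, c1) + fr * fc * idx(r1, c1)
}

sample_nearest <- function(img, rr, cc) {
  h <- nrow(img); w <- ncol(img)
  r <- pmin(pmax(round(rr), 0), h - 1)
  c <- pmin(pmax(round(cc), 0), w - 1)
  img[cbind(r + 1, c + 1)]
}

#' Resize a frame with bilinear resampling
#'
#' Output pixel centers are mapped to input continuous coordinates
#' (half-pixel-centered), so resizing to the input size is the identity.
#'
#' @param frame Numeric matrix in `[0, 1]`.
#' @param resolution Target side length; must be a power of two.
#' @return Resized matrix with intensities still in `[0, 1]`.
#' @export
resize_frame <- function(frame, resolution) {
  if (!is_pow2(resolution))
    cs_abort("target resolution must be a power of two", "cs_resolution_error")
  h <- nrow(frame); w <- ncol(frame)
  if (h == resolution && w == resolution) return(frame)
  g <- seq_len(resolution) - 1
  rr <- (g + 0.5) * h / resolution - 0.5
  cc <- (g + 0.5) * w / resolution - 0.5
  grid_r <- matrix(rep(rr, resolution), resolution, resolution)
  grid_c <- matrix(rep(cc, each = resolution), resolution, resolution)
  out <- matrix(sample_bilinear(frame, as.vector(grid_r), as.vector(grid_c)),
                resolution, resolution)
  pmin(pmax(out, 0), 1)
}

# ---- manifests ---------------------------------------------------------------

#' Write / read a dataset manifest
#'
#' A manifest is a CSV with columns `frame`, `mask`, `view`, `seed` holding
#' paths relative to the manifest's directory.
#' @param manifest Data frame with the manifest columns.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, c("frame", "mask", "view", "seed")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) cs_abort(paste0("manifest not found: ", path), "cs_io_error")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(m)
}

# Load all (frame, mask) pairs referenced by a manifest.
load_pairs <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    list(frame = read_frame(file.path(base, man$frame[i])),
         mask = read_mask(file.path(base, man$mask[i])),
         view = man$view[i], seed = man$seed[i])
  })
}

# ---- minimal DICOM reader ----------------------------------------------------

is_dicom_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132)
  length(hdr) == 132 && rawToChar(hdr[129:132]) == "DICM"
}

# DICOM strings are padded with trailing spaces or NUL bytes
dicom_str <- function(v) {
  while (length(v) && v[length(v)] %in% as.raw(c(0L, 32L))) v <- v[-length(v)]
  rawToChar(v)
}

# Reads uncompressed little-endian (implicit or explicit VR) monochrome DICOM.
read_dicom_minimal <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 140 || rawToChar(raw_all[129:132]) != "DICM")
    cs_abort("not a DICOM file (missing DICM magic)", "cs_io_error")
  u16 <- function(i) as.integer(raw_all[i]) + 256L * as.integer(raw_all[i + 1])
  u32 <- function(i) as.numeric(raw_all[i]) + 256 * as.numeric(raw_all[i + 1]) +
    65536 * as.numeric(raw_all[i + 2]) + 16777216 * as.numeric(raw_all[i + 3])
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

  tags <- list()
  pos <- 133
  explicit <- TRUE
  ts <- NULL
  meta_end <- Inf
  repeat {
    if (pos + 7 > length(raw_all)) break
    grp <- u16(pos); ele <- u16(pos + 2)
    in_meta <- grp == 2L
    if (!in_meta && pos > meta_end && !is.null(ts))
      explicit <- ts != "1.2.840.10008.1.2"
    exp_here <- if (in_meta) TRUE else explicit
    if (exp_here) {
      vr <- rawToChar(raw_all[(pos + 4):(pos + 5)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8); hdr <- 12
      } else {
        len <- u16(pos + 6); hdr <- 8
      }
    } else {
      len <- u32(pos + 4); hdr <- 8
    }
    key <- sprintf("%04x,%04x", grp, ele)
    val_start <- pos + hdr
    if (len > 0 && val_start + len - 1 <= length(raw_all))
      tags[[key]] <- raw_all[val_start:(val_start + len - 1)]
    if (key == "0002,0010") ts <- dicom_str(tags[[key]])
    if (key == "0002,0000") meta_end <- pos + hdr + len + u32(val_start) - 1
    pos <- val_start + len
    if (key == "7fe0,0010") break
  }
  if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    cs_abort(paste0("unsupported DICOM transfer syntax: ", ts), "cs_io_error")

  dec_us <- function(key, default = NULL) {
    v <- tags[[key]]
    if (is.null(v)) return(default)
    as.integer(v[1]) + 256L * as.integer(v[2])
  }
  dec_str <- function(key, default = NULL) {
    v <- tags[[key]]
    if (is.null(v)) return(default)
    dicom_str(v)
  }
  rows <- dec_us("0028,0010"); cols <- dec_us("0028,0011")
  bits <- dec_us("0028,0100", 16L)
  n_frames <- as.integer(dec_str("0028,0008", "1"))
  photo <- dec_str("0028,0004", "MONOCHROME2")
  if (is.null(rows) || is.null(cols) || is.null(tags[["7fe0,0010"]]))
    cs_abort("DICOM missing Rows/Columns/PixelData", "cs_io_error")
  if (!grepl("^MONOCHROME", photo))
    cs_abort(paste0("unsupported photometric interpretation: ", photo), "cs_io_error")

  px_raw <- tags[["7fe0,0010"]]
  vals <- if (bits <= 8) {
    as.numeric(px_raw)
  } else {
    i <- seq(1, length(px_raw), 2)
    as.numeric(px_raw[i]) + 256 * as.numeric(px_raw[i + 1])
  }
  per <- rows * cols
  if (length(vals) < per * n_frames)
    cs_abort("DICOM pixel data shorter than Rows*Columns*NumberOfFrames", "cs_io_error")
  frames <- lapply(seq_len(n_frames), function(k) {
    v <- vals[((k - 1) * per + 1):(k * per)]
    if (photo == "MONOCHROME1") v <- max(v) - v
    matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  })
  list(frames = frames, n_frames = n_frames, bits = as.integer(bits))
}
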