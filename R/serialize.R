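# Descriptor container I/O.
#
# Binary format (all integers little-endian int32 unless noted):
#   bytes 0-7   magic "DHOGDESC"
#   int32       version (1)
#   int32       scheme (0 = bosh bits, 1 = hog reals)
#   int32 x 4   patch_w, patch_h, cell_size, m
#   int32       n_samples
#   int32       descriptor length per sample
#   body        bosh: per sample ceil(len/8) bytes, bits packed
#               8-per-byte with the first bit in the most significant
#               position; hog: per sample `len` float64 values.
#
# The bit order within a descriptor (block-major, pair-major,
# shift-major, see extract_bosh) is part of the format.

pack_bits_msb <- function(bits) {
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  b <- c(as.integer(bits), integer(pad))
  # packBits() packs LSB-first; reverse each byte's bits for MSB-first
  idx <- as.vector(matrix(seq_along(b), nrow = 8L)[8:1, , drop = FALSE])
  packBits(as.integer(b[idx]), type = "raw")
}

unpack_bits_msb <- function(raw, n) {
  b <- as.integer(rawToBits(raw))
  idx <- as.vector(matrix(seq_along(b), nrow = 8L)[8:1, , drop = FALSE])
  b[idx][seq_len(n)]
}

#' Write and read descriptor containers
#'
#' Serializes a set of descriptors sharing one layout. The binary
#' container stores a header (magic, version, scheme and geometry)
#' followed by packed bits (BOSH; 8 bits per byte, first bit most
#' significant) or float64 values (baseline HOG). The text format
#' writes a `# drowsyhog-desc` header line followed by one row per
#' sample: a contiguous 0/1 string for BOSH, space-separated values
#' for HOG.
#'
#' @param descs a list of `bosh_descriptor` or `hog_descriptor`
#'   objects with identical layouts.
#' @param path output/input file path.
#' @param format `"binary"` or `"text"`.
#' @return `write_descriptors`: `path` invisibly;
#'   `read_descriptors`: a list with `layout`, `scheme` and
#'   `descriptors` (list of plain vectors).
#' @export
write_descriptors <- function(descs, path, format = c("binary", "text")) {
  format <- match.arg(format)
  if (length(descs) == 0L) stop("write_descriptors: empty set", call. = FALSE)
  lay <- attr(descs[[1]], "layout")
  for (d in descs) {
    if (!identical(attr(d, "layout"), lay)) {
      stop("write_descriptors: descriptors have differing layouts",
           call. = FALSE)
    }
  }
  scheme <- lay$scheme
  len <- length(descs[[1]])
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# drowsyhog-desc 1 %s %d %d %d %d %d",
                       scheme, lay$patch_w, lay$patch_h, lay$cell_size,
                       lay$m, len), con)
    for (d in descs) {
      if (scheme == "bosh") {
        writeLines(paste(as.integer(d), collapse = ""), con)
      } else {
        writeLines(paste(sprintf("%.17g", as.numeric(d)), collapse = " "), con)
      }
    }
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("DHOGDESC"), con)
  writeBin(as.integer(c(1L, if (scheme == "bosh") 0L else 1L,
                        lay$patch_w, lay$patch_h, lay$cell_size, lay$m,
                        length(descs), len)),
           con, size = 4L, endian = "little")
  for (d in descs) {
    if (scheme == "bosh") {
      writeBin(pack_bits_msb(as.integer(d)), con)
    } else {
      writeBin(as.numeric(d), con, size = 8L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path, format = c("binary", "text")) {
  format <- match.arg(format)
  wrap <- function(vals, lay) {
    cls <- if (lay$scheme == "bosh") "bosh_descriptor" else "hog_descriptor"
    lapply(vals, function(v) structure(v, layout = lay, class = cls))
  }
  if (format == "text") {
    lines <- readLines(path)
    hdr <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
    if (length(hdr) < 9L || hdr[2] != "drowsyhog-desc") {
      stop("read_descriptors: not a descriptor text file", call. = FALSE)
    }
    lay <- descriptor_layout(
      as.integer(hdr[6]) %/% as.integer(hdr[7]),
      as.integer(hdr[5]) %/% as.integer(hdr[7]),
      as.integer(hdr[7]), as.integer(hdr[8]), hdr[4]
    )
    len <- as.integer(hdr[9])
    vals <- lapply(lines[-1], function(ln) {
      if (lay$scheme == "bosh") {
        v <- as.integer(strsplit(ln, "", fixed = TRUE)[[1]])
      } else {
        v <- as.numeric(strsplit(ln, " ", fixed = TRUE)[[1]])
      }
      if (length(v) != len) {
        stop("read_descriptors: row length mismatch", call. = FALSE)
      }
      v
    })
    return(list(layout = lay, scheme = lay$scheme,
                descriptors = wrap(vals, lay)))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (magic != "DHOGDESC") {
    stop("read_descriptors: bad magic (not a descriptor container)",
         call. = FALSE)
  }
  hdr <- readBin(con, "integer", 8L, size = 4L, endian = "little")
  version <- hdr[1]
  if (version != 1L) {
    stop("read_descriptors: unsupported version", call. = FALSE)
  }
  scheme <- if (hdr[2] == 0L) "bosh" else "hog"
  lay <- descriptor_layout(hdr[4] %/% hdr[5], hdr[3] %/% hdr[5],
                           hdr[5], hdr[6], scheme)
  n <- hdr[7]; len <- hdr[8]
  vals <- vector("list", n)
  nbytes <- ceiling(len / 8)
  for (i in seq_len(n)) {
    if (scheme == "bosh") {
      vals[[i]] <- unpack_bits_msb(readBin(con, "raw", nbytes), len)
    } else {
      vals[[i]] <- readBin(con, "numeric", len, size = 8L, endian = "little")
    }
  }
  list(layout = lay, scheme = scheme, descriptors = wrap(vals, lay))
}
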