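#' Bounding boxes
#'
#' Axis-aligned rectangles in 0-based, half-open pixel coordinates:
#' a box covers columns `[x, x + w)` and rows `[y, y + h)`.
#'
#' @param x,y top-left corner (0-based).
#' @param w,h positive extents in pixels.
#' @return A list of class `bbox`.
#' @export
bbox <- function(x, y, w, h) {
  if (w <= 0 || h <= 0) {
    stop("bbox: width and height must be positive", call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)),
            class = "bbox")
}

#' @export
format.bbox <- function(x, ...) {
  sprintf("bbox(x=%g, y=%g, w=%g, h=%g)", x$x, x$y, x$w, x$h)
}

#' @export
print.bbox <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

bbox_area <- function(b) b$w * b$h

#' Intersection-over-union of two boxes
#'
#' @param a,b `bbox` objects.
#' @return IoU in `[0, 1]`.
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  union <- bbox_area(a) + bbox_area(b) - inter
  if (union <= 0) 0 else inter / union
}

clip_bbox <- function(b, width, height) {
  x0 <- max(0, b$x); y0 <- max(0, b$y)
  x1 <- min(width, b$x + b$w); y1 <- min(height, b$y + b$h)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  bbox(x0, y0, x1 - x0, y1 - y0)
}

#' Face detector backends
#'
#' Face detection is a pluggable contract: a backend is a list with a
#' `detect(gray_image)` function returning a list of
#' `list(box = bbox, confidence = numeric)` candidates (possibly
#' empty), plus a `name`. Two backends ship with the package:
#'
#' * `annotation_backend(annotations, frame_id)` — replays stored
#'   ground-truth boxes (from [read_roi_annotations()] or a generator
#'   manifest); the standard way to run the pipeline without any
#'   trained detector.
#' * `brightness_face_backend(threshold)` — a minimal intensity-blob
#'   detector for the synthetic frames: it finds the bounding box of
#'   the largest connected bright region. It is intended for
#'   generated fixtures, not for real photographs (a trained cascade
#'   would plug in through the same contract).
#'
#' @param annotations a named list mapping frame id to `bbox`.
#' @param frame_id the frame id the backend should report.
#' @param threshold brightness threshold in `[0, 1]`.
#' @return A backend object (list with `name` and `detect`).
#' @export
annotation_backend <- function(annotations, frame_id) {
  key <- as.character(frame_id)
  list(
    name = "annotation",
    detect = function(img) {
      b <- annotations[[key]]
      if (is.null(b)) return(list())
      list(list(box = b, confidence = 1.0))
    }
  )
}

#' @rdname annotation_backend
#' @export
brightness_face_backend <- function(threshold = 0.55) {
  list(
    name = "brightness",
    detect = function(img) {
      m <- if (is_gray_image(img)) as_plain_matrix(img) else img
      mask <- m > threshold
      if (!any(mask)) return(list())
      lab <- label_components(mask)
      sizes <- tabulate(lab[lab > 0L])
      best <- which.max(sizes)
      idx <- which(lab == best, arr.ind = TRUE)
      y0 <- min(idx[, 1]) - 1L; y1 <- max(idx[, 1])
      x0 <- min(idx[, 2]) - 1L; x1 <- max(idx[, 2])
      list(list(box = bbox(x0, y0, x1 - x0, y1 - y0),
                confidence = sizes[best] / length(m)))
    }
  )
}

# 4-connected component labelling by iterative label propagation
# (images here are small; bright face blobs converge in a few sweeps).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    old <- lab
    # propagate the minimum positive label from the 4-neighborhood
    up    <- rbind(lab[1, , drop = FALSE] * 0L, lab[-h, , drop = FALSE])
    down  <- rbind(lab[-1, , drop = FALSE], lab[h, , drop = FALSE] * 0L)
    left  <- cbind(lab[, 1, drop = FALSE] * 0L, lab[, -w, drop = FALSE])
    right <- cbind(lab[, -1, drop = FALSE], lab[, w, drop = FALSE] * 0L)
    for (nb in list(up, down, left, right)) {
      take <- mask & nb > 0L & (nb < lab)
      lab[take] <- nb[take]
    }
    if (identical(old, lab)) break
  }
  # compact labels
  ids <- sort(unique(lab[lab > 0L]))
  matrix(match(lab, ids, nomatch = 0L), h, w)
}

#' Detect the driver's face
#'
#' Runs a detector backend on a grayscale frame and returns the best
#' face box, clipped to the image bounds. When the backend reports
#' several candidates the largest-area box wins (the driver is the
#' face closest to the camera). Returns `NULL` when nothing is
#' detected — absence of a face is a valid outcome, not an error.
#'
#' @param img a `gray_image`.
#' @param backend a detector backend, see [annotation_backend()].
#' @return A `bbox` or `NULL`.
#' @export
detect_face <- function(img, backend) {
  if (!is.list(backend) || !is.function(backend$detect)) {
    stop("detect_face: invalid backend (needs a detect() function)",
         call. = FALSE)
  }
  cands <- tryCatch(backend$detect(img), error = function(e) {
    stop(sprintf("detect_face: backend '%s' failed: %s",
                 backend$name %||% "?", conditionMessage(e)), call. = FALSE)
  })
  if (length(cands) == 0L) return(NULL)
  areas <- vapply(cands, function(c) bbox_area(c$box), numeric(1))
  best <- cands[[which.max(areas)]]$box
  clip_bbox(best, width = ncol(img), height = nrow(img))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Eye-pair region from a face box
#'
#' Anthropometric eye-band prior: the eye-pair region occupies the
#' horizontal band from 15% to 85% of the face width and the vertical
#' band from 25% to 55% of the face height. The mapping is affine in
#' the face box, hence translation- and scale-equivariant.
#'
#' @param face a `bbox` for the detected face.
#' @return The eye-pair `bbox`.
#' @examples
#' eye_pair_from_face(bbox(0, 0, 100, 100)) # bbox(15, 25, 70, 30)
#' @export
eye_pair_from_face <- function(face) {
  if (!inherits(face, "bbox")) {
    stop("eye_pair_from_face: expected a bbox", call. = FALSE)
  }
  bbox(
    face$x + 0.15 * face$w,
    face$y + 0.25 * face$h,
    0.70 * face$w,
    0.30 * face$h
  )
}

#' Extract a canonical eye patch
#'
#' Crops a box from a grayscale image (zero-padding any part of the
#' box outside the image) and resamples it to the canonical patch
#' size — area averaging when shrinking, bilinear when growing. The
#' canonical size (default 64x32, width x height) is chosen so both
#' dimensions are multiples of the 8-pixel HOG cell.
#'
#' @param img a `gray_image`.
#' @param box a `bbox`; its intersection with the image must be
#'   non-empty.
#' @param canonical integer `c(width, height)` of the output patch.
#' @return An object of class `eye_patch` (a `gray_image` with a
#'   `source_box` attribute).
#' @export
extract_patch <- function(img, box, canonical = c(64L, 32L)) {
  if (!is_gray_image(img)) {
    stop("extract_patch: expected a gray_image", call. = FALSE)
  }
  h <- nrow(img); w <- ncol(img)
  x0 <- as.integer(round(box$x)); y0 <- as.integer(round(box$y))
  x1 <- as.integer(round(box$x + box$w)); y1 <- as.integer(round(box$y + box$h))
  if (x1 <= 0L || y1 <= 0L || x0 >= w || y0 >= h) {
    stop("extract_patch: box does not intersect the image", call. = FALSE)
  }
  crop <- matrix(0, y1 - y0, x1 - x0)
  sx0 <- max(x0, 0L); sy0 <- max(y0, 0L)
  sx1 <- min(x1, w); sy1 <- min(y1, h)
  crop[(sy0 - y0 + 1L):(sy1 - y0), (sx0 - x0 + 1L):(sx1 - x0)] <-
    as_plain_matrix(img)[(sy0 + 1L):sy1, (sx0 + 1L):sx1]
  cw <- as.integer(canonical[1]); chh <- as.integer(canonical[2])
  out <- if (nrow(crop) == chh && ncol(crop) == cw) crop
         else resample_matrix(crop, chh, cw)
  out <- pmin(pmax(out, 0), 1)
  structure(out, source_box = box,
            class = c("eye_patch", "gray_image", "matrix", "array"))
}

#' Read and write ROI annotation files
#'
#' Annotation format: CSV lines `frame_id,x,y,w,h` with 0-based
#' half-open boxes; blank lines and lines starting with `#` are
#' ignored. Duplicate frame ids keep the last record (with a
#' warning).
#'
#' @param path annotation file path.
#' @param annotations named list mapping frame id to `bbox` (for
#'   writing).
#' @return `read_roi_annotations`: a named list of `bbox` keyed by
#'   frame id; `write_roi_annotations`: `path`, invisibly.
#' @export
read_roi_annotations <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) != 5L || anyNA(suppressWarnings(as.numeric(parts[-1])))) {
      stop(sprintf("read_roi_annotations: malformed line %d: '%s'", i, ln),
           call. = FALSE)
    }
    id <- trimws(parts[1])
    v <- as.numeric(parts[-1])
    if (!is.null(out[[id]])) {
      warning(sprintf(
        "read_roi_annotations: duplicate frame id '%s' at line %d; last wins",
        id, i))
    }
    out[[id]] <- bbox(v[1], v[2], v[3], v[4])
  }
  out
}

#' @rdname read_roi_annotations
#' @export
write_roi_annotations <- function(annotations, path) {
  lines <- vapply(names(annotations), function(id) {
    b <- annotations[[id]]
    sprintf("%s,%g,%g,%g,%g", id, b$x, b$y, b$w, b$h)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Locate and extract the eye patch of one frame
#'
#' Convenience chain: [detect_face()], [eye_pair_from_face()],
#' [extract_patch()]. Returns `NULL` when no face is found.
#'
#' @param img a `gray_image` frame.
#' @param backend a face-detector backend.
#' @param canonical canonical patch size `c(width, height)`.
#' @return An `eye_patch` or `NULL`.
#' @export
locate_eye_patch <- function(img, backend, canonical = c(64L, 32L)) {
  face <- detect_face(img, backend)
  if (is.null(face)) return(NULL)
  extract_patch(img, eye_pair_from_face(face), canonical)
}
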