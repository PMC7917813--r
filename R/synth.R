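# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Scenario names
#'
#' The five illumination/occlusion recording conditions emulated by
#' the generator: bare face and glasses in daylight, sunglasses,
#' and bare face / glasses under night-time (infrared-like, low gain)
#' illumination.
#'
#' @return Character vector of the five scenario identifiers, in
#'   canonical report order.
#' @export
scenario_names <- function() {
  c("bareface", "glasses", "sunglasses", "night_bareface", "night_glasses")
}

scenario_defaults <- function(scenario) {
  switch(scenario,
    bareface       = list(illum_gain = 1.00, illum_offset = 0,
                          occlusion_alpha = 0.00, glasses_band = FALSE),
    glasses        = list(illum_gain = 1.00, illum_offset = 0,
                          occlusion_alpha = 0.45, glasses_band = TRUE),
    sunglasses     = list(illum_gain = 1.00, illum_offset = 0,
                          occlusion_alpha = 0.65, glasses_band = FALSE),
    night_bareface = list(illum_gain = 0.35, illum_offset = 0.02,
                          occlusion_alpha = 0.00, glasses_band = FALSE),
    night_glasses  = list(illum_gain = 0.35, illum_offset = 0.02,
                          occlusion_alpha = 0.45, glasses_band = TRUE),
    stop(sprintf("unknown scenario '%s'", scenario), call. = FALSE)
  )
}

#' Generator parameters
#'
#' Bundles the parameters controlling one synthetic eye patch. The
#' generator is a pure function of these parameters (including the
#' seed): identical parameters give bit-identical pixels.
#'
#' @param eye_state `"open"` or `"closed"`.
#' @param scenario one of [scenario_names()].
#' @param aperture eyelid opening fraction in `[0, 1]`; defaults to
#'   0.75 for open and 0.05 for closed eyes.
#' @param noise_sd additive Gaussian pixel noise standard deviation.
#' @param illum_gain,illum_offset global illumination transform
#'   applied after rendering (defaults set by the scenario: night
#'   scenarios use gain 0.35).
#' @param occlusion_alpha opacity of the dark occluding band
#'   (scenario default: 0.45 for glasses, 0.65 for sunglasses).
#' @param seed RNG seed for the noise.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(eye_state = c("open", "closed"),
                         scenario = scenario_names(),
                         aperture = NULL,
                         noise_sd = 0.02,
                         illum_gain = NULL,
                         illum_offset = NULL,
                         occlusion_alpha = NULL,
                         seed = 1L) {
  eye_state <- match.arg(eye_state)
  scenario <- match.arg(scenario)
  sd_ <- scenario_defaults(scenario)
  if (is.null(aperture)) aperture <- if (eye_state == "open") 0.75 else 0.05
  if (aperture < 0 || aperture > 1) {
    stop("synth_params: aperture must be in [0, 1]", call. = FALSE)
  }
  if (eye_state == "closed" && aperture > 0.15) {
    stop("synth_params: closed eyes require aperture <= 0.15", call. = FALSE)
  }
  if (noise_sd < 0) stop("synth_params: noise_sd must be >= 0", call. = FALSE)
  structure(list(
    eye_state = eye_state, scenario = scenario, aperture = aperture,
    noise_sd = noise_sd,
    illum_gain = illum_gain %||% sd_$illum_gain,
    illum_offset = illum_offset %||% sd_$illum_offset,
    occlusion_alpha = occlusion_alpha %||% sd_$occlusion_alpha,
    glasses_band = sd_$glasses_band,
    seed = as.integer(seed)
  ), class = "synth_params")
}

# Noise-free 64x32 eye-pair rendering in [0,1]. The generator
# emulates what gradient descriptors measure — open eyes contribute
# strong sclera/iris edge texture, closed eyes a smooth lid — rather
# than photorealism.
render_eye_band <- function(aperture, width = 64L, height = 32L) {
  xs <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
  ys <- matrix(rep(seq_len(height) - 0.5, times = width), height, width)
  # skin: gentle horizontal gradient with a soft vertical shading
  skin <- 0.58 + 0.10 * (xs / width) + 0.05 * sin(pi * ys / height)
  img <- skin
  for (cx in c(width / 4, 3 * width / 4)) {
    cy <- height / 2
    rx <- width / 6.4   # 10 px at width 64
    ry <- height / 4.6  # ~7 px at height 32
    inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
    # upper eyelid: only the lowest `aperture` fraction of the eye
    # ellipse is visible; the lid above it is slightly shaded skin
    lid_y <- cy - ry + (1 - aperture) * 2 * ry
    visible <- inside & ys >= lid_y
    lid <- inside & ys < lid_y
    img[visible] <- 0.86                       # sclera
    iris <- visible & ((xs - cx)^2 + (ys - cy - (1 - aperture) * ry)^2 <=
                         (width / 16)^2)
    img[iris] <- 0.15                          # iris/pupil disc
    img[lid] <- skin[lid] * 0.93               # lid shading/crease
  }
  pmin(pmax(img, 0), 1)
}

#' Generate one synthetic eye patch
#'
#' Renders a 64x32 (width x height) eye-pair patch for the given
#' parameters: two eye ellipses with bright sclera and a dark
#' iris/pupil disc, clipped by an upper eyelid at the configured
#' aperture; a smooth skin gradient elsewhere. Scenario transforms
#' follow: a semi-transparent dark band over the upper eye margin for
#' glasses, a high-opacity band over the whole eye region for
#' sunglasses, and a global low-gain illumination transform for night
#' scenarios. Additive Gaussian noise (from the seed) is applied
#' last, and pixels are clipped to `[0, 1]`.
#'
#' @param params a `synth_params` object.
#' @return A list of class `synth_sample`: fields `patch`
#'   (`eye_patch`), `label`, `scenario`, `params`.
#' @export
generate_patch <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  img <- render_eye_band(params$aperture)
  h <- nrow(img); w <- ncol(img)
  if (params$glasses_band) {
    rows <- 5:11 # upper eye margin
    img[rows, ] <- (1 - params$occlusion_alpha) * img[rows, ] +
      params$occlusion_alpha * 0.12
  } else if (params$occlusion_alpha > 0) {
    rows <- 5:28 # whole eye band (sunglasses lens)
    img[rows, ] <- (1 - params$occlusion_alpha) * img[rows, ] +
      params$occlusion_alpha * 0.08
  }
  img <- params$illum_gain * img + params$illum_offset
  if (params$noise_sd > 0) {
    img <- img + with_local_seed(params$seed,
                                 matrix(stats::rnorm(h * w, 0, params$noise_sd),
                                        h, w))
  }
  img <- pmin(pmax(img, 0), 1)
  patch <- structure(img, source_box = NULL,
                     class = c("eye_patch", "gray_image", "matrix", "array"))
  structure(list(patch = patch, label = params$eye_state,
                 scenario = params$scenario, params = params),
            class = "synth_sample")
}

#' Generate a balanced synthetic dataset
#'
#' Generates `n_per_class` open-eye and `n_per_class` closed-eye
#' patches. Apertures are drawn per class: closed from
#' `U(0, 0.15)`, open from `U(lo, 1)` with
#' `lo = 0.15 + 0.35 * separability`, so the class gap shrinks to
#' zero as `separability` approaches 0 (at the default
#' `separability = 1`, open apertures are at least 0.5). Scenarios
#' are assigned by largest-remainder allocation of the mix within
#' each class. Each sample's RNG seed is derived from the master seed
#' by `bitwXor(seed, sample_index)` (1-based index over the whole
#' dataset), making generation reproducible sample-by-sample.
#'
#' @param n_per_class samples per class (`>= 1`).
#' @param scenario_mix named numeric vector of proportions over
#'   [scenario_names()]; must sum to 1. Default: uniform.
#' @param separability class-separation control in `(0, 1]`.
#' @param noise_sd additive noise level passed to every sample.
#' @param seed master seed.
#' @return A list of `synth_sample` objects, open class first.
#' @export
generate_dataset <- function(n_per_class,
                             scenario_mix = NULL,
                             separability = 1.0,
                             noise_sd = 0.02,
                             seed = 1L) {
  if (n_per_class < 1L) {
    stop("generate_dataset: n_per_class must be >= 1", call. = FALSE)
  }
  if (separability <= 0 || separability > 1) {
    stop("generate_dataset: separability must be in (0, 1]", call. = FALSE)
  }
  scn <- scenario_names()
  if (is.null(scenario_mix)) {
    scenario_mix <- stats::setNames(rep(1 / length(scn), length(scn)), scn)
  }
  if (!all(names(scenario_mix) %in% scn) ||
      abs(sum(scenario_mix) - 1) > 1e-9 || any(scenario_mix < 0)) {
    stop("generate_dataset: scenario_mix must be non-negative proportions over the five scenarios summing to 1",
         call. = FALSE)
  }
  mix <- stats::setNames(numeric(length(scn)), scn)
  mix[names(scenario_mix)] <- scenario_mix
  # largest-remainder allocation of n_per_class to scenarios
  raw <- mix * n_per_class
  cnt <- floor(raw)
  rem <- n_per_class - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  scn_seq <- rep(scn, times = cnt)
  lo_open <- 0.15 + 0.35 * separability
  samples <- vector("list", 2L * n_per_class)
  idx <- 0L
  for (state in c("open", "closed")) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sub_seed <- bitwXor(as.integer(seed), idx)
      ap <- with_local_seed(sub_seed, {
        if (state == "open") stats::runif(1, lo_open, 1)
        else stats::runif(1, 0, 0.15)
      })
      p <- synth_params(
        eye_state = state, scenario = scn_seq[i], aperture = ap,
        noise_sd = noise_sd, seed = bitwXor(sub_seed, 1234567L)
      )
      samples[[idx]] <- generate_patch(p)
    }
  }
  samples
}

#' Generate a full synthetic frame
#'
#' Renders a 320x240 frame containing a bright face-like oval at a
#' seeded random position and scale, with the eye patch composited at
#' the anthropometric eye-band position consistent with
#' [eye_pair_from_face()] (15-85% of face width, 25-55% of face
#' height). Ground-truth face and eye boxes are recorded, so the ROI
#' chain can be exercised end-to-end with either the annotation or
#' the brightness backend.
#'
#' @param params a `synth_params` object.
#' @param frame_size integer `c(width, height)` of the frame.
#' @return A `synth_sample` with fields `frame` (`gray_image`),
#'   `patch` (the composited `eye_patch`), `face_box`, `eye_box`,
#'   `label`, `scenario`, `params`.
#' @export
generate_frame <- function(params, frame_size = c(320L, 240L)) {
  stopifnot(inherits(params, "synth_params"))
  w <- frame_size[1]; h <- frame_size[2]
  geom <- with_local_seed(bitwXor(params$seed, 99991L), {
    fw <- round(stats::runif(1, 100, 150))
    fh <- round(fw * stats::runif(1, 1.15, 1.3))
    fx <- round(stats::runif(1, 10, w - fw - 10))
    fy <- round(stats::runif(1, 10, h - fh - 10))
    c(fx, fy, fw, fh)
  })
  face <- bbox(geom[1], geom[2], geom[3], geom[4])
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  frame <- 0.15 + 0.04 * (ys / h) # dim cabin background
  cx <- face$x + face$w / 2; cy <- face$y + face$h / 2
  oval <- ((xs - cx) / (face$w / 2))^2 + ((ys - cy) / (face$h / 2))^2 <= 1
  frame[oval] <- 0.72 - 0.05 * ((ys[oval] - cy) / (face$h / 2))^2
  # night scenarios dim the whole frame like low-gain IR capture
  frame <- params$illum_gain * frame + params$illum_offset

  sample <- generate_patch(params)
  eye <- eye_pair_from_face(face)
  ex0 <- as.integer(round(eye$x)); ey0 <- as.integer(round(eye$y))
  ew <- as.integer(round(eye$w)); eh <- as.integer(round(eye$h))
  frame[(ey0 + 1L):(ey0 + eh), (ex0 + 1L):(ex0 + ew)] <-
    resample_matrix(as_plain_matrix(sample$patch), eh, ew)
  frame <- pmin(pmax(frame, 0), 1)
  structure(list(
    frame = gray_image(frame), patch = sample$patch,
    face_box = face, eye_box = eye,
    label = params$eye_state, scenario = params$scenario, params = params
  ), class = "synth_sample")
}
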