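#' Specification of a synthetic stroboscopic frame sequence
#'
#' Describes a laryngeal-like test scene: a dark glottal gap (ellipse or
#' V-shaped chink) on a bright textured "tissue" background, an optional
#' bright lesion bump protruding into the gap from one fold edge, sinusoidal
#' per-frame modulation of the gap area (the apparent stroboscopic
#' vibration), and optional additive pixel noise. All geometry is in pixels.
#'
#' @param width,height Frame size in pixels (default 160 x 120).
#' @param shape `"ellipse"` (closed gap outline) or `"vgap"` (triangular
#'   chink between two straight fold edges).
#' @param gap_area_px Target gap area in pixels; for the ellipse the
#'   rendered pixel count matches exactly.
#' @param aspect Ellipse elongation (vertical/horizontal radius ratio,
#'   default 3: the glottis is elongated along the anterior-posterior
#'   axis).
#' @param edge_angles_deg For `"vgap"`: angles of the image-left and
#'   image-right fold edges from the vertical midline, degrees.
#' @param gap_height For `"vgap"`: vertical extent of the chink in rows.
#' @param apex_width For `"vgap"`: horizontal separation of the two edges
#'   at the apex in pixels (0 = edges meet; use > 0 for parallel-edge
#'   scenes).
#' @param lesion_side `NA`, `"left"` or `"right"` (image side) for a lesion
#'   bump on that fold edge.
#' @param lesion_px Lesion size in pixels (exact).
#' @param n_frames Number of frames.
#' @param mod_amplitude Fractional amplitude of the sinusoidal area
#'   modulation in `[0, 1)`.
#' @param mod_period Modulation period in frames.
#' @param mod_phase_sd Standard deviation of per-frame phase jitter in
#'   radians (0 = perfectly regular oscillation).
#' @param noise_sd Additive Gaussian pixel-noise standard deviation, in
#'   intensity units of the 0-255 scale.
#' @param bg_level,gap_level Background (tissue) and gap intensities.
#' @param texture_amp Amplitude of the deterministic background texture.
#' @param seed Integer RNG seed.
#' @return A `strobe_spec`.
#' @export
strobe_spec <- function(width = 160, height = 120,
                        shape = c("ellipse", "vgap"),
                        gap_area_px = 1200, aspect = 3,
                        edge_angles_deg = c(-15, 15), gap_height = 80,
                        apex_width = 0,
                        lesion_side = NA, lesion_px = 0,
                        n_frames = 1, mod_amplitude = 0, mod_period = 10,
                        mod_phase_sd = 0,
                        noise_sd = 0, bg_level = 200, gap_level = 40,
                        texture_amp = 8, seed = 1) {
  shape <- match.arg(shape)
  if (gap_area_px < 20) stop_spec("gap_area_px must be at least 20")
  if (gap_area_px * (1 + mod_amplitude) > 0.45 * width * height) {
    stop_spec("gap does not fit inside the frame")
  }
  if (shape == "vgap" && gap_height > height - 10) {
    stop_spec("vgap height does not fit inside the frame")
  }
  if (!is.na(lesion_side) && !lesion_side %in% c("left", "right")) {
    stop_spec('lesion_side must be NA, "left" or "right"')
  }
  if (mod_amplitude < 0 || mod_amplitude >= 1) {
    stop_spec("mod_amplitude must be in [0, 1)")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         shape = shape, gap_area_px = as.integer(gap_area_px),
         aspect = aspect, edge_angles_deg = edge_angles_deg,
         gap_height = as.integer(gap_height),
         apex_width = as.integer(apex_width),
         lesion_side = lesion_side, lesion_px = as.integer(lesion_px),
         n_frames = as.integer(n_frames), mod_amplitude = mod_amplitude,
         mod_period = mod_period, mod_phase_sd = mod_phase_sd,
         noise_sd = noise_sd, bg_level = bg_level, gap_level = gap_level,
         texture_amp = texture_amp, seed = as.integer(seed)),
    class = "strobe_spec"
  )
}

#' Synthesize a stroboscopic frame sequence with known ground truth
#'
#' Renders the scene described by a [strobe_spec()]. For the elliptical
#' gap the pixel count is exact by construction: pixels are ranked by
#' elliptical distance from the gap center and exactly the requested
#' number of nearest pixels is darkened (so modulated areas are nested,
#' connected, near-elliptical regions). Lesions are carved by re-brightening
#' exactly `lesion_px` gap pixels nearest a point on the chosen fold edge.
#' The emitted ground truth records, per frame, the exact dark-pixel count,
#' and globally the lesion size/side, the fold-edge angles (V-gap), and the
#' modulation parameters.
#'
#' @param spec A [strobe_spec()].
#' @return A list: `frames` (list of [strobe_frame()]) and `ground_truth`
#'   (`gap_area_px` per frame, `lesion_px`, `lesion_side`,
#'   `edge_angles_deg`/`deviation_deg` for V-gaps, `amplitude`,
#'   `mod_period`).
#' @examples
#' out <- synth_strobe_sequence(strobe_spec(gap_area_px = 1234))
#' sum(segment_glottal_space(out$frames[[1]])$mask)  # 1234
#' @export
synth_strobe_sequence <- function(spec) {
  if (!inherits(spec, "strobe_spec")) {
    stop_spec("`spec` must be a strobe_spec object")
  }
  rng <- local_rng(spec$seed)
  h <- spec$height; w <- spec$width
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)

  # deterministic mild background texture (low spatial frequency)
  texture <- spec$bg_level +
    spec$texture_amp * sin(2 * pi * rr / 37) * cos(2 * pi * cc / 53)

  # per-frame target areas
  k <- seq_len(spec$n_frames)
  phase <- 2 * pi * (k - 1) / spec$mod_period
  if (spec$mod_phase_sd > 0) {
    phase <- phase + rng$norm(spec$n_frames) * spec$mod_phase_sd
  }
  target <- round(spec$gap_area_px * (1 + spec$mod_amplitude * sin(phase)))
  target <- pmax(target, 20L)

  if (spec$shape == "ellipse") {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    d <- ((rr - cy) / spec$aspect)^2 + (cc - cx)^2
    ord <- order(d, rr, cc)   # deterministic tie-break
    gap_pixels <- function(n) ord[seq_len(n)]
    gt_angles <- NULL
  } else {
    apex_r <- (h - spec$gap_height) %/% 2
    cx <- (w + 1) / 2
    aw <- spec$apex_width / 2
    tl <- tan(spec$edge_angles_deg[1] * pi / 180)
    trr <- tan(spec$edge_angles_deg[2] * pi / 180)
    depth <- rr - apex_r
    inside <- depth >= 1 & depth <= spec$gap_height &
      cc >= cx - aw + depth * tl & cc <= cx + aw + depth * trr
    vg <- which(inside)
    gap_pixels <- function(n) vg   # area fixed by geometry
    gt_angles <- spec$edge_angles_deg
    target <- rep.int(length(vg), spec$n_frames)
  }

  # lesion: exactly lesion_px gap pixels nearest a point on the fold edge
  carve_lesion <- function(px) {
    if (is.na(spec$lesion_side) || spec$lesion_px <= 0) return(integer(0))
    rows <- rr[px]; cols <- cc[px]
    mid_r <- stats::median(rows)
    near <- abs(rows - mid_r) <= 1
    edge_c <- if (spec$lesion_side == "left") min(cols[near]) else max(cols[near])
    d2 <- (rows - mid_r)^2 + (cols - edge_c)^2
    if (spec$lesion_px >= length(px)) {
      stop_spec("lesion larger than the glottal gap")
    }
    px[order(d2, rows, cols)[seq_len(spec$lesion_px)]]
  }

  frames <- vector("list", spec$n_frames)
  gt_area <- integer(spec$n_frames)
  for (i in k) {
    px <- gap_pixels(target[i])
    les <- carve_lesion(px)
    px_eff <- setdiff(px, les)
    img <- texture
    img[px_eff] <- spec$gap_level
    if (spec$noise_sd > 0) {
      img <- img + rng$norm(length(img)) * spec$noise_sd
      img <- pmin(pmax(img, 0), 255)
    }
    frames[[i]] <- strobe_frame(matrix(img, h, w))
    gt_area[i] <- length(px_eff)
  }

  gt <- list(
    gap_area_px = gt_area,
    lesion_px = if (is.na(spec$lesion_side)) 0L else spec$lesion_px,
    lesion_side = spec$lesion_side,
    amplitude = spec$mod_amplitude,
    mod_period = spec$mod_period
  )
  if (!is.null(gt_angles)) {
    gt$edge_angles_deg <- gt_angles
    gt$deviation_deg <- abs(diff(gt_angles))
  }
  list(frames = frames, ground_truth = gt)
}
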