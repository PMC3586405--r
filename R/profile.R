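#' Axis order and normal limits of the vocal profile
#'
#' The vocal profile has 13 axes in the fixed published order. Each
#' clinical value is normalized by a documented normal limit so that 1.0
#' is exactly the edge of the normal range (the red threshold circle of
#' the radar chart). For "higher is worse" measures the radius is
#' `value / limit`; for "lower is worse" measures (subjective quality,
#' MFT, HNR) it is `limit / value`.
#'
#' Default limits: subjective quality 7/10, repercussion 3/10, GRBAS
#' G/R/B 1 (the mild boundary), MFT 10 s (the published pathology
#' threshold), jitter 1.0%, shimmer 3.8%, HNR 20 dB, stroboscopic ratings
#' 2/10.
#'
#' @return Named list with `limits` (numeric) and `direction`
#'   (`"higher_worse"` / `"lower_worse"`) per axis, in axis order.
#' @export
profile_axes <- function() {
  axes <- c("subjective_quality", "subjective_repercussion",
            "perception_g", "perception_r", "perception_b",
            "mft", "jitter", "shimmer", "hnr",
            "strobe_closure", "strobe_mucosal_wave",
            "strobe_regularity", "strobe_symmetry")
  limits <- c(7, 3, 1, 1, 1, 10, 1.0, 3.8, 20, 2, 2, 2, 2)
  direction <- c("lower_worse", "higher_worse",
                 "higher_worse", "higher_worse", "higher_worse",
                 "lower_worse", "higher_worse", "higher_worse",
                 "lower_worse",
                 "higher_worse", "higher_worse", "higher_worse",
                 "higher_worse")
  names(limits) <- axes
  names(direction) <- axes
  list(axes = axes, limits = limits, direction = direction)
}

#' Construct a vocal profile from the 13 axis values
#'
#' @param values Named numeric vector with the 13 axis values on their
#'   clinical scales (see [profile_axes()] for names and units). `NA`
#'   values yield radius 0 with a warning.
#' @param limits Optional replacement normal limits (named as the axes).
#' @return A `vocal_profile`: `radii` (named, length 13), `values`,
#'   `limits`.
#' @export
vocal_profile <- function(values, limits = NULL) {
  ax <- profile_axes()
  if (!is.null(limits)) {
    ax$limits[names(limits)] <- limits
  }
  missing_ax <- ax$axes[!(ax$axes %in% names(values)) |
                          is.na(values[match(ax$axes, names(values))])]
  if (length(missing_ax) > 0) {
    warning("missing profile values set to radius 0: ",
            paste(missing_ax, collapse = ", "), call. = FALSE)
  }
  radii <- vapply(ax$axes, function(a) {
    v <- if (a %in% names(values)) values[[a]] else NA_real_
    if (is.na(v)) return(0)
    if (!is.finite(v)) stop_validation(sprintf("axis %s is non-finite", a))
    lim <- ax$limits[[a]]
    if (ax$direction[[a]] == "higher_worse") {
      if (v < 0) stop_validation(sprintf("axis %s must be >= 0", a))
      v / lim
    } else {
      if (v <= 0) stop_validation(sprintf(
        "axis %s must be positive (lower-is-worse normalization)", a))
      lim / v
    }
  }, numeric(1))
  structure(
    list(radii = radii, values = values, limits = ax$limits),
    class = "vocal_profile"
  )
}

#' Build the vocal profile of a patient session
#'
#' Collects the 13 profile parameters from the session's analysis blocks
#' (short form, GRBAS, aerodynamics, acoustic report, stroboscopic
#' ratings) and normalizes them per [profile_axes()].
#'
#' @param session A [patient_session()].
#' @param limits Optional replacement normal limits.
#' @return A [vocal_profile()].
#' @export
build_profile <- function(session, limits = NULL) {
  if (!inherits(session, "patient_session")) {
    stop_invalid_input("expected a patient_session")
  }
  sf <- session$scores$short_form
  gr <- session$scores$grbas
  ae <- session$scores$aerodynamics
  ac <- session$acoustic
  vl <- session$scores$vlg
  grab <- function(x, f) if (is.null(x)) NA_real_ else as.numeric(x[[f]])
  values <- c(
    subjective_quality = grab(sf, "quality"),
    subjective_repercussion = grab(sf, "repercussion"),
    perception_g = grab(gr, "G"),
    perception_r = grab(gr, "R"),
    perception_b = grab(gr, "B"),
    mft = grab(ae, "mft_a_s"),
    jitter = grab(ac, "jitter_pct"),
    shimmer = grab(ac, "shimmer_pct"),
    hnr = grab(ac, "hnr_db"),
    strobe_closure = grab(vl, "glottal_closure"),
    strobe_mucosal_wave = grab(vl, "mucosal_wave"),
    strobe_regularity = grab(vl, "regularity"),
    strobe_symmetry = grab(vl, "symmetry")
  )
  vocal_profile(values, limits = limits)
}

#' Polygon area of a vocal profile
#'
#' The radar polygon joins the 13 axis points at equal angular spacing;
#' its area is `1/2 * sin(2*pi/13) * sum(r_i * r_(i+1))` (cyclic). The
#' larger the area, the worse the overall vocal impairment; all radii at
#' the normal limit give the regular 13-gon area `13/2 * sin(2*pi/13)`,
#' about 3.037.
#'
#' @param profile A [vocal_profile()].
#' @return Dimensionless area (>= 0).
#' @export
profile_area <- function(profile) {
  if (!inherits(profile, "vocal_profile")) {
    stop_invalid_input("expected a vocal_profile")
  }
  r <- profile$radii
  0.5 * sin(2 * pi / length(r)) * sum(r * c(r[-1], r[1]))
}

#' @export
print.vocal_profile <- function(x, ...) {
  cat("<vocal_profile>\n")
  for (a in names(x$radii)) {
    flagged <- if (x$radii[[a]] > 1) "  * outside normal circle" else ""
    cat(sprintf("  %-24s r = %.2f%s\n", a, x$radii[[a]], flagged))
  }
  cat(sprintf("  polygon area %.3f (normal circle %.3f)\n",
              profile_area(x), 13 / 2 * sin(2 * pi / 13)))
  invisible(x)
}

#' Radar-chart SVG of a vocal profile
#'
#' Renders the 13-axis radar as a standalone SVG string: grey spokes and
#' rings, the red unit circle marking the normal threshold, and the
#' patient polygon. Output is deterministic text, suitable for embedding
#' in the HTML report.
#'
#' @param profile A [vocal_profile()].
#' @param size Image side length in pixels (default 420).
#' @param r_max Radius value mapped to the outer ring (default: at least 2,
#'   grown to fit the data).
#' @return Character scalar containing the SVG document.
#' @export
radar_svg <- function(profile, size = 420, r_max = NULL) {
  r <- profile$radii
  n <- length(r)
  if (is.null(r_max)) r_max <- max(2, ceiling(max(r) * 1.1))
  cx <- size / 2
  scale <- (size / 2 - 55) / r_max
  ang <- -pi / 2 + 2 * pi * (seq_len(n) - 1) / n
  px <- function(rad) cx + rad * scale * cos(ang)
  py <- function(rad) cx + rad * scale * sin(ang)
  num <- function(x) sprintf("%.2f", x)

  rings <- paste(vapply(seq_len(r_max), function(k) {
    sprintf('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#cccccc"/>',
            num(cx), num(cx), num(k * scale))
  }, character(1)), collapse = "\n")
  spokes <- paste(sprintf(
    '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#dddddd"/>',
    num(cx), num(cx), num(px(r_max)), num(py(r_max))), collapse = "\n")
  labels <- paste(sprintf(
    '<text x="%s" y="%s" font-size="9" text-anchor="middle" fill="#444444">%s</text>',
    num(cx + (r_max * scale + 28) * cos(ang)),
    num(cx + (r_max * scale + 28) * sin(ang)),
    gsub("_", " ", names(r))), collapse = "\n")
  poly <- sprintf(
    '<polygon points="%s" fill="rgba(40,90,180,0.35)" stroke="#28519c" stroke-width="1.5"/>',
    paste(sprintf("%s,%s", num(px(pmin(r, r_max))), num(py(pmin(r, r_max)))),
          collapse = " "))
  threshold <- sprintf(
    '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#cc0000" stroke-width="1.5"/>',
    num(cx), num(cx), num(scale))

  paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">\n',
            size, size, size, size),
    sprintf('<rect width="%d" height="%d" fill="white"/>\n', size, size),
    rings, "\n", spokes, "\n", threshold, "\n", poly, "\n", labels,
    "\n</svg>\n"
  )
}
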