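#' Score the Voice Handicap Index (VHI-30)
#'
#' The VHI-30 has 30 self-report items in three 10-item subscales
#' (functional, physical, emotional), each item rated 0-4, giving 0-40
#' per subscale and a global score of 0-120. Subscale bands are Low
#' (0-20), Moderate (21-30), Severe (31-40); global bands Low (0-30),
#' Moderate (31-60), Serious (61-90), Severe (91-120).
#'
#' @param responses Integer vector of 30 item ratings in `{0..4}`, ordered
#'   functional items 1-10, physical 11-20, emotional 21-30.
#' @return A `vhi_score`: `functional`, `physical`, `emotional`, `total`,
#'   per-domain `bands` and `global_band`.
#' @examples
#' score_vhi(rep(2, 30))
#' @export
score_vhi <- function(responses) {
  if (length(responses) != 30) {
    stop_validation(sprintf("VHI needs exactly 30 items, got %d",
                            length(responses)))
  }
  bad <- which(!(responses %in% 0:4))
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "VHI item %d has rating %s; ratings must be integers 0-4",
      bad[1], format(responses[bad[1]])
    ))
  }
  sub <- vapply(split(responses, rep(1:3, each = 10)), sum, numeric(1))
  total <- sum(sub)
  structure(
    list(
      responses = as.integer(responses),
      functional = sub[[1]], physical = sub[[2]], emotional = sub[[3]],
      total = total,
      bands = c(functional = classify_vhi_domain(sub[[1]]),
                physical = classify_vhi_domain(sub[[2]]),
                emotional = classify_vhi_domain(sub[[3]])),
      global_band = classify_vhi_global(total)
    ),
    class = "vhi_score"
  )
}

#' @export
print.vhi_score <- function(x, ...) {
  cat(sprintf("<vhi_score> F %d (%s), P %d (%s), E %d (%s); total %d (%s)\n",
              x$functional, x$bands[["functional"]],
              x$physical, x$bands[["physical"]],
              x$emotional, x$bands[["emotional"]],
              x$total, x$global_band))
  invisible(x)
}

#' Classify a VHI subscale score
#'
#' Low 0-20, Moderate 21-30, Severe 31-40.
#'
#' @param subtotal Subscale score, 0-40.
#' @return `"Low"`, `"Moderate"` or `"Severe"`.
#' @export
classify_vhi_domain <- function(subtotal) {
  if (!is.numeric(subtotal) || length(subtotal) != 1 ||
      is.na(subtotal) || subtotal < 0 || subtotal > 40) {
    stop_validation("VHI subscale score must be a number in [0, 40]")
  }
  if (subtotal <= 20) "Low" else if (subtotal <= 30) "Moderate" else "Severe"
}

#' Classify the global VHI score
#'
#' Low 0-30, Moderate 31-60, Serious 61-90, Severe 91-120. (The published
#' band table overlaps Low and Moderate at 31-39; the Moderate lower edge
#' of 31 is kept so the bands partition 0-120.)
#'
#' @param total Global VHI score, 0-120.
#' @return `"Low"`, `"Moderate"`, `"Serious"` or `"Severe"`.
#' @export
classify_vhi_global <- function(total) {
  if (!is.numeric(total) || length(total) != 1 ||
      is.na(total) || total < 0 || total > 120) {
    stop_validation("global VHI score must be a number in [0, 120]")
  }
  if (total <= 30) "Low"
  else if (total <= 60) "Moderate"
  else if (total <= 90) "Serious"
  else "Severe"
}

#' Short-form subjective assessment
#'
#' Two 0-10 questions: perceived voice quality (10 = high quality) and
#' socio-occupational repercussion (10 = maximal effect). Categories use
#' uniform banding: quality 9-10 Good, 7-8 Acceptable, 4-6 Medium, 2-3
#' Bad, 0-1 Very Bad; repercussion 0-1 None, 2-3 Little, 4-6 Moderate,
#' 7-8 Serious, 9-10 Severe.
#'
#' @param quality,repercussion Integers 0-10.
#' @return A `short_form_answers`: the two scores and their categories.
#' @export
short_form <- function(quality, repercussion) {
  chk <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        x != round(x) || x < 0 || x > 10) {
      stop_validation(sprintf("%s must be an integer in [0, 10]", what))
    }
  }
  chk(quality, "quality")
  chk(repercussion, "repercussion")
  qcat <- cut(quality, c(-1, 1, 3, 6, 8, 10),
              labels = c("Very Bad", "Bad", "Medium", "Acceptable", "Good"))
  rcat <- cut(repercussion, c(-1, 1, 3, 6, 8, 10),
              labels = c("None", "Little", "Moderate", "Serious", "Severe"))
  structure(
    list(quality = as.integer(quality),
         repercussion = as.integer(repercussion),
         quality_category = as.character(qcat),
         repercussion_category = as.character(rcat)),
    class = "short_form_answers"
  )
}

#' @export
print.short_form_answers <- function(x, ...) {
  cat(sprintf("<short_form> quality %d/10 (%s), repercussion %d/10 (%s)\n",
              x$quality, x$quality_category,
              x$repercussion, x$repercussion_category))
  invisible(x)
}

#' Validate a GRBAS perceptual rating vector
#'
#' Grade, Roughness and Breathiness are required; Asthenia and Strain are
#' harder to judge and may be omitted. Each rating is an integer 0 (normal)
#' to 3 (severe).
#'
#' @param g,r,b Required ratings, integers 0-3.
#' @param a,s Optional ratings, integers 0-3 or `NA`.
#' @return A `grbas_vector`: `G`, `R`, `B`, `A`, `S` (NA when absent),
#'   `complete` (whether A and S were given), `normal` (all given ratings
#'   zero).
#' @examples
#' validate_grbas(2, 1, 0)
#' @export
validate_grbas <- function(g, r, b, a = NA, s = NA) {
  chk <- function(x, what, optional = FALSE) {
    if (optional && (length(x) == 0 || is.na(x))) return(NA_integer_)
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || !(x %in% 0:3)) {
      stop_validation(sprintf(
        "%s rating must be an integer 0-3 (0 normal ... 3 severe)", what))
    }
    as.integer(x)
  }
  out <- list(
    G = chk(g, "G (grade)"),
    R = chk(r, "R (roughness)"),
    B = chk(b, "B (breathiness)"),
    A = chk(a, "A (asthenia)", optional = TRUE),
    S = chk(s, "S (strain)", optional = TRUE)
  )
  given <- unlist(out)[!is.na(unlist(out))]
  out$complete <- !is.na(out$A) && !is.na(out$S)
  out$normal <- all(given == 0)
  structure(out, class = "grbas_vector")
}

#' @export
print.grbas_vector <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else as.character(v)
  cat(sprintf("<grbas> G%s R%s B%s A%s S%s%s\n",
              fmt(x$G), fmt(x$R), fmt(x$B), fmt(x$A), fmt(x$S),
              if (x$normal) " (normal)" else ""))
  invisible(x)
}

#' Subjective stroboscopic (VLG) rating
#'
#' Clinician ratings of glottal closure, mucosal wave, regularity and
#' symmetry on a 0-10 scale where 0 is normal, plus the closure type.
#'
#' @param glottal_closure,mucosal_wave,regularity,symmetry Integers 0-10.
#' @param closure_type One of
#'   `"complete", "hourglass", "posterior", "irregular", "anterior",
#'   "longitudinal"`.
#' @return A `vlg_rating`.
#' @export
vlg_rating <- function(glottal_closure = 0, mucosal_wave = 0,
                       regularity = 0, symmetry = 0,
                       closure_type = "complete") {
  chk <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        x != round(x) || x < 0 || x > 10) {
      stop_validation(sprintf("%s must be an integer in [0, 10]", what))
    }
    as.integer(x)
  }
  closure_type <- match.arg(closure_type, closure_types)
  structure(
    list(glottal_closure = chk(glottal_closure, "glottal_closure"),
         mucosal_wave = chk(mucosal_wave, "mucosal_wave"),
         regularity = chk(regularity, "regularity"),
         symmetry = chk(symmetry, "symmetry"),
         closure_type = closure_type),
    class = "vlg_rating"
  )
}

#' Aerodynamic efficiency measures
#'
#' Maximum phonation times of the sustained /a/ and /s/, in seconds, and
#' the phonorespiratory index `MFT(/s/) / MFT(/a/)`. An MFT(/a/) strictly
#' below 10 s is considered pathological; a phonorespiratory index
#' strictly above 1.5 indicates glottic incompetence (air escapes faster
#' through an incompetent glottis while the /s/ time, limited only by the
#' respiratory system, is preserved).
#'
#' @param mft_a MFT of /a/ in seconds (> 0).
#' @param mft_s MFT of /s/ in seconds (> 0).
#' @return An `aerodynamic_measures`: `mft_a_s`, `mft_s_s`,
#'   `phonorespiratory_index`, `mft_pathological`, `pri_pathological`.
#' @examples
#' aerodynamics(mft_a = 11.4, mft_s = 19.4)
#' @export
aerodynamics <- function(mft_a, mft_s) {
  for (v in list(mft_a, mft_s)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop_validation("phonation times must be positive numbers (seconds)")
    }
  }
  idx <- mft_s / mft_a
  structure(
    list(mft_a_s = mft_a, mft_s_s = mft_s,
         phonorespiratory_index = idx,
         mft_pathological = mft_a < 10,
         pri_pathological = idx > 1.5),
    class = "aerodynamic_measures"
  )
}

#' @export
print.aerodynamic_measures <- function(x, ...) {
  cat(sprintf("<aerodynamics> MFT/a/ %.1f s%s, MFT/s/ %.1f s, PRI %.2f%s\n",
              x$mft_a_s, if (x$mft_pathological) " (pathological)" else "",
              x$mft_s_s, x$phonorespiratory_index,
              if (x$pri_pathological) " (pathological)" else ""))
  invisible(x)
}
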