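#' Generate a randomized synthetic patient session
#'
#' Draws plausible values for every block of a [patient_session()] from a
#' seeded RNG: random questionnaire responses, ratings, aerodynamic times,
#' stored acoustic numbers and stroboscopic measures. Intended for
#' persistence round-trip and report testing; the acoustic and strobe
#' numbers are drawn, not computed from signals (use [synth_voice()] and
#' [synth_strobe_sequence()] plus the analysis functions for end-to-end
#' sessions).
#'
#' @param seed Integer seed.
#' @param blocks Character vector naming which optional blocks to fill,
#'   any of `"acoustic"`, `"grade"`, `"strobe"`, `"vhi"`, `"short_form"`,
#'   `"grbas"`, `"vlg"`, `"aerodynamics"` (default all).
#' @return A [patient_session()].
#' @export
synth_session <- function(seed = 1,
                          blocks = c("acoustic", "grade", "strobe", "vhi",
                                     "short_form", "grbas", "vlg",
                                     "aerodynamics")) {
  rng <- local_rng(seed)
  ri <- function(n, lo, hi) as.integer(lo + floor(rng$unif(n) * (hi - lo + 1)))
  has <- function(b) b %in% blocks

  acoustic <- if (has("acoustic")) {
    structure(
      list(f0_mean = 90 + rng$unif(1) * 210,
           f0_sd = rng$unif(1) * 5,
           jitter_pct = rng$unif(1) * 3,
           shimmer_pct = rng$unif(1) * 12,
           hnr_db = 5 + rng$unif(1) * 30,
           freq_range_hz = 100 + rng$unif(1) * 300,
           segment_used = c(start = 0.5, end = 0.5 + rng$unif(1)),
           n_cycles = ri(1, 30, 200)),
      class = "acoustic_report"
    )
  }
  grade <- if (has("grade")) {
    structure(
      list(grade = grade_factor(grade_levels[ri(1, 1, 5)]),
           rule = "synthetic", manual = grade_factor(NA)),
      class = "yanagihara_grade"
    )
  }
  strobe <- if (has("strobe")) {
    areas <- ri(12, 400, 1400)
    structure(
      list(glottal_area_px = max(areas),
           right_size_px = ri(1, 0, 300),
           left_size_px = ri(1, 0, 300),
           deviation_deg = rng$unif(1) * 60,
           closure_type = closure_types[ri(1, 1, 6)],
           closure_type_manual = NA,
           movement = structure(c(list(areas_px = areas),
                                  movement_components(areas)),
                                class = "movement_series"),
           reference_frame = NA_integer_),
      class = "glottal_measures"
    )
  }
  vhi <- if (has("vhi")) {
    resp <- ri(30, 0, 4)
    out <- score_vhi(resp)
    out$responses <- resp
    out
  }
  sf <- if (has("short_form")) short_form(ri(1, 0, 10), ri(1, 0, 10))
  grbas <- if (has("grbas")) {
    if (rng$unif(1) < 0.5) {
      validate_grbas(ri(1, 0, 3), ri(1, 0, 3), ri(1, 0, 3))
    } else {
      validate_grbas(ri(1, 0, 3), ri(1, 0, 3), ri(1, 0, 3),
                     ri(1, 0, 3), ri(1, 0, 3))
    }
  }
  vlg <- if (has("vlg")) {
    vlg_rating(ri(1, 0, 10), ri(1, 0, 10), ri(1, 0, 10), ri(1, 0, 10),
               closure_types[ri(1, 1, 6)])
  }
  aero <- if (has("aerodynamics")) {
    aerodynamics(mft_a = 4 + rng$unif(1) * 24, mft_s = 4 + rng$unif(1) * 24)
  }

  patient_session(
    visit_date = as.Date("2010-01-01") + ri(1, 0, 1500),
    anamnesis = list(
      name = sprintf("case-%04d", ri(1, 1, 9999)),
      age = ri(1, 18, 80),
      sex = c("F", "M")[ri(1, 1, 2)],
      history = "synthetic record",
      toxic_habits = c("none", "smoker")[ri(1, 1, 2)]
    ),
    acoustic = acoustic, grade = grade, strobe = strobe, vhi = vhi,
    short_form = sf, grbas = grbas, vlg = vlg, aerodynamics = aero
  )
}
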