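#' Patient examination session
#'
#' One clinic visit: patient anamnesis, the visit date (sessions are
#' archived and ordered by it), and whichever of the five protocol blocks
#' were performed — subjective questionnaires, perceptual rating,
#' acoustic analysis, aerodynamic measures, and stroboscopic analysis.
#'
#' @param visit_date Visit date, `Date` or `"YYYY-MM-DD"` string
#'   (required).
#' @param anamnesis List with any of `name`, `age`, `sex`, `history`,
#'   `toxic_habits`.
#' @param acoustic An [acoustic_report()] or `NULL`.
#' @param grade A `yanagihara_grade` (see [grade_recording()]) or `NULL`.
#' @param strobe A `glottal_measures` (see [strobe_measures()]) or `NULL`.
#' @param vhi A `vhi_score` (see [score_vhi()]) or `NULL`.
#' @param short_form A `short_form_answers` (see [short_form()]) or `NULL`.
#' @param grbas A `grbas_vector` (see [validate_grbas()]) or `NULL`.
#' @param vlg A `vlg_rating` or `NULL`.
#' @param aerodynamics An `aerodynamic_measures` (see [aerodynamics()]) or
#'   `NULL`.
#' @return A `patient_session`.
#' @export
patient_session <- function(visit_date, anamnesis = list(),
                            acoustic = NULL, grade = NULL, strobe = NULL,
                            vhi = NULL, short_form = NULL, grbas = NULL,
                            vlg = NULL, aerodynamics = NULL) {
  if (missing(visit_date) || is.null(visit_date) ||
      is.na(suppressWarnings(as.Date(visit_date)))) {
    stop_validation("visit_date is mandatory (Date or 'YYYY-MM-DD')")
  }
  structure(
    list(
      visit_date = format(as.Date(visit_date)),
      anamnesis = anamnesis,
      acoustic = acoustic,
      grade = grade,
      strobe = strobe,
      scores = list(vhi = vhi, short_form = short_form, grbas = grbas,
                    vlg = vlg, aerodynamics = aerodynamics)
    ),
    class = "patient_session"
  )
}

#' @export
print.patient_session <- function(x, ...) {
  blocks <- c(
    subjective = !is.null(x$scores$vhi) || !is.null(x$scores$short_form),
    perceptual = !is.null(x$scores$grbas),
    acoustic = !is.null(x$acoustic),
    aerodynamic = !is.null(x$scores$aerodynamics),
    stroboscopic = !is.null(x$strobe) || !is.null(x$scores$vlg)
  )
  cat(sprintf("<patient_session> %s (%s): %s\n",
              if (!is.null(x$anamnesis$name)) x$anamnesis$name else "anonymous",
              x$visit_date,
              paste(names(blocks)[blocks], collapse = ", ")))
  invisible(x)
}

# ---- XML persistence --------------------------------------------------

num_chr <- function(x) sprintf("%.17g", as.numeric(x))
chr_num <- function(s) as.numeric(s)

xml_child_text <- function(node, name) {
  ch <- xml2::xml_find_first(node, name)
  if (inherits(ch, "xml_missing")) NULL else xml2::xml_text(ch)
}

add_num <- function(parent, name, value) {
  if (is.null(value) || length(value) == 0 || is.na(value)) return(invisible())
  xml2::xml_add_child(parent, name, num_chr(value))
  invisible()
}

add_chr <- function(parent, name, value) {
  if (is.null(value) || length(value) == 0 || is.na(value)) return(invisible())
  xml2::xml_add_child(parent, name, as.character(value))
  invisible()
}

session_to_node <- function(session, parent) {
  node <- xml2::xml_add_child(parent, "session", version = "1")
  add_chr(node, "visit-date", session$visit_date)
  an <- xml2::xml_add_child(node, "anamnesis")
  add_chr(an, "name", session$anamnesis$name)
  add_num(an, "age", session$anamnesis$age)
  add_chr(an, "sex", session$anamnesis$sex)
  add_chr(an, "history", session$anamnesis$history)
  add_chr(an, "toxic-habits", session$anamnesis$toxic_habits)

  if (!is.null(session$acoustic)) {
    ac <- xml2::xml_add_child(node, "acoustic")
    a <- session$acoustic
    add_num(ac, "f0-mean", a$f0_mean)
    add_num(ac, "f0-sd", a$f0_sd)
    add_num(ac, "jitter-pct", a$jitter_pct)
    add_num(ac, "shimmer-pct", a$shimmer_pct)
    add_num(ac, "hnr-db", a$hnr_db)
    add_num(ac, "freq-range-hz", a$freq_range_hz)
    add_num(ac, "segment-start", a$segment_used[1])
    add_num(ac, "segment-end", a$segment_used[2])
    add_num(ac, "n-cycles", a$n_cycles)
  }
  if (!is.null(session$grade)) {
    gd <- xml2::xml_add_child(node, "yanagihara")
    add_chr(gd, "grade", as.character(session$grade$grade))
    add_chr(gd, "rule", session$grade$rule)
    if (!is.null(session$grade$manual) && !is.na(session$grade$manual)) {
      add_chr(gd, "manual", as.character(session$grade$manual))
    }
  }
  if (!is.null(session$strobe)) {
    st <- xml2::xml_add_child(node, "strobe")
    s <- session$strobe
    add_num(st, "glottal-area-px", s$glottal_area_px)
    add_num(st, "right-size-px", s$right_size_px)
    add_num(st, "left-size-px", s$left_size_px)
    add_num(st, "deviation-deg", s$deviation_deg)
    add_chr(st, "closure-type", s$closure_type)
    if (!is.null(s$movement)) {
      add_num(st, "movement-index", s$movement$movement_index)
      add_chr(st, "areas-px", paste(s$movement$areas_px, collapse = " "))
    }
  }
  sc <- session$scores
  if (!is.null(sc$vhi)) {
    add_chr(xml2::xml_add_child(node, "vhi"), "responses",
            paste(sc$vhi$responses, collapse = " "))
  }
  if (!is.null(sc$short_form)) {
    sf <- xml2::xml_add_child(node, "short-form")
    add_num(sf, "quality", sc$short_form$quality)
    add_num(sf, "repercussion", sc$short_form$repercussion)
  }
  if (!is.null(sc$grbas)) {
    gr <- xml2::xml_add_child(node, "grbas")
    add_num(gr, "g", sc$grbas$G)
    add_num(gr, "r", sc$grbas$R)
    add_num(gr, "b", sc$grbas$B)
    add_num(gr, "a", sc$grbas$A)
    add_num(gr, "s", sc$grbas$S)
  }
  if (!is.null(sc$vlg)) {
    vl <- xml2::xml_add_child(node, "vlg")
    add_num(vl, "glottal-closure", sc$vlg$glottal_closure)
    add_num(vl, "mucosal-wave", sc$vlg$mucosal_wave)
    add_num(vl, "regularity", sc$vlg$regularity)
    add_num(vl, "symmetry", sc$vlg$symmetry)
    add_chr(vl, "closure-type", sc$vlg$closure_type)
  }
  if (!is.null(sc$aerodynamics)) {
    ae <- xml2::xml_add_child(node, "aerodynamics")
    add_num(ae, "mft-a", sc$aerodynamics$mft_a_s)
    add_num(ae, "mft-s", sc$aerodynamics$mft_s_s)
  }
  node
}

node_to_session <- function(node, path = "session") {
  vd <- xml_child_text(node, "visit-date")
  if (is.null(vd) || is.na(suppressWarnings(as.Date(vd)))) {
    stop_parse(sprintf("missing or invalid element: %s/visit-date", path))
  }
  an_node <- xml2::xml_find_first(node, "anamnesis")
  anam <- list()
  if (!inherits(an_node, "xml_missing")) {
    anam <- list(
      name = xml_child_text(an_node, "name"),
      age = if (!is.null(x <- xml_child_text(an_node, "age"))) chr_num(x),
      sex = xml_child_text(an_node, "sex"),
      history = xml_child_text(an_node, "history"),
      toxic_habits = xml_child_text(an_node, "toxic-habits")
    )
    anam <- anam[!vapply(anam, is.null, logical(1))]
  }

  acoustic <- NULL
  ac <- xml2::xml_find_first(node, "acoustic")
  if (!inherits(ac, "xml_missing")) {
    g <- function(nm) {
      x <- xml_child_text(ac, nm)
      if (is.null(x)) NA_real_ else chr_num(x)
    }
    acoustic <- structure(
      list(f0_mean = g("f0-mean"), f0_sd = g("f0-sd"),
           jitter_pct = g("jitter-pct"), shimmer_pct = g("shimmer-pct"),
           hnr_db = g("hnr-db"), freq_range_hz = g("freq-range-hz"),
           segment_used = c(start = g("segment-start"),
                            end = g("segment-end")),
           n_cycles = g("n-cycles")),
      class = "acoustic_report"
    )
  }

  grade <- NULL
  gd <- xml2::xml_find_first(node, "yanagihara")
  if (!inherits(gd, "xml_missing")) {
    grade <- structure(
      list(grade = grade_factor(xml_child_text(gd, "grade")),
           rule = xml_child_text(gd, "rule"),
           manual = grade_factor(xml_child_text(gd, "manual") %||% NA)),
      class = "yanagihara_grade"
    )
  }

  strobe <- NULL
  st <- xml2::xml_find_first(node, "strobe")
  if (!inherits(st, "xml_missing")) {
    g <- function(nm) {
      x <- xml_child_text(st, nm)
      if (is.null(x)) NA_real_ else chr_num(x)
    }
    movement <- NULL
    if (!is.null(a <- xml_child_text(st, "areas-px"))) {
      areas <- as.integer(strsplit(a, " ")[[1]])
      movement <- structure(c(list(areas_px = areas),
                              movement_components(areas)),
                            class = "movement_series")
    }
    strobe <- structure(
      list(glottal_area_px = as.integer(g("glottal-area-px")),
           right_size_px = g("right-size-px"),
           left_size_px = g("left-size-px"),
           deviation_deg = g("deviation-deg"),
           closure_type = xml_child_text(st, "closure-type"),
           closure_type_manual = NA,
           movement = movement,
           reference_frame = NA_integer_),
      class = "glottal_measures"
    )
  }

  vhi <- NULL
  vh <- xml2::xml_find_first(node, "vhi")
  if (!inherits(vh, "xml_missing")) {
    resp <- as.integer(strsplit(xml_child_text(vh, "responses"), " ")[[1]])
    vhi <- score_vhi(resp)
    vhi$responses <- resp
  }
  sf_node <- xml2::xml_find_first(node, "short-form")
  sf <- if (!inherits(sf_node, "xml_missing")) {
    short_form(chr_num(xml_child_text(sf_node, "quality")),
               chr_num(xml_child_text(sf_node, "repercussion")))
  }
  gr_node <- xml2::xml_find_first(node, "grbas")
  grbas <- if (!inherits(gr_node, "xml_missing")) {
    gx <- function(nm) {
      x <- xml_child_text(gr_node, nm)
      if (is.null(x)) NA else chr_num(x)
    }
    validate_grbas(gx("g"), gx("r"), gx("b"), gx("a"), gx("s"))
  }
  vl_node <- xml2::xml_find_first(node, "vlg")
  vlg <- if (!inherits(vl_node, "xml_missing")) {
    vlg_rating(chr_num(xml_child_text(vl_node, "glottal-closure")),
               chr_num(xml_child_text(vl_node, "mucosal-wave")),
               chr_num(xml_child_text(vl_node, "regularity")),
               chr_num(xml_child_text(vl_node, "symmetry")),
               xml_child_text(vl_node, "closure-type"))
  }
  ae_node <- xml2::xml_find_first(node, "aerodynamics")
  aero <- if (!inherits(ae_node, "xml_missing")) {
    aerodynamics(chr_num(xml_child_text(ae_node, "mft-a")),
                 chr_num(xml_child_text(ae_node, "mft-s")))
  }

  patient_session(visit_date = vd, anamnesis = anam, acoustic = acoustic,
                  grade = grade, strobe = strobe, vhi = vhi,
                  short_form = sf, grbas = grbas, vlg = vlg,
                  aerodynamics = aero)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save one or more patient sessions as XML
#'
#' Sessions are stored under a versioned root element; numeric fields are
#' written with 17 significant digits so that a save/load round trip is
#' lossless.
#'
#' @param sessions A [patient_session()] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_session <- function(sessions, path) {
  if (inherits(sessions, "patient_session")) sessions <- list(sessions)
  doc <- xml2::xml_new_root("phonolaryn-sessions", version = "1")
  for (s in sessions) {
    if (!inherits(s, "patient_session")) {
      stop_invalid_input("all elements must be patient_session objects")
    }
    session_to_node(s, doc)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Load patient sessions from XML
#'
#' Reads a session archive written by [save_session()], validating the
#' structure (a malformed document or a session without a visit date is a
#' parse error naming the offending element) and returning the sessions
#' ordered by visit date.
#'
#' @param path XML file path.
#' @return A list of [patient_session()] objects, ordered by visit date;
#'   a single session is still returned in a length-one list.
#' @export
load_session <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop_parse(sprintf("cannot parse XML '%s': %s", path,
                       conditionMessage(e)))
  })
  if (xml2::xml_name(doc) != "phonolaryn-sessions") {
    stop_parse("root element must be phonolaryn-sessions")
  }
  nodes <- xml2::xml_find_all(doc, "session")
  if (length(nodes) == 0) stop_parse("no session elements found")
  sessions <- lapply(seq_along(nodes), function(i) {
    node_to_session(nodes[[i]],
                    path = sprintf("phonolaryn-sessions/session[%d]", i))
  })
  sessions[order(vapply(sessions, function(s) s$visit_date, character(1)))]
}

# ---- report -----------------------------------------------------------

#' Render the examination report
#'
#' Self-contained HTML with the five protocol blocks (subjective,
#' perceptual, acoustic, aerodynamic, stroboscopic), the Yanagihara grade
#' and the radar figure of the vocal profile. Blocks that were not
#' examined are marked as such. Output is deterministic for a fixed
#' `timestamp`.
#'
#' @param session A [patient_session()].
#' @param profile Optional [vocal_profile()]; computed from the session
#'   when omitted and enough blocks are present.
#' @param file Optional output path; when given the HTML is written there.
#' @param timestamp Optional fixed timestamp string for reproducible
#'   output; defaults to the current time.
#' @return The HTML document as a character scalar (invisibly when `file`
#'   is given).
#' @export
render_report <- function(session, profile = NULL, file = NULL,
                          timestamp = NULL) {
  if (!inherits(session, "patient_session")) {
    stop_invalid_input("expected a patient_session")
  }
  has_any <- !is.null(session$acoustic) || !is.null(session$strobe) ||
    !is.null(session$grade) ||
    any(!vapply(session$scores, is.null, logical(1)))
  if (!has_any) {
    stop_nothing_to_report("session has no analysis blocks to report")
  }
  if (is.null(profile)) {
    profile <- suppressWarnings(build_profile(session))
  }
  if (is.null(timestamp)) timestamp <- format(Sys.time(), "%Y-%m-%d %H:%M")

  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  row <- function(k, v) sprintf("<tr><th>%s</th><td>%s</td></tr>", esc(k), esc(v))
  block <- function(title, body) {
    sprintf("<section><h2>%s</h2>\n%s\n</section>", esc(title), body)
  }
  not_examined <- "<p class='na'>not examined</p>"
  tbl <- function(rows) sprintf("<table>%s</table>", paste(rows, collapse = "\n"))

  subj <- if (!is.null(session$scores$vhi) || !is.null(session$scores$short_form)) {
    rows <- character(0)
    if (!is.null(v <- session$scores$vhi)) {
      rows <- c(rows,
        row("VHI functional", sprintf("%d (%s)", v$functional, v$bands[["functional"]])),
        row("VHI physical", sprintf("%d (%s)", v$physical, v$bands[["physical"]])),
        row("VHI emotional", sprintf("%d (%s)", v$emotional, v$bands[["emotional"]])),
        row("VHI global", sprintf("%d (%s)", v$total, v$global_band)))
    }
    if (!is.null(s <- session$scores$short_form)) {
      rows <- c(rows,
        row("Subjective quality", sprintf("%d/10 (%s)", s$quality, s$quality_category)),
        row("Subjective repercussion", sprintf("%d/10 (%s)", s$repercussion, s$repercussion_category)))
    }
    tbl(rows)
  } else not_examined

  perc <- if (!is.null(g <- session$scores$grbas)) {
    fmt <- function(v) if (is.na(v)) "not rated" else as.character(v)
    tbl(c(row("G (grade)", fmt(g$G)), row("R (roughness)", fmt(g$R)),
          row("B (breathiness)", fmt(g$B)), row("A (asthenia)", fmt(g$A)),
          row("S (strain)", fmt(g$S))))
  } else not_examined

  acou <- if (!is.null(a <- session$acoustic)) {
    rows <- c(
      row("F0 mean", sprintf("%.2f Hz (sd %.2f)", a$f0_mean, a$f0_sd)),
      row("Jitter", sprintf("%.2f %%", a$jitter_pct)),
      row("Shimmer", sprintf("%.2f %%", a$shimmer_pct)),
      row("HNR", sprintf("%.2f dB", a$hnr_db)))
    if (is.finite(a$freq_range_hz)) {
      rows <- c(rows, row("Frequency range", sprintf("%.1f Hz", a$freq_range_hz)))
    }
    if (!is.null(session$grade)) {
      rows <- c(rows, row("Yanagihara grade", as.character(session$grade$grade)))
    }
    tbl(rows)
  } else not_examined

  aero <- if (!is.null(ae <- session$scores$aerodynamics)) {
    tbl(c(
      row("MFT /a/", sprintf("%.1f s%s", ae$mft_a_s,
                             if (ae$mft_pathological) " - pathological" else "")),
      row("MFT /s/", sprintf("%.1f s", ae$mft_s_s)),
      row("Phonorespiratory index",
          sprintf("%.2f%s", ae$phonorespiratory_index,
                  if (ae$pri_pathological) " - pathological" else ""))))
  } else not_examined

  strobo <- if (!is.null(st <- session$strobe) || !is.null(session$scores$vlg)) {
    rows <- character(0)
    if (!is.null(st)) {
      rows <- c(rows,
        row("Glottal area", sprintf("%d px", st$glottal_area_px)),
        row("Right size", sprintf("%g px", st$right_size_px)),
        row("Left size", sprintf("%g px", st$left_size_px)),
        row("Deviation", sprintf("%.1f deg", st$deviation_deg)),
        row("Closure type", st$closure_type))
      if (!is.null(st$movement)) {
        rows <- c(rows, row("Movement index",
                            sprintf("%.3f", st$movement$movement_index)))
      }
    }
    if (!is.null(v <- session$scores$vlg)) {
      rows <- c(rows,
        row("Glottal closure (0-10)", v$glottal_closure),
        row("Mucosal wave (0-10)", v$mucosal_wave),
        row("Regularity (0-10)", v$regularity),
        row("Symmetry (0-10)", v$symmetry))
    }
    tbl(rows)
  } else not_examined

  prof_rows <- vapply(names(profile$radii), function(a) {
    row(gsub("_", " ", a), sprintf("%.2f", profile$radii[[a]]))
  }, character(1))
  prof <- paste0(
    radar_svg(profile), "\n",
    tbl(c(prof_rows,
          row("Profile polygon area", sprintf("%.3f", profile_area(profile)))))
  )

  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'>\n",
    "<title>Voice examination report</title>\n",
    "<style>body{font-family:sans-serif;max-width:760px;margin:2em auto}",
    "table{border-collapse:collapse}th{text-align:left;padding:2px 12px 2px 0}",
    "td{padding:2px 0}section{margin-bottom:1.4em}.na{color:#888}</style>",
    "</head><body>\n",
    sprintf("<h1>Voice examination report</h1>\n<p>%s - visit %s - generated %s</p>\n",
            esc(session$anamnesis$name %||% "anonymous"),
            esc(session$visit_date), esc(timestamp)),
    block("Subjective assessment", subj),
    block("Perceptual assessment (GRBAS)", perc),
    block("Acoustic analysis", acou),
    block("Aerodynamic analysis", aero),
    block("Stroboscopic analysis", strobo),
    block("Vocal profile", prof),
    "</body></html>\n"
  )
  if (!is.null(file)) {
    writeLines(html, file, useBytes = TRUE)
    return(invisible(html))
  }
  html
}
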