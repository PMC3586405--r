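axes <- profile_axes()

# a session with every parameter exactly at its normal limit
limit_session <- function() {
  patient_session(
    visit_date = "2026-02-01",
    acoustic = structure(
      list(f0_mean = 180, f0_sd = 1, jitter_pct = 1.0, shimmer_pct = 3.8,
           hnr_db = 20, freq_range_hz = NA_real_,
           segment_used = c(start = 0.5, end = 1.5), n_cycles = 50),
      class = "acoustic_report"),
    short_form = short_form(7, 3),
    grbas = validate_grbas(1, 1, 1),
    vlg = vlg_rating(2, 2, 2, 2, "posterior"),
    aerodynamics = aerodynamics(mft_a = 10, mft_s = 12)
  )
}

test_that("normalization has the limit circle as its fixed point", {
  p <- build_profile(limit_session())
  expect_equal(unname(p$radii), rep(1, 13), tolerance = 1e-12)

  # jitter at twice its limit doubles that radius only
  s <- limit_session()
  s$acoustic$jitter_pct <- 2.0
  p2 <- build_profile(s)
  expect_equal(unname(p2$radii[["jitter"]]), 2)
  expect_equal(unname(p2$radii[axes$axes != "jitter"]), rep(1, 12),
               tolerance = 1e-12)
})

test_that("a healthy synthetic session stays inside the normal circle", {
  v <- synth_voice(voice_spec(f0 = 180, duration = 1.2, seed = 2))
  session <- patient_session(
    visit_date = "2026-02-02",
    acoustic = acoustic_report(v$recording),
    short_form = short_form(9, 1),
    grbas = validate_grbas(0, 0, 0),
    vlg = vlg_rating(0, 0, 0, 0),
    aerodynamics = aerodynamics(mft_a = 20, mft_s = 22)
  )
  p <- build_profile(session)
  expect_true(all(p$radii <= 1))
})

test_that("missing blocks give radius 0 with a warning; bad values error", {
  s <- limit_session()
  s$scores$grbas <- NULL
  expect_warning(p <- build_profile(s), "perception_g")
  expect_equal(unname(p$radii[["perception_g"]]), 0)

  vals <- setNames(rep(1, 13), axes$axes)
  vals["hnr"] <- Inf
  expect_error(vocal_profile(vals), class = "phl_validation")
  vals["hnr"] <- -2
  expect_error(vocal_profile(vals), class = "phl_validation")
})

test_that("profile area matches the closed form and the shoelace oracle", {
  unit <- vocal_profile(setNames(
    c(7, 3, 1, 1, 1, 10, 1.0, 3.8, 20, 2, 2, 2, 2), axes$axes))
  expect_equal(profile_area(unit), 13 / 2 * sin(2 * pi / 13),
               tolerance = 1e-12)

  zero <- unit
  zero$radii[] <- 0
  expect_equal(profile_area(zero), 0)

  for (seed in 1:5) {
    r <- withr::with_seed(seed, stats::runif(13, 0, 3))
    p <- unit
    p$radii[] <- r
    expect_equal(profile_area(p), shoelace_area(r), tolerance = 1e-12)
  }
})

test_that("area and radii are monotone in clinical worsening", {
  p <- build_profile(limit_session())
  a0 <- profile_area(p)
  for (i in 1:13) {
    q <- p
    q$radii[i] <- q$radii[i] * 1.5
    expect_gt(profile_area(q), a0)
  }
  # worsening a raw value never lowers its radius
  s <- limit_session()
  s$acoustic$shimmer_pct <- 6
  expect_gt(build_profile(s)$radii[["shimmer"]],
            p$radii[["shimmer"]])
  s2 <- limit_session()
  s2$acoustic$hnr_db <- 10   # lower HNR is worse
  expect_gt(build_profile(s2)$radii[["hnr"]], p$radii[["hnr"]])
})

test_that("XML round trip is lossless and archives order by visit date", {
  s <- synth_session(seed = 7)
  path <- withr::local_tempfile(fileext = ".xml")
  save_session(s, path)
  s2 <- load_session(path)[[1]]
  expect_equal(s, s2, tolerance = 1e-12)

  trio <- list(synth_session(3), synth_session(4), synth_session(5))
  path2 <- withr::local_tempfile(fileext = ".xml")
  save_session(trio, path2)
  loaded <- load_session(path2)
  dates <- vapply(loaded, function(x) x$visit_date, character(1))
  expect_false(is.unsorted(dates))
})

test_that("schema violations are reported with their element path", {
  s <- synth_session(seed = 9)
  path <- withr::local_tempfile(fileext = ".xml")
  save_session(s, path)
  doc <- xml2::read_xml(path)
  xml2::xml_remove(xml2::xml_find_first(doc, "session/visit-date"))
  bad <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc, bad)
  expect_error(load_session(bad), "visit-date", class = "phl_parse")

  garbled <- withr::local_tempfile(fileext = ".xml")
  writeLines("<phonolaryn-sessions><session></phonolaryn-sessions>", garbled)
  expect_error(load_session(garbled), class = "phl_parse")

  expect_error(patient_session(visit_date = NULL),
               class = "phl_validation")
})

test_that("the report contains every profile axis and the acoustic numbers", {
  s <- synth_session(seed = 12)
  html <- render_report(s, timestamp = "2026-01-01 00:00")
  for (a in axes$axes) {
    expect_match(html, gsub("_", " ", a), fixed = TRUE)
  }
  expect_match(html, "F0 mean")
  expect_match(html, "Jitter")
  expect_match(html, "Shimmer")
  expect_match(html, "HNR")
  expect_match(html, "<svg", fixed = TRUE)
})

test_that("a voice-only session reports unexamined blocks", {
  v <- synth_voice(voice_spec(f0 = 180, duration = 1.2, seed = 2))
  s <- patient_session(visit_date = "2026-03-01",
                       acoustic = acoustic_report(v$recording))
  html <- suppressWarnings(render_report(s, timestamp = "2026-01-01 00:00"))
  expect_match(html, "not examined")
  expect_match(html, "F0 mean")
})

test_that("the report is deterministic under a fixed timestamp", {
  s <- synth_session(seed = 21)
  h1 <- render_report(s, timestamp = "2026-01-01 00:00")
  h2 <- render_report(s, timestamp = "2026-01-01 00:00")
  expect_identical(h1, h2)
  empty <- patient_session(visit_date = "2026-01-05")
  expect_error(render_report(empty), class = "phl_nothing_to_report")
})
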