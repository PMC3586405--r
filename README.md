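# phonolaryn

Computer-aided examination of dysphonic voices for ENT and speech-therapy
practice, implementing the five-step clinical protocol in one package:

1. **Subjective** — Voice Handicap Index (VHI-30; three 10-item subscales,
   items 0–4, global 0–120 with Low/Moderate/Serious/Severe bands) and the
   two-question short form (0–10 voice quality and socio-occupational
   repercussion).
2. **Perceptual** — GRBAS rating (Grade, Roughness, Breathiness, Asthenia,
   Strain; each 0–3, A/S optional).
3. **Acoustic** — objective analysis of sustained vowels: F0 by normalized
   cross-correlation, local jitter `100·mean|T_i − T_{i−1}|/mean(T)`, local
   shimmer `100·mean|A_i − A_{i−1}|/mean(A)`, cycle-synchronous
   harmonics-to-noise ratio `10·log10(P_periodic/P_noise)` dB, and the
   physiological frequency range from the lowest/highest sustainable /a/.
   A narrowband (46 ms Hann) spectrogram is graded automatically on the
   Yanagihara I–IV hoarseness scale from band-wise harmonicity (first and
   second formant regions, high-frequency noise above 3000 Hz).
4. **Aerodynamic** — maximum phonation time (pathological below 10 s) and
   the phonorespiratory index MFT(/s/)/MFT(/a/) (glottic incompetence
   above 1.5).
5. **Stroboscopic** — pixel-level measures from laryngeal strobe frames:
   glottal-space area (automatic Otsu segmentation + largest dark
   component), per-fold lesion sizes (edge-profile protrusions against a
   robust baseline), fold deviation angle (total-least-squares edge
   lines), and a movement index (area-waveform amplitude × spectral
   regularity), plus the clinician's 0–10 ratings of closure, mucosal
   wave, regularity and symmetry.

Results are combined into the 13-axis **vocal profile** radar chart, each
axis normalized so 1.0 is the edge of the normal range; the polygon area
`½·sin(2π/13)·Σ r_i·r_{i+1}` summarizes overall severity. Sessions persist
as XML and render to a self-contained HTML report with an SVG radar.

Seeded generators (`synth_voice()`, `synth_strobe_sequence()`,
`synth_session()`) produce vowels with controlled F0/jitter/shimmer/HNR and
strobe frames with exactly known gap areas, lesion sizes and edge angles, so
the whole chain is testable without patient data.

## Worked example

```r
library(phonolaryn)

v <- synth_voice(voice_spec(f0 = 178.12, jitter_pct = 0.35,
                            shimmer_pct = 4.10, hnr_db = 23.12, seed = 1))
acoustic_report(v$recording, target_cycles = 200)
#> <acoustic_report>
#>   F0      178.12 Hz (sd 0.16)
#>   jitter  0.329 %
#>   shimmer 4.196 %
#>   HNR     22.55 dB
#>   segment 0.485-1.485 s (177 cycles)

st <- synth_strobe_sequence(strobe_spec(shape = "vgap",
                                        edge_angles_deg = c(-15, 15),
                                        gap_height = 90,
                                        lesion_side = "right",
                                        lesion_px = 120))
strobe_measures(st$frames)
#> <glottal_measures>
#>   glottal area  2076 px (frame 1)
#>   lesion right  0 px, left 105.5 px
#>   deviation     28.2 deg
#>   closure type  irregular (suggested)
```

The acoustic estimates recover the generator's settings (the jitter/shimmer
values differ from 0.35/4.10 only by the sampling variability of a
~180-cycle segment); the strobe measures recover the constructed geometry —
the patient's *left* fold is on the *right* of the image, hence the side
swap. A full visit is assembled with `patient_session()`, normalized with
`build_profile()`, summarized with `profile_area()`, stored with
`save_session()`/`load_session()` and rendered with `render_report()`.

A command-line front end is installed at
`system.file("cli/phonolaryn", package = "phonolaryn")` with subcommands
`voice analyze`, `spectro grade`, `scales vhi|aero`, `strobe analyze` and
`synth voice|strobe`, all emitting JSON.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the whole pipeline from scratch against the installed package:
it synthesizes the examination inputs (sustained, lowest- and highest-pitch
vowels; a modulated strobe sequence with a known lesion), runs the acoustic,
spectrographic and image analyses, scores the questionnaires, assembles the
session, verifies the XML round trip, renders the report and writes the
result JSON to `--out`.
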