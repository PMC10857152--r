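#' Reference cohort tables of the emulated phantom study
#'
#' `cohort_demographics()` returns the 19-case demographic table of the
#' phantom cohort the synthetic generator emulates (sex, age, pathology,
#' lesion localization, surgical position). `cohort_hologram_content()`
#' returns the per-case reference-image and hologram inventory: which
#' structure classes were segmented, how many lesions (`n_lesions`, 1 or
#' 2; 21 in total across the 19 cases) and how many scalp fiducial
#' markers each case carries.
#'
#' Note one internal inconsistency of the source inventory, reproduced
#' verbatim rather than resolved: the per-case marker column sums to 125
#' while the printed overall marker count is 124 (returned as the
#' `printed_marker_total` attribute).
#'
#' @return A tibble (19 rows).
#' @examples
#' demographics_summary(cohort_demographics())
#' @export
cohort_demographics <- function() {
  tibble(
    case = sprintf("%02d", 1:19),
    sex = c("M", "M", "M", "M", "M", "F", "M", "F", "F", "F", "F", "M",
            "F", "M", "F", "M", "M", "M", "M"),
    age = c(49, 58, 8, 62, 41, 27, 51, 66, 37, 73, 54, 79, 41, 74, 58,
            84, 63, 57, 51),
    pathology = c("Metastasis", "Diffused astrocytoma",
                  "Cavernous malformation", "Meningioma",
                  "Diffuse large B-cell lymphoma", "Meningioma",
                  "Metastasis", "Metastasis", "Aneurysm", "Metastasis",
                  "Meningioma", "Metastasis", "High grade glioma",
                  "Metastasis", "Metastasis", "Hematoma", "Hematoma",
                  "Hematoma", "Hematoma"),
    localization = c("Left temporal", "Right temporal", "Left frontal",
                     "Left cerebellar", "Left occipital", "Left frontal",
                     "Right occipital", "Bilateral occipital",
                     "Fourth ventricular", "Right parietal",
                     "Left parietal", "Left occipital", "Left parietal",
                     "Right frontal and occipital", "Left occipital",
                     "Right frontal", "Right basal ganglia",
                     "Right basal ganglia", "Left basal ganglia"),
    position = c("Supine", "Supine", "Supine", "Prone", "Prone",
                 "Supine", "Prone", "Prone", "Prone", "Left-lateral",
                 "Left-lateral", "Right-lateral", "Right-lateral",
                 "Left-lateral", "Prone", "Supine", "Supine", "Supine",
                 "Supine"))
}

#' @rdname cohort_demographics
#' @export
cohort_hologram_content <- function() {
  yes_for <- function(cases) 1:19 %in% cases
  out <- tibble(
    case = sprintf("%02d", 1:19),
    reference_image = c(rep("T1", 15), rep("CT", 4)),
    n_lesions = ifelse(1:19 %in% c(8, 14), 2L, 1L),
    arteries = yes_for(1:15),
    venous_sinus = yes_for(1:15),
    ventricle = yes_for(1:19),
    frontal_sinus = yes_for(16:18),
    optic_radiation = yes_for(c(1, 2, 5, 8, 12, 14, 15)),
    pyramidal_tract = yes_for(c(6, 9, 10, 11, 12, 13, 14)),
    puncture_path = yes_for(16:19),
    endoscopic_path = yes_for(c(17, 18, 19)),
    bone_flap = yes_for(c(17, 18, 19)),
    n_markers = c(7L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 6L, 6L, 6L, 6L, 6L,
                  6L, 6L, 7L, 6L, 7L, 7L),
    scalp_quadrants = yes_for(1:19))
  attr(out, "printed_marker_total") <- 124L
  out
}

#' Write the reference cohort tables as CSV fixtures
#'
#' Emits `cohort_demographics.csv` and `cohort_hologram_content.csv` into
#' `outdir` for the descriptive-statistics stage. Re-emission is
#' byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_fixture_tables <- function(outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, mode = 2) != 0) {
    abort(paste0("cannot write to directory: ", outdir))
  }
  paths <- c(file.path(outdir, "cohort_demographics.csv"),
             file.path(outdir, "cohort_hologram_content.csv"))
  readr::write_csv(cohort_demographics(), paths[1])
  readr::write_csv(cohort_hologram_content(), paths[2])
  invisible(paths)
}
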