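#' Resolved configuration for an end-to-end pipeline run
#'
#' Collects every switch that affects the analysis: the master seed, the
#' cohort shape, the noise model, the lateral-rotation sign convention,
#' the HD95 mode and percentile rule. A resolved copy (plus the package
#' version and a config hash) is written next to every run's outputs, and
#' re-running with the same config reproduces the outputs bit-for-bit.
#'
#' @param seed Master seed for all randomness.
#' @param n_cases,position_mix Cohort shape (see [generate_cohort()]).
#' @param noise A [noise_model()].
#' @param lateral_sign Lateral rotation convention (see [make_fem()]).
#' @param hd95_mode `"directed"` or `"symmetric"` (see [hd95()]).
#' @param percentile_rule `"lower"` or `"linear"` (see [hd95()]).
#' @param outdir Output directory for report files, or `NULL` to skip
#'   writing.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, n_cases = 19, position_mix = c(8, 6, 5),
                       noise = noise_model(),
                       lateral_sign = "left_positive",
                       hd95_mode = "directed",
                       percentile_rule = "lower",
                       outdir = NULL) {
  structure(
    list(seed = as.integer(seed), n_cases = n_cases,
         position_mix = position_mix, noise = noise,
         lateral_sign = match.arg(lateral_sign,
                                  c("left_positive", "right_positive")),
         hd95_mode = match.arg(hd95_mode, c("directed", "symmetric")),
         percentile_rule = match.arg(percentile_rule, c("lower", "linear")),
         outdir = outdir),
    class = "run_config")
}

# supine / prone / lateral grouping used in the position comparisons
position_group <- function(position) {
  ifelse(position %in% c("left_lateral", "right_lateral"), "lateral",
         position)
}

#' Run the full simulate-register-evaluate-report pipeline
#'
#' Generates a synthetic phantom cohort, fits the rigid registration of
#' each case, computes the landmark metrics (FLE, TRE, FRE, Frobenius
#' norm) and lesion metrics (volume, depth, L2 norm, DSC, HD95), and runs
#' the cohort statistics: Kruskal-Wallis position comparisons with
#' Bonferroni-corrected Mann-Whitney post hoc tests, Spearman
#' correlations of DSC/HD95 with the lesion characteristics, and
#' median-split subgroup comparisons. When `config$outdir` is set, report
#' CSVs plus the resolved config (JSON, with package version and config
#' hash) are written there.
#'
#' @param config A [run_config()].
#' @return A list (invisibly when writing files): `cohort`,
#'   `per_marker` (one row per marker and metric kind), `landmark_summary`
#'   (per case), `landmark_by_position`, `lesions` (per lesion),
#'   `lesion_by_position`, `position_tests`, `correlations`,
#'   `median_splits`, `config`.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(seed = 7, n_cases = 6,
#'                                position_mix = c(2, 2, 2)))
#' res$landmark_by_position
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(n_cases = config$n_cases,
                            position_mix = config$position_mix,
                            noise = config$noise, seed = config$seed)

  per_marker <- purrr::map_dfr(cohort, function(cs) {
    fit <- fit_rigid(cs$fiducials_C, cs$fiducials_P)
    purrr::map_dfr(
      list(compute_fle(cs$fiducials_V, cs$fiducials_C),
           compute_tre(cs$fiducials_P, cs$fiducials_C),
           compute_fre(cs$fiducials_C, cs$fiducials_P, fit)),
      function(dv) dplyr::mutate(tibble::as_tibble(dv),
                                 case_id = cs$case_id,
                                 kind = attr(dv, "kind"),
                                 .before = 1))
  })

  landmark_summary <- purrr::map_dfr(cohort, summarize_case)
  landmark_summary$group <- position_group(landmark_summary$position)

  lesions <- purrr::map_dfr(cohort, evaluate_lesions,
                            mode = config$hd95_mode,
                            rule = config$percentile_rule)
  lesions$group <- position_group(lesions$position)

  by_pos <- function(df, cols) {
    overall <- dplyr::summarise(
      df, dplyr::across(dplyr::all_of(cols),
                        list(mean = mean, sd = sd)),
      n = dplyr::n())
    per <- dplyr::summarise(
      dplyr::group_by(df, .data$group),
      dplyr::across(dplyr::all_of(cols), list(mean = mean, sd = sd)),
      n = dplyr::n(), .groups = "drop")
    dplyr::bind_rows(dplyr::mutate(overall, group = "overall",
                                   .before = 1), per)
  }
  landmark_by_position <- by_pos(landmark_summary,
                                 c("mean_fle", "mean_tre", "mean_fre", "fn"))
  lesion_by_position <- by_pos(lesions,
                               c("volume_cm3", "depth_cm", "l2_norm_cm",
                                 "dsc", "hd95_mm"))

  # degenerate cohorts (e.g. zero noise) make some tests undefined; those
  # rows are reported as NA rather than failing the whole report
  one_test <- function(df, mt) {
    tryCatch({
      cmp <- compare_positions(df, mt, group = "group")
      tibble(metric = mt, omnibus_p = cmp$omnibus_p,
             alpha_adjusted = cmp$alpha_adjusted,
             min_pairwise_p = min(cmp$pairwise$p))
    }, error = function(e) tibble(metric = mt, omnibus_p = NA_real_,
                                  alpha_adjusted = 0.05 / 3,
                                  min_pairwise_p = NA_real_))
  }
  position_tests <- dplyr::bind_rows(
    purrr::map_dfr(c("mean_fle", "mean_tre", "mean_fre", "fn"),
                   function(mt) one_test(landmark_summary, mt)),
    purrr::map_dfr(c("dsc", "hd95_mm"),
                   function(mt) one_test(lesions, mt)))

  correlations <- purrr::map_dfr(
    list(c("dsc", "volume_cm3"), c("dsc", "depth_cm"),
         c("dsc", "l2_norm_cm"), c("hd95_mm", "volume_cm3"),
         c("hd95_mm", "depth_cm"), c("hd95_mm", "l2_norm_cm")),
    function(pr) tryCatch(
      correlate(lesions, pr[2], pr[1]),
      error = function(e) tibble(pair = paste0(pr[2], "-", pr[1]),
                                 rho = NA_real_, p = NA_real_,
                                 n = nrow(lesions))))

  median_splits <- purrr::map_dfr(
    list(c("hd95_mm", "volume_cm3"), c("hd95_mm", "depth_cm"),
         c("hd95_mm", "l2_norm_cm"), c("dsc", "volume_cm3"),
         c("dsc", "depth_cm"), c("dsc", "l2_norm_cm")),
    function(pr) tryCatch(
      median_split(lesions, pr[1], pr[2]),
      error = function(e) tibble(characteristic = pr[2], metric = pr[1],
                                 median = NA_real_)))

  result <- list(cohort = cohort, per_marker = per_marker,
                 landmark_summary = landmark_summary,
                 landmark_by_position = landmark_by_position,
                 lesions = lesions,
                 lesion_by_position = lesion_by_position,
                 position_tests = position_tests,
                 correlations = correlations,
                 median_splits = median_splits,
                 config = config)

  if (!is.null(config$outdir)) {
    write_report(result, config$outdir)
    return(invisible(result))
  }
  result
}

# write the report CSVs and the resolved config next to them
write_report <- function(result, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok) abort(paste0("cannot create output directory: ", outdir))
  tables <- c("per_marker", "landmark_summary", "landmark_by_position",
              "lesions", "lesion_by_position", "position_tests",
              "correlations", "median_splits")
  for (tb in tables) {
    readr::write_csv(result[[tb]], file.path(outdir, paste0(tb, ".csv")))
  }
  cfg <- result$config
  resolved <- list(
    package = "phantomreg",
    version = as.character(utils::packageVersion("phantomreg")),
    seed = cfg$seed, n_cases = cfg$n_cases,
    position_mix = cfg$position_mix,
    noise = unclass(cfg$noise),
    lateral_sign = cfg$lateral_sign, hd95_mode = cfg$hd95_mode,
    percentile_rule = cfg$percentile_rule)
  resolved$config_hash <- rlang::hash(resolved)
  jsonlite::write_json(resolved, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_fixture_tables(outdir)
  invisible(outdir)
}
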