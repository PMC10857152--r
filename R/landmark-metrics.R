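#' Landmark-based accuracy metrics
#'
#' Per-marker displacement vectors between the ordered fiducial sets of a
#' navigation accuracy experiment, all expressed in the reference image
#' frame (RICS, mm):
#'
#' * **FLE** (fiducial localization error), `V_i - C_i`: displacement from a
#'   marker's ground-truth centroid to its perceived *virtual* counterpart.
#'   Measures probe/perception error and serves as the quality control for
#'   the measurement process itself.
#' * **TRE** (target registration error), `P_i - C_i`: displacement from the
#'   ground-truth centroid to the perceived *physical* counterpart after the
#'   system's registration -- the headline virtual-to-physical accuracy.
#' * **FRE** (fiducial registration error), `R* C_i + t* - P_i`: the
#'   residual after optimally rigidly aligning C onto P; gauges the
#'   geometric consistency of the two sets and underpins extrapolated
#'   (lesion-level) accuracy.
#'
#' Each function returns a `displacement_vectors` tibble with columns
#' `label`, `dx`, `dy`, `dz`, `magnitude` and a `kind` attribute.
#'
#' @param v_set,p_set,c_set [fiducial_set()]s with matching labels in
#'   matching order (virtual, physical, ground truth).
#' @param fit A [fit_rigid()] result produced from `(c_set, p_set)`.
#'
#' @return A `displacement_vectors` tibble.
#' @examples
#' c_pts <- fiducial_set(cbind(c(0, 80, 0), c(0, 0, 90), c(0, 0, 0)))
#' v_pts <- fiducial_set(fid_matrix(c_pts) + rep(c(1, 2, 2), each = 3),
#'                       role = "V")
#' compute_fle(v_pts, c_pts)$magnitude  # all 3 mm
#' @name landmark-metrics
NULL

displacement_vectors <- function(labels, delta, kind) {
  dimnames(delta) <- NULL
  out <- tibble(label = labels,
                dx = delta[, 1], dy = delta[, 2], dz = delta[, 3],
                magnitude = sqrt(rowSums(delta^2)))
  structure(out, kind = kind,
            class = c("displacement_vectors", class(out)))
}

#' @rdname landmark-metrics
#' @export
compute_fle <- function(v_set, c_set) {
  check_matched_sets(v_set, c_set, "virtual (V)", "ground-truth (C)")
  displacement_vectors(c_set$label, fid_matrix(v_set) - fid_matrix(c_set),
                       kind = "FLE")
}

#' @rdname landmark-metrics
#' @export
compute_tre <- function(p_set, c_set) {
  check_matched_sets(p_set, c_set, "physical (P)", "ground-truth (C)")
  displacement_vectors(c_set$label, fid_matrix(p_set) - fid_matrix(c_set),
                       kind = "TRE")
}

#' @rdname landmark-metrics
#' @export
compute_fre <- function(c_set, p_set, fit) {
  stopifnot(inherits(fit, "rigid_fit"))
  check_matched_sets(c_set, p_set, "ground-truth (C)", "physical (P)")
  if (fit$n != nrow(c_set) ||
      !identical(as.character(fit$residuals$label), as.character(c_set$label))) {
    abort("fit was not produced from these point sets (labels differ)")
  }
  delta <- transform_points(fit$matrix, fid_matrix(c_set)) - fid_matrix(p_set)
  displacement_vectors(c_set$label, delta, kind = "FRE")
}

#' Frobenius norm of the misregistration
#'
#' The entrywise (Frobenius) norm of the fitted 4x4 transform minus the
#' identity, over all 16 entries. It summarizes the overall "size" of the
#' fitted displacement in a single number, mixing dimensionless rotation
#' residuals with millimetre translation entries by construction. A pure
#' translation `(3, 4, 0)` gives 5; a 180-degree rotation gives
#' `sqrt(8)`.
#'
#' @param fit A [fit_rigid()] or [rigid_transform()] result.
#' @param decompose If `TRUE`, additionally return the rotation-part and
#'   translation-part norms (an interpretability extension, off by
#'   default).
#' @return The Frobenius norm (a single number), or when
#'   `decompose = TRUE` a one-row tibble with columns `fn`,
#'   `fn_rotation`, `fn_translation`.
#' @export
compute_fn <- function(fit, decompose = FALSE) {
  stopifnot(inherits(fit, "rigid_fit"))
  d <- fit$matrix - diag(4)
  fn <- sqrt(sum(d^2))
  if (!decompose) return(fn)
  tibble(fn = fn,
         fn_rotation = sqrt(sum((fit$rotation - diag(3))^2)),
         fn_translation = sqrt(sum(fit$translation^2)))
}

#' Per-case landmark accuracy summary
#'
#' Computes FLE, TRE, FRE and the Frobenius norm for one phantom case and
#' summarizes the per-marker magnitudes as mean and sample standard
#' deviation (n - 1). In the study design the virtual set V is measured
#' before the physical set P so that the quality-control FLE is acquired
#' before errors can accumulate; the `measurement_order` column records
#' this ordering.
#'
#' @param case A `case_record` (see [generate_case()]) or any list with
#'   elements `case_id`, `position`, `fiducials_C`, `fiducials_V`,
#'   `fiducials_P`.
#' @return A one-row tibble with per-metric means and SDs (mm) and `fn`.
#' @export
summarize_case <- function(case) {
  needed <- c("fiducials_C", "fiducials_V", "fiducials_P")
  missing <- needed[!vapply(needed, function(f) !is.null(case[[f]]), TRUE)]
  if (length(missing) > 0) {
    abort(paste0("case is missing point sets: ",
                 paste(missing, collapse = ", ")))
  }
  fle <- compute_fle(case$fiducials_V, case$fiducials_C)
  tre <- compute_tre(case$fiducials_P, case$fiducials_C)
  fit <- fit_rigid(case$fiducials_C, case$fiducials_P)
  fre <- compute_fre(case$fiducials_C, case$fiducials_P, fit)
  tibble(case_id = case$case_id %||% NA_character_,
         position = case$position %||% NA_character_,
         n_markers = nrow(case$fiducials_C),
         mean_fle = mean(fle$magnitude), sd_fle = sd(fle$magnitude),
         mean_tre = mean(tre$magnitude), sd_tre = sd(tre$magnitude),
         mean_fre = mean(fre$magnitude), sd_fre = sd(fre$magnitude),
         fn = compute_fn(fit),
         measurement_order = "V_before_P")
}
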