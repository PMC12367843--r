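# Geometric wall-thickness estimation and morphometric indices.
#
# All lengths are in millimetres.  The dome is modelled as a sphere of
# radius R_dome = sqrt(h*w)/2 (geometric-mean diameter over two), the neck
# as an ellipse with perpendicular axes d1 >= d2, and the dome wall material
# as the stretched wall of the parent vessel, whose thickness t_V follows a
# linear thickness-to-diameter-ratio law in the vessel radius.

#' Linear parent-vessel wall model
#'
#' The parent-vessel wall thickness is modelled as
#' `t_V = (slope * r + intercept) * 2r`, i.e. a linear
#' thickness-to-diameter ratio in the vessel radius `r` (mm).  The default
#' coefficients come from a linear fit to intra-operative measurements of
#' cerebral vessel wall thickness against lumen diameter (Nakagawa and
#' colleagues); they can be replaced to admit refitted vessel-wall data.
#'
#' @param slope Change in the thickness-to-diameter ratio per mm of radius
#'   (dimensionless per mm).
#' @param intercept Thickness-to-diameter ratio at zero radius
#'   (dimensionless).
#' @return An object of class `vessel_wall_model`.
#' @examples
#' vessel_wall_model()
#' @export
vessel_wall_model <- function(slope = -0.0297, intercept = 0.1187) {
  stopifnot(is.numeric(slope), length(slope) == 1, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1, is.finite(intercept))
  structure(list(slope = slope, intercept = intercept),
            class = "vessel_wall_model")
}

#' @export
print.vessel_wall_model <- function(x, ...) {
  cat("Linear vessel wall model: t_V = (", format(x$slope), " * r + ",
      format(x$intercept), ") * 2r  [mm]\n", sep = "")
  if (x$slope < 0) {
    cat("valid for r <", format(-x$intercept / x$slope, digits = 4), "mm\n")
  }
  invisible(x)
}

#' Sphericity index of an aneurysm
#'
#' `|h - w| / (h + w)`: zero for a perfect sphere, approaching 1 for
#' extremely elongated shapes.  The inclusion screen for near-spherical,
#' single-lobed aneurysms keeps records with index strictly below 0.2.
#'
#' @param h Aneurysm height (mm), vectorised.
#' @param w Aneurysm width (mm), vectorised.
#' @return Dimensionless index in `[0, 1)`.
#' @examples
#' sphericity_index(10, 7) # 3/17
#' @export
sphericity_index <- function(h, w) {
  check_positive(h = h, w = w)
  abs(h - w) / (h + w)
}

#' Screen a cohort for near-spherical aneurysms
#'
#' Partitions a cohort into records satisfying
#' `sphericity_index(h, w) < threshold` (strict inequality; boundary cases
#' are excluded) and the rest.
#'
#' @param cohort A cohort table with columns `h` and `w` (mm).
#' @param threshold Sphericity threshold, default 0.2.
#' @return A list with elements `kept` and `excluded`, an exhaustive and
#'   disjoint partition of the input rows.
#' @export
screen_spherical <- function(cohort, threshold = 0.2) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) {
    return(list(kept = cohort, excluded = cohort))
  }
  s <- sphericity_index(cohort$h, cohort$w)
  keep <- s < threshold
  list(kept = cohort[keep, , drop = FALSE],
       excluded = cohort[!keep, , drop = FALSE])
}

#' Parent-vessel wall thickness
#'
#' Evaluates the linear wall model `t_V = (slope * r + intercept) * 2r`.
#' The linear thickness-to-diameter ratio crosses zero at
#' `r = -intercept/slope` (about 3.996 mm at the default coefficients);
#' radii at or beyond that point are outside the model's validity and raise
#' an error rather than being clamped, because a clamped thickness of zero
#' would silently zero every downstream index.
#'
#' @param r Parent-vessel radius (mm), vectorised.
#' @param model A [vessel_wall_model()].
#' @return Wall thickness in mm.
#' @examples
#' vessel_wall_thickness(1.5) # 0.22245 mm
#' @export
vessel_wall_thickness <- function(r, model = vessel_wall_model()) {
  check_positive(r = r)
  ratio <- model$slope * r + model$intercept
  if (any(ratio <= 0)) {
    stop("vessel radius outside wall-model validity (predicted ",
         "thickness-to-diameter ratio is not positive)", call. = FALSE)
  }
  ratio * 2 * r
}

#' Aneurysm dome wall thickness
#'
#' Conserves the parent-vessel wall material of the neck disc over the dome
#' sphere: the neck (ellipse, axes `d1`, `d2`) area to dome (sphere of
#' radius `sqrt(h*w)/2`) surface-area ratio times the vessel wall thickness,
#' which simplifies to `d1 * d2 * t_V / (4 * h * w)`.
#'
#' @param h,w Aneurysm height and width (mm).
#' @param d1,d2 Perpendicular neck diameters (mm); the formula is symmetric
#'   in the two.
#' @param t_V Parent-vessel wall thickness (mm), typically from
#'   [vessel_wall_thickness()].
#' @return Dome wall thickness in mm.
#' @export
aneurysm_wall_thickness <- function(h, w, d1, d2, t_V) {
  check_positive(h = h, w = w, d1 = d1, d2 = d2, t_V = t_V)
  d1 * d2 * t_V / (4 * h * w)
}

#' Aneurysm dome radius
#'
#' Half the geometric mean of height and width, `sqrt(h*w)/2`, which
#' approximates the mean dome diameter over two for near-spherical shapes.
#'
#' @param h,w Aneurysm height and width (mm).
#' @return Dome radius in mm.
#' @export
dome_radius <- function(h, w) {
  check_positive(h = h, w = w)
  sqrt(h * w) / 2
}

#' Post-rupture height correction
#'
#' Aneurysm height has been observed to be on average 14.9% greater after
#' rupture than before (width and neck size unchanged), so measured heights
#' of ruptured aneurysms are taken as overestimates and corrected to
#' `h' = h / 1.149`.
#'
#' @param h Measured height (mm), vectorised.
#' @return Corrected height `h'` in mm.
#' @examples
#' apply_height_correction(11.49) # 10
#' @export
apply_height_correction <- function(h) {
  check_positive(h = h)
  h / 1.149
}

#' Compute the morphometric index panel for a set of records
#'
#' Derives, per record: sphericity, parent-vessel wall thickness `t_V`,
#' dome wall thickness `t_A`, dome radius `R_dome`, the
#' wall-thickness-to-radius ratio `WTR = t_A / R_dome`, aspect ratio
#' `AR = h / sqrt(d1*d2)`, bottleneck factor `BF = w / sqrt(d1*d2)` and
#' size ratio `SR = max(h, w) / (2r)`.
#'
#' With `correct_for_rupture = TRUE` the measured heights of ruptured
#' records are replaced by `h' = h / 1.149` (see
#' [apply_height_correction()]) in `t_A`, `R_dome`, `WTR`, `AR` and `SR`,
#' giving the corrected variants usually written WTR', AR' and SR'.  The
#' bottleneck factor does not involve height and is never corrected, and
#' unruptured records are never touched.  SR under correction uses
#' `max(h', w)` (literal substitution).  Sphericity is always reported on
#' the measured, uncorrected dimensions, since the inclusion screen is
#' applied to measurements.
#'
#' @param records A data frame/tibble with columns `h`, `w`, `d1`, `d2`,
#'   `r` (all mm) and, if `correct_for_rupture` is `TRUE`, a logical
#'   `ruptured` column.
#' @param correct_for_rupture Apply the post-rupture height correction to
#'   ruptured records?
#' @param model A [vessel_wall_model()].
#' @return A tibble with columns `t_V`, `t_A`, `R_dome` (mm), `WTR`, `AR`,
#'   `BF`, `SR`, `sphericity` (dimensionless) and the logical flag
#'   `corrected`, one row per input record.
#' @examples
#' rec <- tibble::tibble(h = 10, w = 10, d1 = 4, d2 = 4, r = 1.5)
#' compute_indices(rec)
#' @export
compute_indices <- function(records, correct_for_rupture = FALSE,
                            model = vessel_wall_model()) {
  records <- tibble::as_tibble(records)
  needed <- c("h", "w", "d1", "d2", "r")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop("records lack required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(t_V = double(), t_A = double(), R_dome = double(),
                          WTR = double(), AR = double(), BF = double(),
                          SR = double(), sphericity = double(),
                          corrected = logical()))
  }
  h <- records$h
  if (isTRUE(correct_for_rupture)) {
    if (!"ruptured" %in% names(records)) {
      stop("correct_for_rupture = TRUE requires a logical `ruptured` column",
           call. = FALSE)
    }
    h <- ifelse(records$ruptured, apply_height_correction(records$h),
                records$h)
  }
  w <- records$w
  d1 <- records$d1
  d2 <- records$d2
  r <- records$r
  t_V <- vessel_wall_thickness(r, model)
  t_A <- aneurysm_wall_thickness(h, w, d1, d2, t_V)
  R_dome <- dome_radius(h, w)
  neck <- sqrt(d1 * d2)
  tibble::tibble(
    t_V = t_V,
    t_A = t_A,
    R_dome = R_dome,
    WTR = t_A / R_dome,
    AR = h / neck,
    BF = w / neck,
    SR = pmax(h, w) / (2 * r),
    sphericity = sphericity_index(records$h, w),
    corrected = isTRUE(correct_for_rupture)
  )
}
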