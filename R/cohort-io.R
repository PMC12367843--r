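# Reading, validating and writing per-aneurysm measurement tables.
#
# File schema (CSV, comma-separated, UTF-8, dot decimal, one header row):
#   id, h_mm, w_mm, d1_mm, d2_mm, r_mm, site, ruptured,
#   modality, smoking, hypertension, vessel_choice   (last four optional)
# Internally the same fields live in a tibble without the _mm suffix.

cohort_sites <- c("BT", "Acom", "Pcom")
cohort_modalities <- c("CTA", "MRA", "DSA", "unknown")

required_csv_cols <- c("id", "h_mm", "w_mm", "d1_mm", "d2_mm", "r_mm",
                       "site", "ruptured")

# Internal: lenient logical parser for CSV cells ("1"/"0"/"TRUE"/"false"/...).
parse_flag <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  out
}

new_cohort <- function(df, provenance = NA_character_) {
  df <- tibble::as_tibble(df)
  attr(df, "provenance") <- provenance
  class(df) <- unique(c("aneurysm_cohort", class(df)))
  df
}

#' Coerce and validate a cohort table
#'
#' Checks the record invariants (all dimensions finite and strictly
#' positive, `site` one of BT/Acom/Pcom, unique ids, logical rupture
#' status), canonicalises the neck axes so that `d1 >= d2`, and fills the
#' optional columns (`modality`, `smoking`, `hypertension`,
#' `vessel_choice`) with defaults when absent.
#'
#' @param df A data frame with columns `id`, `h`, `w`, `d1`, `d2`, `r`
#'   (mm), `site`, `ruptured`.
#' @param provenance Free-text source note attached to the table.
#' @return A validated `aneurysm_cohort` tibble.
#' @export
as_cohort <- function(df, provenance = NULL) {
  df <- tibble::as_tibble(df)
  if (is.null(provenance)) {
    provenance <- attr(df, "provenance")
    if (is.null(provenance)) provenance <- NA_character_
  }
  needed <- c("id", "h", "w", "d1", "d2", "r", "site", "ruptured")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("cohort lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("record ids must be unique within a cohort", call. = FALSE)
  }
  if (nrow(df) > 0) {
    check_positive(h = df$h, w = df$w, d1 = df$d1, d2 = df$d2, r = df$r)
    if (!all(df$site %in% cohort_sites)) {
      stop("site must be one of ", paste(cohort_sites, collapse = ", "),
           call. = FALSE)
    }
    if (!is.logical(df$ruptured) || any(is.na(df$ruptured))) {
      stop("ruptured must be TRUE/FALSE with no missing values",
           call. = FALSE)
    }
    # canonical neck axes: d1 is the major axis
    hi <- pmax(df$d1, df$d2)
    lo <- pmin(df$d1, df$d2)
    df$d1 <- hi
    df$d2 <- lo
  }
  if (!"modality" %in% names(df)) df$modality <- "unknown"
  df$modality[is.na(df$modality) | df$modality == ""] <- "unknown"
  if (nrow(df) > 0 && !all(df$modality %in% cohort_modalities)) {
    stop("modality must be one of ", paste(cohort_modalities, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("smoking", "hypertension")) {
    if (!opt %in% names(df)) df[[opt]] <- NA
    df[[opt]] <- as.logical(df[[opt]])
  }
  if (!"vessel_choice" %in% names(df)) df$vessel_choice <- NA_character_
  df$vessel_choice <- as.character(df$vessel_choice)
  new_cohort(df[, c(needed, "modality", "smoking", "hypertension",
                    "vessel_choice")], provenance)
}

#' Read a cohort of aneurysm measurements from CSV
#'
#' Expects the documented schema
#' `id,h_mm,w_mm,d1_mm,d2_mm,r_mm,site,ruptured[,modality,smoking,hypertension,vessel_choice]`.
#' Rows are validated against the record invariants: strictly positive
#' dimensions, a known site, a parseable rupture flag, and unique ids.  The
#' two neck axes are canonicalised so `d1` is the major axis (every
#' downstream formula is symmetric in the pair, so this only stabilises
#' output ordering).
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE` (default) any invariant violation aborts with a
#'   row error naming the offending id; if `FALSE` offending rows are
#'   dropped, a message summarises the reasons, and the dropped rows are
#'   recorded in the `"dropped"` attribute of the result.
#' @return An `aneurysm_cohort` tibble (columns `id`, `h`, `w`, `d1`,
#'   `d2`, `r` in mm, `site`, `ruptured`, `modality`, `smoking`,
#'   `hypertension`, `vessel_choice`).
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  miss <- setdiff(required_csv_cols, names(raw))
  if (length(miss)) {
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  reasons <- rep(NA_character_, n)
  flag <- function(bad, why) {
    fresh <- bad & is.na(reasons)
    reasons[fresh] <<- why
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  h <- num("h_mm"); w <- num("w_mm")
  d1 <- num("d1_mm"); d2 <- num("d2_mm"); r <- num("r_mm")
  for (v in list(c("h_mm", "h"), c("w_mm", "w"), c("d1_mm", "d1"),
                 c("d2_mm", "d2"), c("r_mm", "r"))) {
    x <- get(v[2])
    flag(!is.finite(x) | x <= 0,
         paste0("non-numeric or non-positive ", v[1]))
  }
  flag(!(raw$site %in% cohort_sites), "unknown site")
  ruptured <- parse_flag(raw$ruptured)
  flag(is.na(ruptured), "unparseable ruptured flag")
  if ("modality" %in% names(raw)) {
    modality <- trimws(raw$modality)
    modality[modality == ""] <- "unknown"
    flag(!(modality %in% cohort_modalities), "unknown modality")
  } else {
    modality <- rep("unknown", n)
  }
  flag(duplicated(raw$id), "duplicate id")

  bad <- !is.na(reasons)
  if (any(bad)) {
    labels <- paste0("row ", which(bad), " (id '", raw$id[bad], "'): ",
                     reasons[bad])
    if (strict) {
      stop("row error(s) in ", path, ":\n  ",
           paste(labels, collapse = "\n  "), call. = FALSE)
    }
    message("read_cohort: dropped ", sum(bad), " row(s):\n  ",
            paste(labels, collapse = "\n  "))
  }
  keep <- !bad
  df <- tibble::tibble(
    id = raw$id[keep],
    h = h[keep], w = w[keep], d1 = d1[keep], d2 = d2[keep], r = r[keep],
    site = raw$site[keep], ruptured = as.logical(ruptured[keep]),
    modality = modality[keep],
    smoking = if ("smoking" %in% names(raw)) parse_flag(raw$smoking)[keep] else NA,
    hypertension = if ("hypertension" %in% names(raw)) {
      parse_flag(raw$hypertension)[keep]
    } else NA,
    vessel_choice = if ("vessel_choice" %in% names(raw)) {
      ifelse(raw$vessel_choice[keep] == "", NA_character_,
             raw$vessel_choice[keep])
    } else NA_character_
  )
  out <- as_cohort(df, provenance = path)
  if (any(bad)) {
    attr(out, "dropped") <- tibble::tibble(row = which(bad),
                                           id = raw$id[bad],
                                           reason = reasons[bad])
  }
  out
}

#' Write a cohort back to the CSV schema
#'
#' Inverse of [read_cohort()]; numeric fields are written at full double
#' precision so a write/read round trip is lossless to at least 12
#' significant digits.
#'
#' @param cohort An `aneurysm_cohort` tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  out <- data.frame(
    id = cohort$id,
    h_mm = as.character(cohort$h), w_mm = as.character(cohort$w),
    d1_mm = as.character(cohort$d1), d2_mm = as.character(cohort$d2),
    r_mm = as.character(cohort$r),
    site = cohort$site,
    ruptured = as.integer(cohort$ruptured),
    modality = cohort$modality,
    smoking = ifelse(is.na(cohort$smoking), "", as.integer(cohort$smoking)),
    hypertension = ifelse(is.na(cohort$hypertension), "",
                          as.integer(cohort$hypertension)),
    vessel_choice = ifelse(is.na(cohort$vessel_choice), "",
                           cohort$vessel_choice),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve the parent-vessel radius from candidate vessels
#'
#' When an aneurysm sits at a bifurcation it may abut two candidate parent
#' vessels.  The model assumes the dome wall is stretched parent-vessel
#' wall, so the thinner-walled (smaller) vessel dominates rupture
#' predisposition: if the aneurysm arises at least partially from the
#' branch vessel, the smaller of the two radii is taken.  If it arises
#' entirely from the trunk, the trunk (first-listed by convention) is
#' taken.  Ties between equal radii go to the first-listed vessel (a reader
#' convention, documented rather than inferred).
#'
#' @param candidates Named numeric vector of 1-2 candidate radii (mm), the
#'   names being vessel labels; the trunk vessel listed first.
#' @param arises_from_branch Does the aneurysm arise at least partially
#'   from the branch vessel?
#' @return A list with `radius` (mm) and `vessel` (label).
#' @examples
#' resolve_parent_radius(c(basilar = 2.0, P1 = 1.1), arises_from_branch = TRUE)
#' @export
resolve_parent_radius <- function(candidates, arises_from_branch) {
  if (length(candidates) == 0) {
    stop("no candidate parent vessels supplied", call. = FALSE)
  }
  if (length(candidates) > 2) {
    stop("at most two candidate parent vessels are supported", call. = FALSE)
  }
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    stop("candidates must be a named numeric vector of radii", call. = FALSE)
  }
  check_positive(candidates = as.numeric(candidates))
  pick <- if (length(candidates) == 1 || !isTRUE(arises_from_branch)) {
    1L
  } else {
    which.min(candidates) # ties: first-listed
  }
  list(radius = unname(candidates[pick]), vessel = names(candidates)[pick])
}
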