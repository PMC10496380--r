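#' Build a compound library with theoretical masses
#'
#' Takes a table of compounds with molecular formulas and derives the neutral
#' monoisotopic mass and the theoretical \eqn{[M+H]^+} m/z for each row.
#'
#' @param library data frame with at least columns `name` and `formula`;
#'   `category` and `cas` are carried through when present.
#' @param elements element mass table, see [isotope_masses()].
#' @return the input data frame with columns `monoisotopic_mass` and
#'   `mh_mz` appended.
#' @export
#' @examples
#' compound_library(data.frame(name = "quercetin", formula = "C15H10O7"))
compound_library <- function(library, elements = isotope_masses()) {
  stopifnot(is.data.frame(library))
  required <- c("name", "formula")
  missing_cols <- setdiff(required, names(library))
  if (length(missing_cols)) {
    stop("library table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(library$name)) {
    stop("compound names must be unique", call. = FALSE)
  }
  library$monoisotopic_mass <- vapply(
    library$formula,
    function(f) monoisotopic_mass(parse_formula(f, elements), elements),
    numeric(1L), USE.NAMES = FALSE
  )
  library$mh_mz <- protonated_mz(library$monoisotopic_mass)
  library
}

.empty_hits <- function() {
  data.frame(
    feature_id = character(), compound_name = character(),
    measured_mz = numeric(), theoretical_mz = numeric(),
    ppm_error = numeric(),
    area_sample = numeric(), area_control = numeric(),
    enrichment_ratio = numeric(), ambiguous = logical(),
    stringsAsFactors = FALSE
  )
}

#' Annotate LC-MS peaks against a compound library
#'
#' Matches every measured \eqn{[M+H]^+} m/z against the theoretical m/z of
#' every library compound and keeps the pairs within the ppm tolerance
#' (default 5 ppm, the usual accurate-mass window of Q/TOF annotation).
#' A peak matching several compounds yields one hit per compound, each
#' flagged `ambiguous = TRUE`; resolving such ties (by MS/MS fragmentation
#' or retention time) is outside the scope of this package.
#'
#' @param peaks data frame of LC-MS features with columns `feature_id`,
#'   `mz`, and optionally `rt_min`, `area_sample`, `area_control`.
#' @param library compound table as returned by [compound_library()]
#'   (`mh_mz` is computed on the fly if absent).
#' @param tol_ppm positive mass tolerance in ppm.
#' @return data frame of hits: `feature_id`, `compound_name`, `measured_mz`,
#'   `theoretical_mz`, `ppm_error`, `area_sample`, `area_control`,
#'   `enrichment_ratio` (sample/control area; `Inf` when the control area is
#'   zero and the sample area positive), `ambiguous`.
#' @export
annotate_peaks <- function(peaks, library, tol_ppm = 5) {
  stopifnot(is.data.frame(peaks))
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1L || tol_ppm <= 0) {
    stop("'tol_ppm' must be a single positive number", call. = FALSE)
  }
  if (nrow(peaks) == 0L || nrow(library) == 0L) {
    return(.empty_hits())
  }
  if (!all(c("feature_id", "mz") %in% names(peaks))) {
    stop("peak table needs columns 'feature_id' and 'mz'", call. = FALSE)
  }
  if (!"mh_mz" %in% names(library)) {
    library <- compound_library(library)
  }
  if (!"area_sample" %in% names(peaks)) peaks$area_sample <- NA_real_
  if (!"area_control" %in% names(peaks)) peaks$area_control <- NA_real_

  hits <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(p) {
    err <- ppm_error(peaks$mz[p], library$mh_mz)
    sel <- which(abs(err) <= tol_ppm)
    if (!length(sel)) return(NULL)
    data.frame(
      feature_id = peaks$feature_id[p],
      compound_name = library$name[sel],
      measured_mz = peaks$mz[p],
      theoretical_mz = library$mh_mz[sel],
      ppm_error = err[sel],
      area_sample = peaks$area_sample[p],
      area_control = peaks$area_control[p],
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(hits)) {
    return(.empty_hits())
  }
  hits$enrichment_ratio <- ifelse(
    hits$area_control > 0,
    hits$area_sample / hits$area_control,
    ifelse(hits$area_sample > 0, Inf, NA_real_)
  )
  multi <- table(hits$feature_id)
  hits$ambiguous <- as.vector(multi[hits$feature_id] > 1L)
  rownames(hits) <- NULL
  hits
}

#' Retain annotation hits enriched in the sample versus the control
#'
#' The affinity-ultrafiltration screen: a compound bound by the target
#' protein survives the wash and shows a larger released peak area in the
#' protein-containing sample than in the protein-free control. The rule is a
#' strict ratio test, `area_sample > ratio_threshold * area_control`; a hit
#' with zero control area and positive sample area counts as enriched.
#'
#' @param hits data frame from [annotate_peaks()] carrying `area_sample`
#'   and `area_control`.
#' @param ratio_threshold non-negative ratio cut-off; the default 1 keeps
#'   compounds whose sample area strictly exceeds the control area.
#' @return the subset of `hits` passing the test.
#' @export
screen_enriched <- function(hits, ratio_threshold = 1.0) {
  stopifnot(is.data.frame(hits))
  if (!is.numeric(ratio_threshold) || length(ratio_threshold) != 1L ||
      ratio_threshold < 0) {
    stop("'ratio_threshold' must be a single non-negative number", call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    return(hits)
  }
  if (!all(c("area_sample", "area_control") %in% names(hits))) {
    stop("hits need 'area_sample' and 'area_control' columns", call. = FALSE)
  }
  if (any(hits$area_control < 0, na.rm = TRUE) ||
      any(hits$area_sample < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  keep <- !is.na(hits$area_sample) & !is.na(hits$area_control) &
    hits$area_sample > ratio_threshold * hits$area_control
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write annotation hits to CSV
#'
#' Rounds `ppm_error` to 1 decimal and `enrichment_ratio` to 2, the usual
#' reporting precision of annotation tables.
#'
#' @param hits data frame from [annotate_peaks()] or [screen_enriched()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- hits
  if ("ppm_error" %in% names(out)) out$ppm_error <- round(out$ppm_error, 1)
  if ("enrichment_ratio" %in% names(out)) {
    out$enrichment_ratio <- round(out$enrichment_ratio, 2)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
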