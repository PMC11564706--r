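#' Run the full surgical-planning pipeline on one case
#'
#' Executes, per requested side: laterality restriction, nipple
#' localization, breast-box construction, tumor metrics, quadrant
#' localization, and margin hulls for each requested margin. Partial
#' failures that leave downstream stages meaningful are recorded as
#' warnings in the report; a missing tumor marks the side's metric sections
#' absent and sets the case status to `"no-tumor"`. Identical inputs give
#' identical reports (the analysis path is seed-free).
#'
#' @param map a [LabelMap-class].
#' @param sides character: `"left"`, `"right"` or both.
#' @param marginsMM numeric vector of hull margins in mm (each in [0, 20]).
#' @param hullMode `"multicentric"`, `"unicentric"` or `"both"`.
#' @param connectivity component connectivity for dominant mass and
#'   multicentric hulls.
#' @param params nipple parameters, see [nippleParams()].
#' @param midline optional 0-based laterality midline.
#' @return a `CaseReport`: named list with `version`, `config`, `sides`
#'   (per-side results), `warnings` and `status` (`"success"`, `"no-tumor"`
#'   or `"landmark-failure"`).
#' @export
runCase <- function(map, sides = c("left", "right"),
                    marginsMM = c(0, 5, 10, 20),
                    hullMode = c("multicentric", "unicentric", "both"),
                    connectivity = c("face", "edge", "corner"),
                    params = nippleParams(), midline = NULL) {
  hullMode <- match.arg(hullMode)
  connectivity <- match.arg(connectivity)
  sides <- match.arg(sides, several.ok = TRUE)
  warnings <- character(0)
  status <- "success"
  note <- function(msg) warnings <<- c(warnings, msg)

  sideReports <- list()
  for (side in sides) {
    sr <- list(side = side)
    if (!length(sideIndices(map, side, midline))) {
      note(sprintf("side %s: empty subvolume", side))
      next
    }
    nip <- tryCatch(locateNipple(map, side, params, midline),
                    error = function(e) e)
    if (inherits(nip, "error")) {
      note(sprintf("side %s: %s", side, conditionMessage(nip)))
      status <- "landmark-failure"
      sideReports[[side]] <- sr
      next
    }
    sr$nippleMM <- unname(nip[1:3])
    box <- tryCatch(buildBreastBox(map, side, midline),
                    error = function(e) e)
    if (inherits(box, "error")) {
      note(sprintf("side %s: %s", side, conditionMessage(box)))
      status <- "landmark-failure"
      sideReports[[side]] <- sr
      next
    }
    sr$breastBox <- list(boundsVoxels = box@bounds,
                         boundsMM = box@boundsMM,
                         corrected = box@corrected,
                         fallback = box@fallback)

    tumor <- maskOnSide(tissueMask(map, "tumor"), map, side, midline)
    if (!any(tumor)) {
      note(sprintf("side %s: no tumor voxels; metrics skipped", side))
      if (status == "success") status <- "no-tumor"
      sideReports[[side]] <- sr
      next
    }
    sr$metrics <- tumorMetricsReport(map, side, nip, box, midline,
                                     connectivity)
    pl <- balancePlane(map, side, nip, box)
    if (!pl$converged) note(sprintf("side %s: balance plane not converged",
                                    side))
    sr$quadrants <- assignQuadrants(map, side, nip, pl, tumor)

    hullSummary <- function(hs) list(
      nHulls = length(hs),
      volumesMM3 = vapply(hs, function(h) h@volume, numeric(1)),
      components = lapply(hs, function(h) h@components),
      merged = any(vapply(hs, function(h) length(h@components) > 1L,
                          logical(1))))
    sr$hulls <- lapply(marginsMM, function(m) {
      out <- list(marginMM = m)
      if (hullMode %in% c("multicentric", "both"))
        out$multicentric <- hullSummary(
          multicentricHulls(tumor, map@spacing, m, connectivity))
      if (hullMode %in% c("unicentric", "both"))
        out$unicentric <- hullSummary(list(
          unicentricHull(tumor, map@spacing, m, connectivity)))
      out
    })
    sideReports[[side]] <- sr
  }

  list(version = as.character(utils::packageVersion("mammoplan")),
       config = list(sides = sides, marginsMM = marginsMM,
                     hullMode = hullMode, connectivity = connectivity,
                     nippleParams = params,
                     midline = if (is.null(midline)) NA_integer_
                               else as.integer(midline),
                     units = list(distance = "mm", volume = "mm^3",
                                  angle = "deg")),
       sides = sideReports,
       warnings = warnings,
       status = status)
}

#' Write a case report as JSON
#'
#' @param report result of [runCase()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCaseReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
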