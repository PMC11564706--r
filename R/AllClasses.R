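#' Tissue label schema
#'
#' Maps the seven semantic tissue classes (air, skin, adipose,
#' fibroglandular, vessel, chest, tumor) to the integer labels used in a
#' label map. All seven classes must be present and labels pairwise
#' distinct; by convention air is 0 but any distinct integer is accepted.
#'
#' @slot labels named integer vector with one entry per semantic class.
#' @export
setClass("TissueSchema", representation(labels = "integer"))

setValidity("TissueSchema", function(object) {
  lab <- object@labels
  if (!setequal(names(lab), TISSUE_CLASSES))
    return(sprintf("schema must name exactly the classes: %s",
                   paste(TISSUE_CLASSES, collapse = ", ")))
  if (anyNA(lab)) return("labels must not be NA")
  if (anyDuplicated(lab)) return("labels must be pairwise distinct")
  if (any(lab < 0)) return("labels must be non-negative")
  TRUE
})

#' Construct a TissueSchema
#'
#' @param ... named integer labels, one per semantic class, or a single
#'   named vector/list covering all seven classes.
#' @return A [TissueSchema-class] object.
#' @examples
#' defaultSchema()
#' TissueSchema(air = 0, skin = 1, adipose = 2, fibroglandular = 3,
#'              vessel = 4, chest = 5, tumor = 6)
#' @export
TissueSchema <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.list(args[[1L]]) || length(args[[1L]]) > 1L))
    args <- as.list(args[[1L]])
  lab <- unlist(args)
  storage.mode(lab) <- "integer"
  new("TissueSchema", labels = lab[TISSUE_CLASSES])
}

#' @rdname TissueSchema
#' @export
defaultSchema <- function() {
  TissueSchema(air = 0L, skin = 1L, adipose = 2L, fibroglandular = 3L,
               vessel = 4L, chest = 5L, tumor = 6L)
}

#' @describeIn TissueSchema integer label of a semantic class.
#' @param schema a `TissueSchema`.
#' @param tissue character, one of the seven semantic class names.
#' @export
labelOf <- function(schema, tissue) {
  tissue <- match.arg(tissue, TISSUE_CLASSES, several.ok = TRUE)
  unname(schema@labels[tissue])
}

setMethod("show", "TissueSchema", function(object) {
  cat("TissueSchema:",
      paste(sprintf("%s=%d", names(object@labels), object@labels),
            collapse = " "), "\n")
})

#' Multi-tissue 3D label map
#'
#' A 3D integer voxel grid in the canonical LPS-like anatomical frame with
#' physical voxel spacing (mm) and a tissue schema. Every voxel value must be
#' one of the schema's labels.
#'
#' @slot voxels 3D integer array indexed (i, j, k).
#' @slot spacing numeric(3), voxel spacing in mm, all positive.
#' @slot schema a [TissueSchema-class].
#' @export
setClass("LabelMap", representation(voxels = "array", spacing = "numeric",
                                    schema = "TissueSchema"))

setValidity("LabelMap", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three positive finite numbers (mm)")
  bad <- setdiff(unique(as.vector(object@voxels)), object@schema@labels)
  if (length(bad))
    return(sprintf("voxel value(s) not in schema: %s",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' Construct a LabelMap
#'
#' @param voxels 3D integer array of labels.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param schema a [TissueSchema-class]; defaults to [defaultSchema()].
#' @return A [LabelMap-class].
#' @export
LabelMap <- function(voxels, spacing = c(1, 1, 1), schema = defaultSchema()) {
  storage.mode(voxels) <- "integer"
  new("LabelMap", voxels = voxels, spacing = as.numeric(spacing),
      schema = schema)
}

#' @describeIn LabelMap the voxel array.
#' @param map a `LabelMap`.
#' @export
voxels <- function(map) map@voxels

#' @describeIn LabelMap voxel spacing in mm.
#' @export
spacing <- function(map) map@spacing

#' @describeIn LabelMap the tissue schema.
#' @export
schema <- function(map) map@schema

setMethod("dim", "LabelMap", function(x) dim(x@voxels))

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabelMap %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  cnt <- tabulate(match(as.vector(object@voxels), object@schema@labels),
                  nbins = length(TISSUE_CLASSES))
  names(cnt) <- names(object@schema@labels)
  cat("  voxel counts:",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "), "\n")
})

#' Triangulated tissue surface mesh
#'
#' Watertight triangulated surface extracted from a binary mask: vertices in
#' mm, 1-based triangular faces with outward winding, and outward unit
#' vertex normals.
#'
#' @slot vertices numeric matrix (n x 3), mm.
#' @slot faces integer matrix (m x 3), 1-based vertex indices.
#' @slot normals numeric matrix (n x 3), outward unit vertex normals.
#' @export
setClass("SurfaceMesh", representation(vertices = "matrix", faces = "matrix",
                                       normals = "matrix"))

setValidity("SurfaceMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@faces) != 3L) return("faces must be m x 3")
  if (!all(object@faces >= 1 & object@faces <= nrow(object@vertices)))
    return("face indices out of range")
  if (!identical(dim(object@normals), dim(object@vertices)))
    return("normals must match vertices")
  nl <- sqrt(rowSums(object@normals^2))
  if (any(abs(nl - 1) > 1e-6)) return("normals must be unit length")
  TRUE
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces, volume %.2f mm^3\n",
              nrow(object@vertices), nrow(object@faces),
              meshVolume(object)))
})

#' Convex margin hull
#'
#' Convex polytope (vertices and triangular facets, mm) representing a
#' tumor-plus-margin excision volume, tagged with the ids of the tumor
#' components it encloses.
#'
#' @slot marginMM surgical margin in mm, in [0, 20].
#' @slot vertices hull vertex coordinates (v x 3, mm).
#' @slot faces triangular facets (f x 3), 1-based indices into `vertices`.
#' @slot facetNormals outward unit facet normals (f x 3).
#' @slot facetOffsets plane offsets: interior points satisfy
#'   `x . n <= offset` for every facet.
#' @slot components integer ids of member tumor components.
#' @slot volume enclosed volume, mm^3.
#' @export
setClass("MarginHull", representation(marginMM = "numeric",
                                      vertices = "matrix",
                                      faces = "matrix",
                                      facetNormals = "matrix",
                                      facetOffsets = "numeric",
                                      components = "integer",
                                      volume = "numeric"))

setValidity("MarginHull", function(object) {
  if (length(object@marginMM) != 1L || object@marginMM < 0 ||
      object@marginMM > 20)
    return("marginMM must be a single value in [0, 20]")
  if (ncol(object@vertices) != 3L) return("vertices must be v x 3")
  if (object@volume <= 0) return("hull volume must be positive")
  TRUE
})

setMethod("show", "MarginHull", function(object) {
  cat(sprintf(
    "MarginHull: margin %.1f mm, %d vertices, %d facets, volume %.1f mm^3, components {%s}\n",
    object@marginMM, nrow(object@vertices), nrow(object@faces),
    object@volume, paste(object@components, collapse = ",")))
})

#' Breast bounding box
#'
#' Axis-aligned box enclosing all breast tissue of one side, built from five
#' skin-anchored key points with a corrective pass. Index bounds are 1-based
#' and inclusive; mm bounds are outer voxel edges.
#'
#' @slot side "left" or "right".
#' @slot bounds integer matrix 2 x 3 (rows lo/hi; columns i, j, k).
#' @slot boundsMM numeric matrix 2 x 3, outer-edge physical bounds in mm.
#' @slot keyPoints named list of the defining points (mm) and construction
#'   intermediates.
#' @slot corrected logical(6): whether each face (i-lo, i-hi, j-lo, j-hi,
#'   k-lo, k-hi) was moved by the corrective pass.
#' @slot fallback TRUE when the construction fell back to the tight
#'   bounding box of breast tissue.
#' @export
setClass("BreastBox", representation(side = "character", bounds = "matrix",
                                     boundsMM = "matrix", keyPoints = "list",
                                     corrected = "logical",
                                     fallback = "logical"))

setValidity("BreastBox", function(object) {
  if (!object@side %in% c("left", "right")) return("side must be left/right")
  if (any(object@bounds[1, ] > object@bounds[2, ]))
    return("box bounds must satisfy lo <= hi on every axis")
  TRUE
})

setMethod("show", "BreastBox", function(object) {
  b <- object@bounds
  cat(sprintf("BreastBox (%s): i %d..%d, j %d..%d, k %d..%d%s\n",
              object@side, b[1, 1], b[2, 1], b[1, 2], b[2, 2],
              b[1, 3], b[2, 3],
              if (object@fallback) " [fallback: tight bounds]" else ""))
})

#' Two-rater agreement table
#'
#' 2x2 cross-classification of two raters' accept/reject calls:
#' `a` both approve, `b` rater 1 approves / rater 2 rejects, `c` the
#' converse, `d` both reject.
#'
#' @slot a,b,c,d non-negative counts.
#' @export
setClass("AgreementTable", representation(a = "numeric", b = "numeric",
                                          c = "numeric", d = "numeric"))

setValidity("AgreementTable", function(object) {
  cnt <- c(object@a, object@b, object@c, object@d)
  if (length(cnt) != 4L || anyNA(cnt) || any(cnt < 0) ||
      any(cnt != round(cnt)))
    return("a, b, c, d must be single non-negative integer counts")
  if (sum(cnt) <= 0) return("total count must be positive")
  TRUE
})

#' Construct an AgreementTable
#'
#' @param a,b,c,d counts: both approve; rater1 approve/rater2 reject; rater1
#'   reject/rater2 approve; both reject.
#' @return An [AgreementTable-class].
#' @examples
#' AgreementTable(a = 64, b = 10, c = 9, d = 7)
#' @export
AgreementTable <- function(a, b, c, d) {
  new("AgreementTable", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), d = as.numeric(d))
}

setMethod("show", "AgreementTable", function(object) {
  n <- object@a + object@b + object@c + object@d
  cat(sprintf(
    "AgreementTable: a=%g b=%g c=%g d=%g (n=%g), concordance %.1f%%, AC1 %.3f\n",
    object@a, object@b, object@c, object@d, n,
    concordance(object), gwetAC1(object)))
})
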