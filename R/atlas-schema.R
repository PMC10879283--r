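#' Atlas schema for the 735-feature morphometry layout
#'
#' An `atlas_schema` fixes the ordered label registry the whole package is
#' keyed to: 360 cortical patches (a 360-region multimodal surface
#' parcellation, 180 per hemisphere) and 15 subcortical gray-matter
#' structures (7 bilateral pairs plus brainstem). Feature tables carry one
#' thickness and one volume column per cortical patch and one volume column
#' per subcortical structure, 735 columns in all, in schema order.
#'
#' @param cortical_labels Character vector of exactly 360 unique,
#'   hemisphere-prefixed patch labels (left-hemisphere block first).
#' @param subcortical_labels Character vector of exactly 15 unique structure
#'   names.
#' @return An object of class `atlas_schema`.
#' @seealso [default_atlas_schema()]
#' @export
atlas_schema <- function(cortical_labels, subcortical_labels) {
  cortical_labels <- as.character(cortical_labels)
  subcortical_labels <- as.character(subcortical_labels)
  if (length(cortical_labels) != 360L) {
    stop("`cortical_labels` must contain exactly 360 labels, got ",
         length(cortical_labels), call. = FALSE)
  }
  if (length(subcortical_labels) != 15L) {
    stop("`subcortical_labels` must contain exactly 15 labels, got ",
         length(subcortical_labels), call. = FALSE)
  }
  all_labels <- c(cortical_labels, subcortical_labels)
  if (anyDuplicated(all_labels)) {
    stop("atlas labels must be unique; duplicated: ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(cortical_labels = cortical_labels,
         subcortical_labels = subcortical_labels),
    class = "atlas_schema"
  )
}

#' Default atlas schema with systematic placeholder labels
#'
#' The true 360-patch label strings are tied to the surface atlas
#' distribution, so the default registry uses systematic placeholders
#' (`L_ROI_001` ... `L_ROI_180`, then `R_ROI_001` ... `R_ROI_180`); a real
#' label list can be supplied to [atlas_schema()] instead. Subcortical
#' structures use the conventional segmentation names in a fixed, documented
#' order: left then right of thalamus, caudate, putamen, pallidum,
#' hippocampus, amygdala, accumbens, then brainstem.
#'
#' @return An `atlas_schema` with 360 cortical and 15 subcortical labels.
#' @examples
#' sc <- default_atlas_schema()
#' length(sc$cortical_labels)    # 360
#' length(sc$subcortical_labels) # 15
#' @export
default_atlas_schema <- function() {
  cort <- c(sprintf("L_ROI_%03d", 1:180), sprintf("R_ROI_%03d", 1:180))
  pairs <- c("Thalamus", "Caudate", "Putamen", "Pallidum",
             "Hippocampus", "Amygdala", "Accumbens")
  subc <- c(as.vector(rbind(paste0("Left.", pairs), paste0("Right.", pairs))),
            "Brainstem")
  atlas_schema(cort, subc)
}

#' Ordered feature-column names for a schema
#'
#' Column order is the package-wide contract: 360 thickness columns
#' (`thk_<label>`), then 360 cortical-volume columns (`cvol_<label>`), then
#' 15 subcortical-volume columns (`svol_<label>`).
#'
#' @param schema An `atlas_schema`.
#' @return Character vector of length 735.
#' @export
feature_names <- function(schema) {
  stopifnot(inherits(schema, "atlas_schema"))
  c(paste0("thk_", schema$cortical_labels),
    paste0("cvol_", schema$cortical_labels),
    paste0("svol_", schema$subcortical_labels))
}

#' Feature block index helper
#'
#' @param schema An `atlas_schema`.
#' @return Named list of integer index vectors into the 735-feature order:
#'   `thickness` (1-360), `cortical_volume` (361-720),
#'   `subcortical_volume` (721-735), and `volume` (their union, the
#'   375-feature volume arm).
#' @export
feature_blocks <- function(schema) {
  stopifnot(inherits(schema, "atlas_schema"))
  list(thickness = 1:360,
       cortical_volume = 361:720,
       subcortical_volume = 721:735,
       volume = 361:735)
}

#' @export
print.atlas_schema <- function(x, ...) {
  cat("<atlas_schema>\n")
  cat("  cortical patches:      ", length(x$cortical_labels),
      " (", x$cortical_labels[1], " ... ", x$cortical_labels[360], ")\n",
      sep = "")
  cat("  subcortical structures:", length(x$subcortical_labels), "\n")
  cat("  feature columns:       ", length(feature_names(x)), "\n", sep = "")
  invisible(x)
}

#' Write / read an atlas schema as JSON
#'
#' @param schema An `atlas_schema`.
#' @param path File path for the JSON document.
#' @return `write_schema_json()` returns `path` invisibly;
#'   `read_schema_json()` returns an `atlas_schema`.
#' @export
write_schema_json <- function(schema, path) {
  stopifnot(inherits(schema, "atlas_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_schema_json
#' @export
read_schema_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  atlas_schema(x$cortical_labels, x$subcortical_labels)
}
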