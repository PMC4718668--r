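#' Region registries
#'
#' A region registry is the canonical catalogue of brain regions a network is
#' built over: one row per region with its abbreviation, full anatomical name,
#' anatomical area group, and a fixed 2-D layout coordinate used for
#' pseudoanatomical network rendering (cortical areas on top, striatum in the
#' centre, hippocampus/septum on the left, amygdala/hypothalamus along the
#' bottom). The packaged default covers the 27 forebrain regions of interest
#' commonly quantified in regional immediate-early-gene mapping studies.
#'
#' Layout coordinates are unitless plane positions chosen for legible,
#' anatomically suggestive figures; they are an arbitrary packaged constant
#' and carry no quantitative meaning.
#'
#' @name region_registry
NULL

AREA_GROUPS <- c(
  "prefrontal cortex", "sensorimotor cortex", "striatum",
  "hippocampus/septum", "amygdala/hypothalamus"
)

#' Default 27-region registry
#'
#' Returns the packaged registry of 27 forebrain regions: 4 prefrontal
#' cortical, 6 sensorimotor cortical, 6 striatal, 6 hippocampal/septal and 5
#' amygdalar/hypothalamic regions, each with a fixed pseudoanatomical layout
#' coordinate.
#'
#' @return A `region_registry` data frame with columns `region_id`,
#'   `full_name`, `area_group`, `x`, `y`.
#' @export
#' @examples
#' reg <- default_region_registry()
#' nrow(reg)          # 27
#' table(reg$area_group)
default_region_registry <- function() {
  path <- system.file("extdata", "region_registry.tsv", package = "cgenet",
                      mustWork = TRUE)
  load_region_registry(path)
}

#' Read a region registry from a TSV file
#'
#' @param path TSV file with header `region_id, full_name, area_group, x, y`.
#' @return A validated `region_registry` data frame.
#' @export
load_region_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "numeric", "numeric"))
  required <- c("region_id", "full_name", "area_group", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("MissingColumn: registry file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_registry(df[required])
}

validate_registry <- function(df) {
  df$region_id <- trimws(df$region_id)
  if (any(!nzchar(df$region_id))) {
    stop("region ids must be non-empty", call. = FALSE)
  }
  dup <- duplicated(toupper(df$region_id))
  if (any(dup)) {
    stop("duplicate region id(s): ",
         paste(unique(df$region_id[dup]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop("MissingLayout: every region needs finite layout coordinates",
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("region_registry", "data.frame")
  df
}

#' @export
print.region_registry <- function(x, ...) {
  cat(sprintf("<region_registry> %d regions, %d area groups\n",
              nrow(x), length(unique(x$area_group))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Resolve region ids against a registry
#'
#' Region ids are matched case-insensitively and canonicalized to the
#' registry spelling.
#'
#' @param ids character vector of region ids.
#' @param registry a `region_registry`.
#' @return character vector of canonical ids.
#' @keywords internal
canonical_region_id <- function(ids, registry) {
  idx <- match(toupper(trimws(ids)), toupper(registry$region_id))
  if (anyNA(idx)) {
    bad <- unique(ids[is.na(idx)])
    stop("UnknownRegion: region id(s) not in registry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  registry$region_id[idx]
}
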