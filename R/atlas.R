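#' Built-in table of network regions of interest
#'
#' Returns the 42 spherical seed regions used to delineate seven intrinsic
#' connectivity networks: default mode (DMN), salience (SN), dorsal attention
#' (DAN), fronto-parietal control (FPCN), auditory (AN), visual (VN) and motor
#' (MN). Coordinates are MNI millimetres; each region is a 6 mm radius sphere
#' centred on a published focus. Abbreviations may repeat across networks
#' (e.g. RACC appears in both SN and AN); nodes are always keyed by
#' (network, name).
#'
#' @return A tibble with columns `name`, `network`, `x`, `y`, `z`,
#'   `radius_mm`, one row per node, in canonical node order.
#' @export
default_roi_table <- function() {
  path <- system.file("extdata", "network_rois.tsv", package = "connlife",
                      mustWork = TRUE)
  read_roi_table(path)
}

# canonical network -> class map for the seven standard networks
.network_class_map <- c(
  DMN = "cognitive", SN = "cognitive", DAN = "cognitive", FPCN = "cognitive",
  AN = "sensorimotor", VN = "sensorimotor", MN = "sensorimotor"
)

#' Build an ROI atlas from a region table
#'
#' Validates a table of named spherical regions and fixes the canonical node
#' order used by every downstream stage (time-series extraction, connectivity
#' matrices, group statistics). Row order of `roi_table` is preserved as node
#' order; nodes are keyed by the (network, name) pair so the same abbreviation
#' may appear in two networks.
#'
#' @param roi_table Data frame with columns `name`, `network`, numeric `x`,
#'   `y`, `z` (MNI mm) and optionally `radius_mm` (defaults to 6 mm).
#' @param network_classes Named character vector mapping network label to
#'   class tag (`"cognitive"` or `"sensorimotor"`). Defaults cover the seven
#'   standard networks; unlisted networks are tagged `"other"`.
#'
#' @return A tibble of class `roi_atlas` with columns `node_id`, `name`,
#'   `network`, `x`, `y`, `z`, `radius_mm`, plus a `networks` attribute
#'   (tibble of `network`, `class` in first-appearance order).
#' @export
#' @examples
#' atlas <- build_roi_atlas(default_roi_table())
#' count_node_pairs(atlas)
build_roi_atlas <- function(roi_table, network_classes = .network_class_map) {
  stopifnot(is.data.frame(roi_table))
  required <- c("name", "network", "x", "y", "z")
  missing_cols <- setdiff(required, names(roi_table))
  if (length(missing_cols) > 0L) {
    stop("roi_table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab <- tibble::as_tibble(roi_table)
  if (!"radius_mm" %in% names(tab)) tab$radius_mm <- 6
  tab$radius_mm[is.na(tab$radius_mm)] <- 6

  for (col in c("x", "y", "z", "radius_mm")) {
    v <- tab[[col]]
    if (is.character(v) || is.factor(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop("non-numeric coordinate in column '", col, "' at row ", bad[1L],
             " (", tab$network[bad[1L]], ":", tab$name[bad[1L]], ")")
      }
      tab[[col]] <- vn
    }
    if (anyNA(tab[[col]]) || !is.numeric(tab[[col]])) {
      stop("non-numeric or missing coordinate in column '", col, "'")
    }
  }
  if (any(tab$radius_mm <= 0)) stop("radius_mm must be positive")

  key <- paste(tab$network, tab$name, sep = ":")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate (network, name) pair at row ", dup[1L], ": ", key[dup[1L]])
  }
  tab <- dplyr::mutate(tab, node_id = key, .before = 1L)

  nets <- unique(tab$network)
  cls <- unname(network_classes[nets])
  cls[is.na(cls)] <- "other"
  networks <- tibble::tibble(network = nets, class = cls)

  structure(tab, networks = networks,
            class = c("roi_atlas", class(tibble::tibble())))
}

#' @export
print.roi_atlas <- function(x, ...) {
  nets <- attr(x, "networks")
  cat("<roi_atlas> ", nrow(x), " nodes in ", nrow(nets), " networks\n", sep = "")
  NextMethod()
}

#' Networks of an atlas
#'
#' @param atlas An `roi_atlas`.
#' @return Tibble with `network` and `class` columns in canonical order.
#' @export
atlas_networks <- function(atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  attr(atlas, "networks")
}

#' Stable fingerprint of an atlas node order
#'
#' Used to assert that every subject's connectivity matrix was computed under
#' the same node order.
#'
#' @param atlas An `roi_atlas`.
#' @return A character scalar.
#' @export
atlas_hash <- function(atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  rlang::hash(list(atlas$node_id, atlas$x, atlas$y, atlas$z, atlas$radius_mm))
}

#' Enumerate node pairs of an atlas
#'
#' Lists every unordered node pair (i < j in canonical node order), tagging
#' each as within-network or between-network.
#'
#' @param atlas An `roi_atlas`.
#' @return Tibble with columns `i`, `j` (node indices), `node_a`, `node_b`,
#'   `network_a`, `network_b`, `within` (logical).
#' @export
node_pair_table <- function(atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  n <- nrow(atlas)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]
  j <- idx[, 2L]
  tibble::tibble(
    i = i, j = j,
    node_a = atlas$node_id[i], node_b = atlas$node_id[j],
    network_a = atlas$network[i], network_b = atlas$network[j],
    within = atlas$network[i] == atlas$network[j]
  )
}

#' Count node pairs of an atlas
#'
#' Total pairs n(n-1)/2, split into within-network and between-network pairs.
#' For the standard 42-node atlas this gives 861 total = 109 within + 752
#' between.
#'
#' @param atlas An `roi_atlas`.
#' @return Tibble with one row: `total`, `within`, `between`.
#' @export
count_node_pairs <- function(atlas) {
  pairs <- node_pair_table(atlas)
  tibble::tibble(
    total = nrow(pairs),
    within = sum(pairs$within),
    between = sum(!pairs$within)
  )
}
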