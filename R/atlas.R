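# Region hierarchy + per-slice 2-D label masks. All counts downstream live in
# this coordinate frame. Coordinates handed to/from users are 0-based
# (x = column, y = row); matrix indexing inside the package is 1-based R.

LEVEL_TAGS <- c("leaf", "summary", "meta")

#' Construct and validate a region hierarchy table
#'
#' @param nodes data.frame with columns `id` (positive integer, unique),
#'   `acronym`, `name`, `parent_id` (NA for the single root) and `level_tag`
#'   (one of `"leaf"`, `"summary"`, `"meta"`).
#' @return the validated data.frame, classed `region_nodes`.
#' @export
region_nodes <- function(nodes) {
  req <- c("id", "acronym", "name", "parent_id", "level_tag")
  if (!all(req %in% names(nodes))) {
    stop("hierarchy must have columns: ", paste(req, collapse = ", "))
  }
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyNA(nodes$id) || any(nodes$id <= 0)) stop("region ids must be positive integers")
  if (anyDuplicated(nodes$id)) stop("duplicate region ids")
  if (!all(nodes$level_tag %in% LEVEL_TAGS)) {
    stop("level_tag must be one of: ", paste(LEVEL_TAGS, collapse = ", "))
  }
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1L) stop("hierarchy must have exactly one root, found ", length(roots))
  known <- nodes$id
  bad <- setdiff(nodes$parent_id[!is.na(nodes$parent_id)], known)
  if (length(bad)) stop("parent_id not in hierarchy: ", paste(bad, collapse = ", "))
  # cycle check: every node must reach the root in <= n steps
  parent_of <- stats::setNames(nodes$parent_id, nodes$id)
  n <- nrow(nodes)
  for (id in nodes$id) {
    cur <- id
    for (step in seq_len(n + 1L)) {
      p <- parent_of[[as.character(cur)]]
      if (is.na(p)) break
      cur <- p
      if (step > n) stop("cyclic hierarchy detected at region ", id)
    }
    if (!is.na(parent_of[[as.character(cur)]])) {
      stop("cyclic hierarchy detected at region ", id)
    }
  }
  class(nodes) <- c("region_nodes", "data.frame")
  nodes
}

#' Construct one atlas slice
#'
#' @param label_mask integer matrix; each pixel a region id or 0 outside brain.
#' @param ap_mm anterior-posterior coordinate in mm from bregma.
#' @param pixel_size_um microns per pixel, > 0.
#' @param midline_x column index (0-based, may be half-integer) of the
#'   sagittal midline.
#' @return an `atlas_slice` object.
#' @export
atlas_slice <- function(label_mask, ap_mm, pixel_size_um, midline_x) {
  stopifnot(is.matrix(label_mask), pixel_size_um > 0)
  structure(list(label_mask = label_mask, ap_mm = as.numeric(ap_mm),
                 pixel_size_um = as.numeric(pixel_size_um),
                 midline_x = as.numeric(midline_x)),
            class = "atlas_slice")
}

#' Assemble a region atlas from nodes and slices
#'
#' @param nodes a `region_nodes` table (or a data.frame accepted by
#'   [region_nodes()]).
#' @param slices list of [atlas_slice()] objects; will be ordered by
#'   decreasing `ap_mm`.
#' @param ap_window_mm analysis window as `c(ap_max, ap_min)` in mm from
#'   bregma; defaults to the +3.5 .. -4.5 mm span that drops the olfactory
#'   bulb and cerebellum.
#' @return a `region_atlas` object.
#' @export
region_atlas <- function(nodes, slices, ap_window_mm = c(3.5, -4.5)) {
  nodes <- region_nodes(as.data.frame(nodes))
  stopifnot(length(ap_window_mm) == 2L, ap_window_mm[1] > ap_window_mm[2])
  aps <- vapply(slices, function(s) s$ap_mm, numeric(1))
  slices <- slices[order(aps, decreasing = TRUE)]
  aps <- sort(aps, decreasing = TRUE)
  if (length(aps) > 1 && any(diff(aps) >= 0)) {
    stop("slice ap_mm values must be strictly decreasing")
  }
  known <- nodes$id
  for (i in seq_along(slices)) {
    ids <- setdiff(unique(as.vector(slices[[i]]$label_mask)), 0L)
    bad <- setdiff(ids, known)
    if (length(bad)) {
      stop("mask slice ", i, " contains undeclared region id(s): ",
           paste(sort(bad), collapse = ", "))
    }
  }
  structure(list(nodes = nodes, slices = slices,
                 ap_window_mm = as.numeric(ap_window_mm)),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("region_atlas:", nrow(x$nodes), "regions,", length(x$slices),
      "slices, AP window [", x$ap_window_mm[2], ",", x$ap_window_mm[1], "] mm\n")
  invisible(x)
}

#' Load an atlas from hierarchy JSON, mask TIFF stack, and JSON sidecar
#'
#' The hierarchy file holds a JSON array of `{id, acronym, name, parent_id,
#' level_tag}` records (`parent_id` null for the root). The mask stack is a
#' multi-page TIFF of integer label images; the sidecar is a JSON array of
#' `{ap_mm, pixel_size_um, midline_x}` in page order, optionally wrapped as
#' `{slices: [...], ap_window_mm: [max, min]}`.
#'
#' @param hierarchy_file path to hierarchy JSON.
#' @param mask_stack_file path to multi-page TIFF of label masks.
#' @param meta_file path to per-page sidecar JSON.
#' @return a `region_atlas`.
#' @export
load_atlas <- function(hierarchy_file, mask_stack_file, meta_file) {
  for (f in c(hierarchy_file, mask_stack_file, meta_file)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  hier <- jsonlite::fromJSON(hierarchy_file)
  if (is.null(hier$parent_id)) hier$parent_id <- NA_integer_
  meta <- jsonlite::fromJSON(meta_file)
  ap_window <- c(3.5, -4.5)
  if (!is.null(meta$slices)) {
    if (!is.null(meta$ap_window_mm)) ap_window <- meta$ap_window_mm
    meta <- meta$slices
  }
  masks <- read_tiff_stack(mask_stack_file)
  if (length(masks) != nrow(meta)) {
    stop("mask stack has ", length(masks), " pages but sidecar describes ",
         nrow(meta))
  }
  slices <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    storage.mode(m) <- "integer"
    atlas_slice(m, meta$ap_mm[i], meta$pixel_size_um[i], meta$midline_x[i])
  })
  region_atlas(hier, slices, ap_window_mm = ap_window)
}

#' Save an atlas as hierarchy JSON + mask TIFF + sidecar JSON
#'
#' Inverse of [load_atlas()]; `load_atlas()` on the written files
#' reconstructs an identical atlas.
#'
#' @param atlas a `region_atlas`.
#' @param hierarchy_file,mask_stack_file,meta_file output paths.
#' @return invisibly, the three paths.
#' @export
save_atlas <- function(atlas, hierarchy_file, mask_stack_file, meta_file) {
  stopifnot(inherits(atlas, "region_atlas"))
  jsonlite::write_json(as.data.frame(atlas$nodes), hierarchy_file,
                       na = "null", digits = NA)
  write_tiff_stack(lapply(atlas$slices, `[[`, "label_mask"), mask_stack_file,
                   bits = 16L)
  meta <- list(
    ap_window_mm = atlas$ap_window_mm,
    slices = data.frame(
      ap_mm = vapply(atlas$slices, `[[`, numeric(1), "ap_mm"),
      pixel_size_um = vapply(atlas$slices, `[[`, numeric(1), "pixel_size_um"),
      midline_x = vapply(atlas$slices, `[[`, numeric(1), "midline_x")
    )
  )
  jsonlite::write_json(meta, meta_file, digits = NA)
  invisible(c(hierarchy_file, mask_stack_file, meta_file))
}

#' Test whether an AP coordinate falls inside the analysis window
#'
#' The window is closed on both ends: `ap_min <= ap_mm <= ap_max`. The
#' default window (+3.5 to -4.5 mm from bregma) excludes olfactory bulb and
#' cerebellum territory.
#'
#' @param atlas a `region_atlas`.
#' @param ap_mm AP coordinate(s) in mm from bregma.
#' @return logical vector.
#' @export
in_ap_window <- function(atlas, ap_mm) {
  stopifnot(inherits(atlas, "region_atlas"))
  ap_mm >= atlas$ap_window_mm[2] & ap_mm <= atlas$ap_window_mm[1]
}

# parent lookup as named integer vector (NA for root)
.parent_map <- function(atlas) {
  stats::setNames(atlas$nodes$parent_id, atlas$nodes$id)
}

#' All region ids in the subtree rooted at a region (self included)
#'
#' @param atlas a `region_atlas`.
#' @param region_id subtree root id.
#' @return integer vector of region ids.
#' @export
region_subtree <- function(atlas, region_id) {
  region_id <- as.integer(region_id)
  if (!region_id %in% atlas$nodes$id) stop("unknown region id: ", region_id)
  out <- region_id
  frontier <- region_id
  while (length(frontier)) {
    kids <- atlas$nodes$id[!is.na(atlas$nodes$parent_id) &
                             atlas$nodes$parent_id %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Aggregate per-region counts up the hierarchy to a reporting tier
#'
#' Each input count is added to its nearest self-or-ancestor node carrying
#' `level_tag`; counts whose ancestor chain carries no such tag accumulate
#' under the root. Totals are conserved exactly.
#'
#' @param counts named numeric vector, names = region ids.
#' @param atlas a `region_atlas`.
#' @param level_tag target tier: `"leaf"`, `"summary"` or `"meta"`.
#' @return named numeric vector of aggregated counts.
#' @export
aggregate_counts <- function(counts, atlas, level_tag) {
  stopifnot(inherits(atlas, "region_atlas"), level_tag %in% LEVEL_TAGS)
  ids <- as.integer(names(counts))
  if (anyNA(ids)) stop("counts must be named by region id")
  bad <- setdiff(ids, atlas$nodes$id)
  if (length(bad)) stop("unknown region id(s): ", paste(sort(bad), collapse = ", "))
  parent_of <- .parent_map(atlas)
  tag_of <- stats::setNames(atlas$nodes$level_tag, atlas$nodes$id)
  root <- atlas$nodes$id[is.na(atlas$nodes$parent_id)]
  target <- vapply(ids, function(id) {
    cur <- id
    repeat {
      if (tag_of[[as.character(cur)]] == level_tag) return(cur)
      p <- parent_of[[as.character(cur)]]
      if (is.na(p)) return(root)
      cur <- p
    }
  }, integer(1))
  out <- tapply(as.numeric(counts), target, sum)
  stats::setNames(as.numeric(out), names(out))
}
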