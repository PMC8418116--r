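#' Vessel centerline geometry
#'
#' A vessel segment is a tibble with one row per centerline sample and two
#' columns: `arc_mm` (arc-length position along the centerline, millimetres,
#' strictly increasing) and `radius_mm` (lumen radius, millimetres, positive).
#' The segment id and an optional anatomical label (e.g. "LAD", "LCx", "RCA")
#' travel as attributes so the object pipes through dplyr verbs untouched.
#'
#' @param arc_mm Numeric vector of arc-length positions (mm), strictly
#'   increasing, at least two values.
#' @param radius_mm Numeric vector of lumen radii (mm), same length, all > 0.
#' @param segment_id Identifier for the segment.
#' @param label Optional free-text anatomical label.
#'
#' @return A `vessel_segment` tibble with columns `arc_mm`, `radius_mm`.
#' @export
#'
#' @examples
#' vessel_segment(c(0, 15, 30), c(1.5, 1.2, 1.5), segment_id = "LAD1")
vessel_segment <- function(arc_mm, radius_mm, segment_id = "vessel", label = NULL) {
  if (length(arc_mm) != length(radius_mm)) {
    stop_invalid("`arc_mm` and `radius_mm` must have the same length.")
  }
  seg <- tibble(arc_mm = as.numeric(arc_mm), radius_mm = as.numeric(radius_mm))
  attr(seg, "segment_id") <- as.character(segment_id)
  attr(seg, "label") <- label
  class(seg) <- c("vessel_segment", class(seg))
  validate_segment(seg)
}

#' @rdname vessel_segment
#' @param segment Object to validate.
#' @export
validate_segment <- function(segment) {
  if (!is.data.frame(segment) || !all(c("arc_mm", "radius_mm") %in% names(segment))) {
    stop_invalid("A vessel segment needs `arc_mm` and `radius_mm` columns.")
  }
  if (nrow(segment) < 2) {
    stop_invalid("A vessel segment needs at least 2 centerline samples.")
  }
  if (any(!is.finite(segment$arc_mm)) || any(!is.finite(segment$radius_mm))) {
    stop_invalid("Centerline samples must be finite.")
  }
  if (any(diff(segment$arc_mm) <= 0)) {
    stop_invalid("`arc_mm` must be strictly increasing along the segment.")
  }
  if (any(segment$radius_mm <= 0)) {
    stop_invalid("All radii must be positive.")
  }
  invisible(segment)
}

segment_id <- function(segment) attr(segment, "segment_id") %||% "vessel"

segment_length <- function(segment) {
  max(segment$arc_mm) - min(segment$arc_mm)
}

#' Build an idealised straight vessel
#'
#' Constant-radius segment sampled at evenly spaced arc positions; the standard
#' starting point for parametric stenosis studies and test fixtures.
#'
#' @param diameter Lumen diameter (mm), > 0.
#' @param length Segment length (mm), > 0.
#' @param n_samples Number of centerline samples (>= 2).
#' @inheritParams vessel_segment
#'
#' @return A [vessel_segment()] tibble.
#' @export
#'
#' @examples
#' make_straight_vessel(3, 30, 31)
make_straight_vessel <- function(diameter, length, n_samples = 201,
                                 segment_id = "vessel", label = NULL) {
  if (!is.numeric(diameter) || diameter <= 0) stop_invalid("`diameter` must be > 0.")
  if (!is.numeric(length) || length <= 0) stop_invalid("`length` must be > 0.")
  if (n_samples < 2) stop_invalid("`n_samples` must be at least 2.")
  vessel_segment(
    arc_mm = seq(0, length, length.out = n_samples),
    radius_mm = rep(diameter / 2, n_samples),
    segment_id = segment_id, label = label
  )
}

#' Parametric stenosis description
#'
#' A focal narrowing parameterised by its centre (arc position), axial length
#' and fractional area stenosis. `area_stenosis = 0.7` means the minimal lumen
#' area is 30% of the local reference area; the corresponding diameter
#' stenosis is `1 - sqrt(1 - 0.7)` = 45.2%.
#'
#' @param center Arc position of the lesion centre (mm).
#' @param length Axial lesion length (mm), > 0.
#' @param area_stenosis Fractional area reduction in `[0, 1)`.
#'
#' @return A `stenosis_spec` list.
#' @export
stenosis_spec <- function(center, length, area_stenosis) {
  if (!is.numeric(length) || length <= 0) stop_invalid("Stenosis `length` must be > 0.")
  if (!is.numeric(area_stenosis) || area_stenosis < 0 || area_stenosis >= 1) {
    stop_invalid("`area_stenosis` must lie in [0, 1).")
  }
  structure(
    list(center = center, length = length, area_stenosis = area_stenosis),
    class = "stenosis_spec"
  )
}

#' Impose a cosine-tapered stenosis on a segment
#'
#' Inside the lesion window the local radius is scaled by a raised-cosine
#' factor so that the minimal radius is `sqrt(1 - area_stenosis)` times the
#' pre-lesion radius (minimal area = `(1 - area_stenosis)` times the reference
#' area) and the profile blends smoothly into the healthy vessel at both ends.
#'
#' @param segment A [vessel_segment()].
#' @param spec A [stenosis_spec()]; its window must lie within the segment.
#'
#' @return The segment with the narrowed radius profile.
#' @export
#'
#' @examples
#' v <- make_straight_vessel(3, 30, 201)
#' apply_stenosis(v, stenosis_spec(center = 15, length = 10, area_stenosis = 0.7))
apply_stenosis <- function(segment, spec) {
  validate_segment(segment)
  if (!inherits(spec, "stenosis_spec")) {
    spec <- do.call(stenosis_spec, as.list(spec))
  }
  lo <- spec$center - spec$length / 2
  hi <- spec$center + spec$length / 2
  if (lo < min(segment$arc_mm) || hi > max(segment$arc_mm)) {
    stop_invalid("Stenosis window falls outside the segment.")
  }
  if (spec$area_stenosis == 0) {
    return(segment)
  }
  depth <- 1 - sqrt(1 - spec$area_stenosis)
  z <- segment$arc_mm
  inside <- z >= lo & z <= hi
  factor <- rep(1, length(z))
  factor[inside] <- 1 - depth * (1 + cos(2 * pi * (z[inside] - spec$center) / spec$length)) / 2
  out <- segment
  out$radius_mm <- segment$radius_mm * factor
  out
}

#' Reference (healthy) radius of a segment
#'
#' The mean radius over the proximal and distal 10% of the arc length — the
#' package's convention for the healthy caliber against which a lesion is
#' measured.
#'
#' @param segment A [vessel_segment()].
#' @param ends_fraction Fraction of the arc length at each end treated as
#'   disease-free (default 0.10).
#'
#' @return Reference radius (mm).
#' @export
reference_radius <- function(segment, ends_fraction = 0.10) {
  validate_segment(segment)
  a0 <- min(segment$arc_mm)
  a1 <- max(segment$arc_mm)
  margin <- ends_fraction * (a1 - a0)
  ends <- segment$arc_mm <= a0 + margin | segment$arc_mm >= a1 - margin
  mean(segment$radius_mm[ends])
}

#' Percent diameter stenosis of a segment
#'
#' `1 - min(radius) / reference radius`, with the reference taken from
#' [reference_radius()]. For a circular lumen the diameter ratio is the square
#' root of the area ratio, so a 70% area stenosis reads as 45.2% diameter
#' stenosis.
#'
#' @inheritParams reference_radius
#'
#' @return Fractional diameter stenosis in `[0, 1)`.
#' @export
percent_diameter_stenosis <- function(segment) {
  1 - min(segment$radius_mm) / reference_radius(segment)
}

#' Read and write centerline CSV files
#'
#' The on-disk format is a UTF-8 CSV with header `arc_mm,radius_mm`, '.'
#' decimal separator and `#` comment lines. Values are written as decimal text
#' with 9 significant digits, so write-then-read reproduces a written file
#' bit-exactly.
#'
#' @param path File path.
#' @inheritParams vessel_segment
#'
#' @return `read_centerline()` returns a [vessel_segment()];
#'   `write_centerline()` returns `path` invisibly.
#' @export
read_centerline <- function(path, segment_id = NULL, label = NULL) {
  if (!file.exists(path)) stop_format(paste0("Centerline file not found: ", path))
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double())),
    error = function(e) stop_format(paste0("Cannot parse ", path, ": ", conditionMessage(e)))
  )
  if (!all(c("arc_mm", "radius_mm") %in% names(df))) {
    stop_format(paste0(path, ": missing required columns `arc_mm,radius_mm`."))
  }
  bad_radius <- which(!is.finite(df$radius_mm) | df$radius_mm <= 0)
  if (length(bad_radius) > 0) {
    stop_format(paste0(path, ": non-positive radius at data row ", bad_radius[1], "."))
  }
  bad_arc <- which(diff(df$arc_mm) <= 0)
  if (length(bad_arc) > 0) {
    stop_format(paste0(path, ": arc_mm not strictly increasing at data row ", bad_arc[1] + 1, "."))
  }
  if (nrow(df) < 2) stop_format(paste0(path, ": needs at least 2 data rows."))
  vessel_segment(df$arc_mm, df$radius_mm,
                 segment_id = segment_id %||% tools::file_path_sans_ext(basename(path)),
                 label = label)
}

#' @rdname read_centerline
#' @param segment A [vessel_segment()] to serialise.
#' @export
write_centerline <- function(segment, path) {
  validate_segment(segment)
  lines <- c(
    "arc_mm,radius_mm",
    paste(fmt9(segment$arc_mm), fmt9(segment$radius_mm), sep = ",")
  )
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# decimal text, 9 significant digits, no scientific notation surprises
fmt9 <- function(x) formatC(x, digits = 9, format = "g", flag = "")

#' Coronary-tree topology
#'
#' A binary tree of vessel segments: exactly one root, every non-root has one
#' parent, and internal nodes have either one child (a continuation) or two
#' (a bifurcation). Trifurcations and cycles are rejected.
#'
#' @param segments Named list of [vessel_segment()] objects (names = ids).
#' @param root Id of the root segment.
#' @param children Named list mapping a parent id to a character vector of
#'   child ids; leaves may be omitted.
#'
#' @return A `coronary_tree` list with elements `segments`, `root`, `children`.
#' @export
coronary_tree <- function(segments, root, children = list()) {
  ids <- names(segments)
  if (is.null(ids) || any(ids == "")) stop_invalid("`segments` must be a named list.")
  if (!root %in% ids) stop_invalid("`root` is not among the segment ids.")
  parent_of <- list()
  for (p in names(children)) {
    kids <- children[[p]]
    if (!p %in% ids) stop_invalid(paste0("Unknown parent id: ", p))
    if (length(kids) > 2) {
      stop_topology(paste0("Node ", p, " has ", length(kids),
                           " children; only continuations (1) and bifurcations (2) are supported."))
    }
    for (k in kids) {
      if (!k %in% ids) stop_invalid(paste0("Unknown child id: ", k))
      if (!is.null(parent_of[[k]])) {
        stop_invalid(paste0("Node ", k, " has more than one parent."))
      }
      parent_of[[k]] <- p
    }
  }
  non_root <- setdiff(ids, root)
  orphans <- setdiff(non_root, names(parent_of))
  if (length(orphans) > 0) {
    stop_invalid(paste0("Multiple roots / disconnected nodes: ", paste(orphans, collapse = ", ")))
  }
  if (!is.null(parent_of[[root]])) stop_invalid("The root must not have a parent.")
  # acyclicity: walk up from every node; a cycle would never reach the root
  for (id in non_root) {
    seen <- character()
    cur <- id
    while (!is.null(parent_of[[cur]])) {
      if (cur %in% seen) stop_invalid("Topology contains a cycle.")
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
    if (cur != root) stop_invalid("Topology contains a cycle or disconnected component.")
  }
  lapply(segments, validate_segment)
  structure(list(segments = segments, root = root, children = children),
            class = "coronary_tree")
}

#' Read a coronary tree from its JSON description
#'
#' The JSON holds `{"segments": [{"id", "label", "centerline_file"}, ...],
#' "root": id, "children": {id: [id, id], ...}}`; centerline files are
#' resolved relative to the JSON file's directory.
#'
#' @param path Path to the tree JSON file.
#'
#' @return A [coronary_tree()].
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop_format(paste0("Tree file not found: ", path))
  spec <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                   error = function(e) stop_format(paste0("Cannot parse ", path, ": ",
                                                          conditionMessage(e))))
  if (is.null(spec$segments) || is.null(spec$root)) {
    stop_format(paste0(path, ": tree JSON needs `segments` and `root`."))
  }
  segs <- spec$segments
  base <- dirname(path)
  segments <- list()
  for (i in seq_len(nrow(segs))) {
    f <- segs$centerline_file[i]
    if (!file.exists(f)) f <- file.path(base, segs$centerline_file[i])
    segments[[segs$id[i]]] <- read_centerline(
      f, segment_id = segs$id[i],
      label = if ("label" %in% names(segs)) segs$label[i] else NULL
    )
  }
  children <- lapply(spec$children, as.character)
  coronary_tree(segments, root = spec$root, children = children)
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<vessel_segment> %s%s: %d samples, length %.2f mm, radius %.3f-%.3f mm\n",
              segment_id(x),
              if (!is.null(attr(x, "label"))) paste0(" (", attr(x, "label"), ")") else "",
              nrow(x), segment_length(x), min(x$radius_mm), max(x$radius_mm)))
  NextMethod()
}
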