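# Export of cutting contours in the Leica LMD XML dialect: three stage
# calibration points followed by per-shape vertex lists. A matching reader is
# provided so exports can be round-tripped and inspected.

fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

#' Export contours and calibration points as LMD-style XML
#'
#' @param contours list of [cell_contour()] (may be empty).
#' @param ref_points exactly three (x, y) calibration points, as a list of
#'   length-2 numeric vectors or a 3 x 2 matrix.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_lmd_xml <- function(contours, ref_points, path) {
  if (is.matrix(ref_points))
    ref_points <- lapply(seq_len(nrow(ref_points)), function(i) ref_points[i, ])
  if (length(ref_points) != 3L)
    zn_stop("exactly 3 reference (calibration) points are required")
  doc <- xml2::xml_new_root("ImageData")
  xml2::xml_add_child(doc, "GlobalCoordinates", "1")
  for (i in 1:3) {
    xml2::xml_add_child(doc, sprintf("X_CalibrationPoint_%d", i),
                        fmt_num(ref_points[[i]][1]))
    xml2::xml_add_child(doc, sprintf("Y_CalibrationPoint_%d", i),
                        fmt_num(ref_points[[i]][2]))
  }
  xml2::xml_add_child(doc, "ShapeCount", as.character(length(contours)))
  for (s in seq_along(contours)) {
    ct <- contours[[s]]
    sh <- xml2::xml_add_child(doc, sprintf("Shape_%d", s))
    xml2::xml_add_child(sh, "PointCount", as.character(nrow(ct$vertices)))
    xml2::xml_add_child(sh, "CapID", ct$id)
    for (i in seq_len(nrow(ct$vertices))) {
      xml2::xml_add_child(sh, sprintf("X_%d", i), fmt_num(ct$vertices[i, 1]))
      xml2::xml_add_child(sh, sprintf("Y_%d", i), fmt_num(ct$vertices[i, 2]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an LMD-style XML contour file
#'
#' @param path file written by [export_lmd_xml()] (or compatible).
#' @return list with `contours` (list of [cell_contour()]) and `ref_points`
#'   (list of three (x, y) points).
#' @export
read_lmd_xml <- function(path) {
  doc <- xml2::read_xml(path)
  get1 <- function(node, name) xml2::xml_text(xml2::xml_find_first(node, name))
  ref_points <- lapply(1:3, function(i) {
    c(as.numeric(get1(doc, sprintf("./X_CalibrationPoint_%d", i))),
      as.numeric(get1(doc, sprintf("./Y_CalibrationPoint_%d", i))))
  })
  n_shapes <- as.integer(get1(doc, "./ShapeCount"))
  contours <- lapply(seq_len(n_shapes), function(s) {
    sh <- xml2::xml_find_first(doc, sprintf("./Shape_%d", s))
    np <- as.integer(get1(sh, "./PointCount"))
    v <- vapply(seq_len(np), function(i) {
      c(as.numeric(get1(sh, sprintf("./X_%d", i))),
        as.numeric(get1(sh, sprintf("./Y_%d", i))))
    }, numeric(2))
    cell_contour(get1(sh, "./CapID"), t(v))
  })
  list(contours = contours, ref_points = ref_points)
}
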