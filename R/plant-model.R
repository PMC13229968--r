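# Domain types for organ-level plant architecture and the XML dialect.
#
# The hierarchy is shoots -> phytomers -> internode / petiole / leaves.
# All angles are stored in degrees; lengths in metres. Conversion to radians
# happens only inside the geometry module.

#' Construct a leaf
#'
#' A leaf (or leaflet) is described by a dimensionless size scale and the
#' pitch/yaw/roll angles of its lamina frame relative to the parent petiole
#' frame.
#'
#' @param scale Dimensionless size scale, > 0. Leaf area is
#'   `scale^2 * unit_leaf_area` (see [reconstruct_geometry()]).
#' @param pitch,yaw,roll Angles in degrees.
#' @return An object of class `pa_leaf`.
#' @export
leaf <- function(scale, pitch = 0, yaw = 0, roll = 0) {
  structure(list(scale = as.numeric(scale), pitch = as.numeric(pitch),
                 yaw = as.numeric(yaw), roll = as.numeric(roll)),
            class = "pa_leaf")
}

#' Construct a petiole
#'
#' @param length,radius Dimensions in metres, > 0.
#' @param pitch Pitch angle away from the internode axis, degrees.
#' @param curvature Signed curvature number as stored in the architecture
#'   file. The geometry module interprets it as a bend rate in degrees per
#'   metre of petiole length.
#' @param leaflet_scale Relative size of the lateral leaflets; present only
#'   for trifoliate phytomers (`NULL` otherwise).
#' @return An object of class `pa_petiole`.
#' @export
petiole <- function(length, radius, pitch = 0, curvature = 0,
                    leaflet_scale = NULL) {
  structure(list(length = as.numeric(length), radius = as.numeric(radius),
                 pitch = as.numeric(pitch), curvature = as.numeric(curvature),
                 leaflet_scale = if (is.null(leaflet_scale)) NULL else as.numeric(leaflet_scale)),
            class = "pa_petiole")
}

#' Construct an internode
#'
#' @param length,radius Dimensions in metres, > 0.
#' @param pitch Pitch angle relative to the previous internode frame, degrees.
#' @param phyllotactic_angle Azimuthal rotation between successive phytomers,
#'   degrees.
#' @return An object of class `pa_internode`.
#' @export
internode <- function(length, radius, pitch = 0, phyllotactic_angle = 0) {
  structure(list(length = as.numeric(length), radius = as.numeric(radius),
                 pitch = as.numeric(pitch),
                 phyllotactic_angle = as.numeric(phyllotactic_angle)),
            class = "pa_internode")
}

#' Construct a phytomer
#'
#' The repeating structural unit of a shoot: one internode with one petiole
#' and the leaves it bears. Unifoliate phytomers carry one or two leaves,
#' trifoliate phytomers exactly three leaflets.
#'
#' @param internode A [internode()] object.
#' @param petiole A [petiole()] object.
#' @param leaves List of 1--3 [leaf()] objects.
#' @return An object of class `pa_phytomer`.
#' @export
phytomer <- function(internode, petiole, leaves) {
  if (inherits(leaves, "pa_leaf")) leaves <- list(leaves)
  structure(list(internode = internode, petiole = petiole, leaves = leaves),
            class = "pa_phytomer")
}

#' Construct a shoot
#'
#' @param shoot_id Integer id, unique within the plant; ids are assigned in
#'   depth-first order starting at 0.
#' @param parent_shoot_id Id of the parent shoot, or -1 for the primary shoot.
#' @param parent_node_index 0-based phytomer index on the parent shoot where
#'   this shoot attaches, or -1 for the primary shoot.
#' @param branching_order Depth in the branching hierarchy; primary shoot is
#'   0, maximum supported order is 3.
#' @param shoot_type_label 1 for a unifoliate shoot, 3 for trifoliate.
#' @param base_pitch,base_yaw,base_roll Shoot base angles, degrees.
#' @param phytomers Ordered list of [phytomer()] objects.
#' @return An object of class `pa_shoot`.
#' @export
shoot <- function(shoot_id, parent_shoot_id = -1L, parent_node_index = -1L,
                  branching_order = 0L, shoot_type_label = 1,
                  base_pitch = 0, base_yaw = 0, base_roll = 0,
                  phytomers = list()) {
  structure(list(shoot_id = as.integer(shoot_id),
                 parent_shoot_id = as.integer(parent_shoot_id),
                 parent_node_index = as.integer(parent_node_index),
                 branching_order = as.integer(branching_order),
                 shoot_type_label = as.numeric(shoot_type_label),
                 base_pitch = as.numeric(base_pitch),
                 base_yaw = as.numeric(base_yaw),
                 base_roll = as.numeric(base_roll),
                 phytomers = phytomers),
            class = "pa_shoot")
}

#' Construct a plant architecture
#'
#' @param shoots Ordered list of [shoot()] objects; every parent must appear
#'   before its children and exactly one shoot must have
#'   `parent_shoot_id == -1`.
#' @param plant_age Days after germination, >= 0.
#' @param base_rotation Numeric length-3 vector of (pitch, yaw, roll) in
#'   degrees applied to the whole plant.
#' @param base_position Numeric length-3 position of the plant base, metres.
#' @return An object of class `pa_plant`.
#' @export
plant_architecture <- function(shoots, plant_age = 0,
                               base_rotation = c(0, 0, 0),
                               base_position = c(0, 0, 0)) {
  structure(list(base_position = as.numeric(base_position),
                 base_rotation = as.numeric(base_rotation),
                 plant_age = as.numeric(plant_age),
                 shoots = shoots),
            class = "pa_plant")
}

#' Construct plant image metadata
#'
#' Plant-level quantities recorded alongside a token sequence: the plant's
#' width and height in metres and the vegetation fraction (proportion of the
#' image window covered by vegetation).
#'
#' @param width_m,height_m Extents in metres, >= 0.
#' @param vegetation_fraction Value in `[0, 1]`.
#' @return An object of class `pa_metadata`.
#' @export
plant_metadata <- function(width_m, height_m, vegetation_fraction) {
  structure(list(width_m = as.numeric(width_m),
                 height_m = as.numeric(height_m),
                 vegetation_fraction = as.numeric(vegetation_fraction)),
            class = "pa_metadata")
}

#' @export
print.pa_plant <- function(x, ...) {
  n_phy <- sum(vapply(x$shoots, function(s) length(s$phytomers), integer(1)))
  n_leaf <- sum(vapply(x$shoots, function(s)
    sum(vapply(s$phytomers, function(p) length(p$leaves), integer(1))), integer(1)))
  cat(sprintf("<plant architecture> age %g d: %d shoot(s), %d phytomer(s), %d leaf/leaves\n",
              x$plant_age, length(x$shoots), n_phy, n_leaf))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Validation

.check_num <- function(x, what, path, positive = FALSE, out) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    return(c(out, sprintf("%s: %s must be a finite number", path, what)))
  if (positive && x <= 0)
    return(c(out, sprintf("%s: %s must be > 0 (got %g)", path, what, x)))
  out
}

#' Validate a plant architecture
#'
#' Checks every structural invariant of the data model and returns the
#' violations as character strings (empty character vector when the plant is
#' valid). Each violation names the offending organ path. Violations are data,
#' not errors.
#'
#' @param plant A [plant_architecture()] object.
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_architecture <- function(plant) {
  v <- character(0)
  if (!inherits(plant, "pa_plant"))
    return("plant: not a pa_plant object")
  if (!is.numeric(plant$plant_age) || plant$plant_age < 0)
    v <- c(v, "plant: plant_age must be >= 0")
  if (length(plant$base_rotation) != 3)
    v <- c(v, "plant: base_rotation must have 3 components")
  if (length(plant$shoots) == 0)
    return(c(v, "plant: must contain at least one shoot"))

  ids <- vapply(plant$shoots, function(s) s$shoot_id, numeric(1))
  roots <- which(vapply(plant$shoots, function(s) s$parent_shoot_id, numeric(1)) == -1)
  if (length(roots) != 1)
    v <- c(v, sprintf("plant: expected exactly one primary shoot (parent_shoot_id -1), found %d",
                      length(roots)))
  if (anyDuplicated(ids))
    v <- c(v, "plant: duplicated shoot ids")

  for (i in seq_along(plant$shoots)) {
    s <- plant$shoots[[i]]
    path <- sprintf("shoot[%d]", i - 1L)
    if (!(s$shoot_type_label %in% c(1, 3)))
      v <- c(v, sprintf("%s: shoot_type_label must be 1 or 3 (got %g)", path, s$shoot_type_label))
    if (s$branching_order < 0 || s$branching_order > 3)
      v <- c(v, sprintf("%s: branching_order must be in 0..3 (got %d)", path, s$branching_order))
    if (s$parent_shoot_id == -1) {
      if (s$branching_order != 0)
        v <- c(v, sprintf("%s: primary shoot must have branching_order 0", path))
    } else {
      j <- match(s$parent_shoot_id, ids)
      if (is.na(j)) {
        v <- c(v, sprintf("%s: parent_shoot_id %d does not exist", path, s$parent_shoot_id))
      } else {
        p <- plant$shoots[[j]]
        if (j >= i)
          v <- c(v, sprintf("%s: parent shoot %d must appear before its child", path, s$parent_shoot_id))
        if (s$branching_order != p$branching_order + 1L)
          v <- c(v, sprintf("%s: branching_order must be parent's + 1 (%d vs parent %d)",
                            path, s$branching_order, p$branching_order))
        if (s$parent_node_index < 0 || s$parent_node_index >= length(p$phytomers))
          v <- c(v, sprintf("%s: parent_node_index %d outside parent's phytomer range",
                            path, s$parent_node_index))
      }
    }
    if (length(s$phytomers) == 0)
      v <- c(v, sprintf("%s: shoot must carry at least one phytomer", path))
    for (k in seq_along(s$phytomers)) {
      ph <- s$phytomers[[k]]
      ppath <- sprintf("%s/phytomer[%d]", path, k - 1L)
      v <- .check_num(ph$internode$length, "internode length", ppath, TRUE, v)
      v <- .check_num(ph$internode$radius, "internode radius", ppath, TRUE, v)
      v <- .check_num(ph$petiole$length, "petiole length", ppath, TRUE, v)
      v <- .check_num(ph$petiole$radius, "petiole radius", ppath, TRUE, v)
      nl <- length(ph$leaves)
      tri <- !is.null(ph$petiole$leaflet_scale)
      if (tri && nl != 3)
        v <- c(v, sprintf("%s: trifoliate phytomer must carry exactly 3 leaflets (got %d)", ppath, nl))
      if (!tri && !(nl %in% c(1, 2)))
        v <- c(v, sprintf("%s: unifoliate phytomer must carry 1 or 2 leaves (got %d)", ppath, nl))
      for (l in seq_along(ph$leaves)) {
        lf <- ph$leaves[[l]]
        if (!is.finite(lf$scale) || lf$scale <= 0)
          v <- c(v, sprintf("%s/leaf[%d]: scale must be > 0", ppath, l - 1L))
      }
    }
  }
  v
}

.stop_if_invalid <- function(plant) {
  v <- validate_architecture(plant)
  if (length(v) > 0)
    stop("invalid plant architecture: ", paste(v, collapse = "; "), call. = FALSE)
  invisible(plant)
}

# ---------------------------------------------------------------------------
# XML dialect
#
# <plant_architecture age="...">
#   <base_position x="" y="" z=""/>
#   <base_rotation pitch="" yaw="" roll=""/>
#   <shoot id="" parent_shoot="" parent_node="" type="" order=""
#          base_pitch="" base_yaw="" base_roll="">
#     <phytomer>
#       <internode length="" radius="" pitch="" phyllotactic_angle=""/>
#       <petiole length="" radius="" pitch="" curvature="" [leaflet_scale=""]/>
#       <leaf scale="" pitch="" yaw="" roll=""/>  (1-3 per phytomer)
#     </phytomer>
#   </shoot>
# </plant_architecture>
#
# Shoots are siblings in depth-first order. Floats are written with 6
# significant digits, "." decimal separator, locale independent.

.fmt <- function(x) sprintf("%.6g", x)

#' Serialize a plant architecture to XML
#'
#' Writes the documented XML dialect with a fixed attribute order and floats
#' at 6 significant digits, so serialization is deterministic and
#' canonical-form documents round-trip byte-identically through
#' [read_architecture_xml()].
#'
#' @param plant A valid [plant_architecture()] object.
#' @param path Optional file path; when given the document is also written
#'   there (UTF-8, one plant per file).
#' @return The XML document as a single character string (invisibly when
#'   `path` is given).
#' @export
write_architecture_xml <- function(plant, path = NULL) {
  .stop_if_invalid(plant)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<plant_architecture age="%s">', .fmt(plant$plant_age)),
    sprintf('  <base_position x="%s" y="%s" z="%s"/>',
            .fmt(plant$base_position[1]), .fmt(plant$base_position[2]),
            .fmt(plant$base_position[3])),
    sprintf('  <base_rotation pitch="%s" yaw="%s" roll="%s"/>',
            .fmt(plant$base_rotation[1]), .fmt(plant$base_rotation[2]),
            .fmt(plant$base_rotation[3]))
  )
  for (s in plant$shoots) {
    out <- c(out, sprintf(
      '  <shoot id="%d" parent_shoot="%d" parent_node="%d" type="%s" order="%d" base_pitch="%s" base_yaw="%s" base_roll="%s">',
      s$shoot_id, s$parent_shoot_id, s$parent_node_index,
      .fmt(s$shoot_type_label), s$branching_order,
      .fmt(s$base_pitch), .fmt(s$base_yaw), .fmt(s$base_roll)))
    for (ph in s$phytomers) {
      out <- c(out, "    <phytomer>",
               sprintf('      <internode length="%s" radius="%s" pitch="%s" phyllotactic_angle="%s"/>',
                       .fmt(ph$internode$length), .fmt(ph$internode$radius),
                       .fmt(ph$internode$pitch), .fmt(ph$internode$phyllotactic_angle)))
      pet <- ph$petiole
      if (is.null(pet$leaflet_scale)) {
        out <- c(out, sprintf('      <petiole length="%s" radius="%s" pitch="%s" curvature="%s"/>',
                              .fmt(pet$length), .fmt(pet$radius), .fmt(pet$pitch),
                              .fmt(pet$curvature)))
      } else {
        out <- c(out, sprintf('      <petiole length="%s" radius="%s" pitch="%s" curvature="%s" leaflet_scale="%s"/>',
                              .fmt(pet$length), .fmt(pet$radius), .fmt(pet$pitch),
                              .fmt(pet$curvature), .fmt(pet$leaflet_scale)))
      }
      for (lf in ph$leaves)
        out <- c(out, sprintf('      <leaf scale="%s" pitch="%s" yaw="%s" roll="%s"/>',
                              .fmt(lf$scale), .fmt(lf$pitch), .fmt(lf$yaw), .fmt(lf$roll)))
      out <- c(out, "    </phytomer>")
    }
    out <- c(out, "  </shoot>")
  }
  out <- c(out, "</plant_architecture>")
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(doc, path, sep = "", useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

.req_attr <- function(node, attr) {
  val <- xml2::xml_attr(node, attr)
  if (is.na(val))
    stop(sprintf("element <%s> missing required attribute '%s'",
                 xml2::xml_name(node), attr), call. = FALSE)
  as.numeric(val)
}

#' Read a plant architecture from XML
#'
#' Parses the documented XML dialect (see [write_architecture_xml()]).
#' Malformed XML raises a parse error naming the offending line; a missing
#' required attribute raises a validation error naming the element and
#' attribute; a child shoot referencing a nonexistent or later-defined parent
#' raises a topology error. Organ order is preserved.
#'
#' @param x A file path or a character string containing an XML document.
#' @return A [plant_architecture()] object.
#' @export
read_architecture_xml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) stop("XML parse error: ", conditionMessage(e),
                                           call. = FALSE))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "plant_architecture")
    stop("root element must be <plant_architecture>", call. = FALSE)
  age <- .req_attr(root, "age")
  bp_node <- xml2::xml_find_first(root, "./base_position")
  br_node <- xml2::xml_find_first(root, "./base_rotation")
  if (inherits(bp_node, "xml_missing") || inherits(br_node, "xml_missing"))
    stop("document must contain <base_position> and <base_rotation>", call. = FALSE)
  base_position <- c(.req_attr(bp_node, "x"), .req_attr(bp_node, "y"),
                     .req_attr(bp_node, "z"))
  base_rotation <- c(.req_attr(br_node, "pitch"), .req_attr(br_node, "yaw"),
                     .req_attr(br_node, "roll"))

  shoot_nodes <- xml2::xml_find_all(root, "./shoot")
  if (length(shoot_nodes) == 0)
    stop("document contains no <shoot> elements", call. = FALSE)
  seen_ids <- integer(0)
  shoots <- vector("list", length(shoot_nodes))
  for (i in seq_along(shoot_nodes)) {
    sn <- shoot_nodes[[i]]
    sid <- as.integer(.req_attr(sn, "id"))
    parent <- as.integer(.req_attr(sn, "parent_shoot"))
    if (parent != -1 && !(parent %in% seen_ids))
      stop(sprintf("topology error: shoot %d references parent shoot %d, which is absent or defined later",
                   sid, parent), call. = FALSE)
    phyt_nodes <- xml2::xml_find_all(sn, "./phytomer")
    phyts <- vector("list", length(phyt_nodes))
    for (k in seq_along(phyt_nodes)) {
      pn <- phyt_nodes[[k]]
      in_node <- xml2::xml_find_first(pn, "./internode")
      pe_node <- xml2::xml_find_first(pn, "./petiole")
      if (inherits(in_node, "xml_missing") || inherits(pe_node, "xml_missing"))
        stop(sprintf("phytomer %d of shoot %d must contain <internode> and <petiole>",
                     k - 1L, sid), call. = FALSE)
      lf_nodes <- xml2::xml_find_all(pn, "./leaf")
      ls_attr <- xml2::xml_attr(pe_node, "leaflet_scale")
      phyts[[k]] <- phytomer(
        internode(length = .req_attr(in_node, "length"),
                  radius = .req_attr(in_node, "radius"),
                  pitch = .req_attr(in_node, "pitch"),
                  phyllotactic_angle = .req_attr(in_node, "phyllotactic_angle")),
        petiole(length = .req_attr(pe_node, "length"),
                radius = .req_attr(pe_node, "radius"),
                pitch = .req_attr(pe_node, "pitch"),
                curvature = .req_attr(pe_node, "curvature"),
                leaflet_scale = if (is.na(ls_attr)) NULL else as.numeric(ls_attr)),
        lapply(lf_nodes, function(ln)
          leaf(scale = .req_attr(ln, "scale"), pitch = .req_attr(ln, "pitch"),
               yaw = .req_attr(ln, "yaw"), roll = .req_attr(ln, "roll"))))
    }
    shoots[[i]] <- shoot(shoot_id = sid, parent_shoot_id = parent,
                         parent_node_index = as.integer(.req_attr(sn, "parent_node")),
                         branching_order = as.integer(.req_attr(sn, "order")),
                         shoot_type_label = .req_attr(sn, "type"),
                         base_pitch = .req_attr(sn, "base_pitch"),
                         base_yaw = .req_attr(sn, "base_yaw"),
                         base_roll = .req_attr(sn, "base_roll"),
                         phytomers = phyts)
    seen_ids <- c(seen_ids, sid)
  }
  plant_architecture(shoots = shoots, plant_age = age,
                     base_rotation = base_rotation, base_position = base_position)
}
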