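# Plain-text archive I/O for meshes, scenes and priors. One file per
# object, sectioned with '>' headers, whitespace-delimited numeric blocks.

write_section <- function(con, name, mat) {
  writeLines(sprintf("> %s %d %d", name, nrow(mat), ncol(mat)), con)
  utils::write.table(mat, con, row.names = FALSE, col.names = FALSE)
}

read_archive <- function(file) {
  lines <- readLines(file)
  heads <- grep("^> ", lines)
  out <- list()
  for (i in seq_along(heads)) {
    h <- strsplit(sub("^> ", "", lines[heads[i]]), " ")[[1]]
    nr <- as.integer(h[2])
    block <- lines[(heads[i] + 1):(heads[i] + nr)]
    out[[h[1]]] <- matrix(scan(text = block, quiet = TRUE), nrow = nr,
                          byrow = TRUE)
  }
  out
}

#' Write a mesh to a single plain-text archive
#' @param mesh an `eit_mesh`
#' @param file output path
#' @export
write_mesh_archive <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# eit_mesh n_elec=%d", mesh$n_elec), con)
  write_section(con, "nodes", mesh$nodes)
  write_section(con, "elements", mesh$elements)
  write_section(con, "conductivity", cbind(mesh$element_conductivity))
  write_section(con, "contact_impedance", cbind(mesh$contact_impedance))
  el <- do.call(rbind, lapply(seq_along(mesh$electrodes), function(l) {
    cbind(l, mesh$electrodes[[l]])
  }))
  write_section(con, "electrodes", el)
  write_section(con, "polygon", mesh$polygon)
  invisible(file)
}

#' Read a mesh archive written by [write_mesh_archive()]
#' @param file input path
#' @return an `eit_mesh`
#' @export
read_mesh_archive <- function(file) {
  a <- read_archive(file)
  elements <- matrix(as.integer(a$elements), nrow(a$elements))
  nodes <- a$nodes
  n_elec <- max(a$electrodes[, 1])
  electrodes <- lapply(seq_len(n_elec), function(l) {
    as.integer(a$electrodes[a$electrodes[, 1] == l, 2])
  })
  areas <- tri_signed_areas(nodes, elements)
  centroids <- (nodes[elements[, 1], , drop = FALSE] +
                nodes[elements[, 2], , drop = FALSE] +
                nodes[elements[, 3], , drop = FALSE]) / 3
  structure(list(
    nodes = nodes, elements = elements,
    element_conductivity = as.numeric(a$conductivity),
    electrodes = electrodes,
    contact_impedance = as.numeric(a$contact_impedance),
    boundary = sort(unique(unlist(electrodes))),
    areas = areas, centroids = centroids,
    polygon = a$polygon,
    centre = polygon_centroid(a$polygon),
    n_elec = as.integer(n_elec)
  ), class = "eit_mesh")
}

#' Write a phantom scene to a single plain-text archive
#'
#' Stores the thorax polygon, the lung mask, the CT surrogate and the
#' ground-truth change raster with the registration extent.
#'
#' @param scene a `phantom_scene`
#' @param file output path
#' @export
write_scene_archive <- function(scene, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# phantom_scene state=%s", scene$state), con)
  write_section(con, "extent", cbind(unlist(scene$extent)))
  write_section(con, "polygon", scene$thorax_polygon)
  write_section(con, "lung_mask", scene$lung_mask * 1)
  write_section(con, "ct_hu", scene$ct_surrogate$values)
  write_section(con, "ground_truth", scene$ground_truth$values)
  invisible(file)
}

#' Import a structural prior from a raster file
#'
#' Reads a whitespace/comma-delimited numeric raster and an extent record,
#' returning a contour prior (values binarized at `threshold`) or a detail
#' prior (values taken as Hounsfield units).
#'
#' @param file raster file (M rows, N columns)
#' @param extent named extent (xmin, xmax, ymin, ymax)
#' @param kind "contour" or "detail"
#' @param lung_mask mask for a detail prior; defaults to nonzero raster
#'   pixels
#' @param threshold binarization threshold for the contour kind
#' @return a `structural_prior`
#' @export
prior_from_raster <- function(file, extent, kind = c("contour", "detail"),
                              lung_mask = NULL, threshold = 0.5) {
  kind <- match.arg(kind)
  v <- as.matrix(utils::read.table(file, sep = "", comment.char = "#"))
  dimnames(v) <- NULL
  if (kind == "contour") {
    make_contour_prior(v >= threshold, extent)
  } else {
    if (is.null(lung_mask)) lung_mask <- v != 0
    make_detail_prior(v, lung_mask, extent)
  }
}
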