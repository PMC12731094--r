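# Export: legacy-VTK image data, ASCII STL of voxel surfaces, YAML
# round-trip of scenario configurations.

#' Write fields on a voxel domain as legacy VTK (STRUCTURED_POINTS)
#'
#' ASCII legacy VTK with one CELL_DATA scalar array per supplied field;
#' readable by ParaView and friends.
#'
#' @param domain a [voxel_domain()].
#' @param path output `.vtk` file.
#' @param fields named list of 3-D arrays matching the domain shape
#'   (`NA`s are written as -1); the label array is always included.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(domain, path, fields = list()) {
  n <- domain$shape
  h <- domain$spacing
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "oxyflow voxel domain", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1] + 1L, n[2] + 1L,
                       n[3] + 1L),
               sprintf("ORIGIN %g %g %g", domain$origin[1],
                       domain$origin[2], domain$origin[3]),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("CELL_DATA %d", prod(n))), con)
  wr <- function(name, arr, type = "float") {
    writeLines(c(sprintf("SCALARS %s %s 1", name, type),
                 "LOOKUP_TABLE default"), con)
    v <- as.vector(arr)
    v[!is.finite(v)] <- -1
    writeLines(paste(formatC(v, format = if (type == "int") "d" else "g"),
                     collapse = " "), con)
  }
  wr("label", domain$labels, "int")
  for (nm in names(fields)) {
    if (!all(dim(fields[[nm]]) == n))
      stop("field '", nm, "' does not match the domain shape")
    wr(nm, fields[[nm]])
  }
  invisible(path)
}

#' Write a scaffold block surface as ASCII STL
#'
#' Emits two triangles per exposed voxel face of the `scaffold` solid.
#'
#' @param block a [voxel_domain()] scaffold block.
#' @param path output `.stl` file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(block, path) {
  lab <- block$labels
  h <- block$spacing
  d <- dim(lab)
  solid <- lab == VOXEL_LABELS[["scaffold"]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid oxyflow_scaffold", con)
  idx <- which(solid)
  ijk <- arrayInd(idx, d)
  tri_block <- function(p0, p1, p2, nrm) {
    # vectorized triangle emission: p0/p1/p2 are n x 3 vertex matrices
    paste(sprintf("facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
          "  outer loop",
          sprintf("    vertex %g %g %g", p0[, 1], p0[, 2], p0[, 3]),
          sprintf("    vertex %g %g %g", p1[, 1], p1[, 2], p1[, 3]),
          sprintf("    vertex %g %g %g", p2[, 1], p2[, 2], p2[, 3]),
          "  endloop", "endfacet", sep = "\n")
  }
  for (ax in 1:3) for (dsgn in c(-1L, 1L)) {
    nb <- ijk; nb[, ax] <- nb[, ax] + dsgn
    inside <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
    exposed <- !inside
    exposed[inside] <- !solid[vox_index(d, nb[inside, 1], nb[inside, 2],
                                        nb[inside, 3])]
    if (!any(exposed)) next
    base <- (ijk[exposed, , drop = FALSE] - 1) * h
    if (dsgn > 0) base[, ax] <- base[, ax] + h
    t1 <- setdiff(1:3, ax)[1]; t2 <- setdiff(1:3, ax)[2]
    nrm <- c(0, 0, 0); nrm[ax] <- dsgn
    p1 <- base; p1[, t1] <- p1[, t1] + h
    p2 <- p1; p2[, t2] <- p2[, t2] + h
    p3 <- base; p3[, t2] <- p3[, t2] + h
    writeLines(tri_block(base, p1, p2, nrm), con)
    writeLines(tri_block(base, p2, p3, nrm), con)
  }
  writeLines("endsolid oxyflow_scaffold", con)
  invisible(path)
}

#' Serialize a scenario configuration to YAML
#' @param config a [scenario_config()].
#' @param path output `.yaml` file.
#' @return `path`, invisibly.
#' @export
config_to_yaml <- function(config, path) {
  x <- list(
    name = config$name,
    chamber = unclass(config$chamber)[c("diameter", "fill_volume",
                                        "n_scaffolds", "port_diameter",
                                        "quarter")],
    scaffold = if (is.null(config$scaffold)) NULL else
      unclass(config$scaffold)[c("dims", "pore_diameter", "pore_spacing",
                                 "target_porosity", "variant", "seed",
                                 "spacing")],
    loading = unclass(config$loading),
    fluid = unclass(config$fluid),
    oxygen = unclass(config$oxygen)[c("D", "Km_mmHg", "C0", "K_O2",
                                      "per_cell_rate")],
    flow_rate = config$flow_rate,
    resolution = config$resolution,
    seed = config$seed,
    schedule = if (identical(config$schedule, "steady")) "steady" else
      config$schedule)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a scenario configuration from YAML
#' @param path a file written by [config_to_yaml()].
#' @return A [scenario_config()].
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  scenario_config(
    name = x$name,
    chamber = do.call(chamber_spec, x$chamber),
    scaffold = if (is.null(x$scaffold)) NULL else
      do.call(scaffold_spec, x$scaffold),
    loading = do.call(cell_loading, x$loading),
    fluid = do.call(fluid_props, x$fluid),
    oxygen = do.call(oxygen_params, x$oxygen),
    flow_rate = x$flow_rate,
    resolution = x$resolution,
    seed = x$seed,
    schedule = if (identical(x$schedule, "steady")) "steady" else x$schedule)
}
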