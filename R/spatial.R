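.zone_labels <- c("0-50 m", "50-250 m", "250-1000 m", ">1000 m")
.zone_breaks <- c(0, 50, 250, 1000, Inf)

#' Assemble a watershed grid
#'
#' Bundles the raster layers the buffer-zone analysis needs: a land-use class
#' layer, a stream mask, and (optionally) a sub-watershed label layer. All
#' layers must share dimensions; when read from ESRI ASCII files they must
#' also agree on cell size and origin.
#'
#' @param landuse integer matrix of class codes (0 = no class, `NA` = NODATA).
#' @param stream logical or 0/1 matrix marking stream (or reservoir) cells.
#' @param subwatershed matrix of sub-watershed labels (0 or `NA` = outside),
#'   or a single label applied everywhere; default `1`.
#' @param cell_size cell edge length in metres (> 0). Taken from the layers'
#'   `cellsize` attributes when present.
#' @return a `watershed_grid` list with fields `landuse`, `stream`,
#'   `subwatershed`, `cell_size`, `origin`.
#' @export
watershed_grid <- function(landuse, stream, subwatershed = 1, cell_size = NULL) {
  geom <- function(m) c(nrow(m), ncol(m),
                        attr(m, "cellsize") %||% NA_real_,
                        attr(m, "xllcorner") %||% NA_real_,
                        attr(m, "yllcorner") %||% NA_real_)
  layers <- list(landuse = landuse, stream = stream)
  if (is.matrix(subwatershed)) layers$subwatershed <- subwatershed
  g0 <- geom(layers[[1]])
  for (nm in names(layers)[-1]) {
    g <- geom(layers[[nm]])
    same <- (g == g0) | is.na(g) | is.na(g0)  # absent attrs are unconstrained
    if (!all(same))
      stop_swrisk(sprintf("layer '%s' geometry differs from 'landuse'", nm),
                  "swrisk_geometry_error")
  }
  cell_size <- cell_size %||% attr(landuse, "cellsize")
  if (is.null(cell_size) || is.na(cell_size) || cell_size <= 0)
    stop_swrisk("cell_size must be a positive length in metres",
                "swrisk_geometry_error")
  if (!is.matrix(subwatershed))
    subwatershed <- matrix(subwatershed, nrow(landuse), ncol(landuse))
  stream_m <- matrix(as.logical(stream), nrow(stream), ncol(stream))
  stream_m[is.na(stream_m)] <- FALSE
  structure(list(landuse = unclass_matrix(landuse), stream = stream_m,
                 subwatershed = unclass_matrix(subwatershed),
                 cell_size = as.numeric(cell_size),
                 origin = c(attr(landuse, "xllcorner") %||% 0,
                            attr(landuse, "yllcorner") %||% 0)),
            class = "watershed_grid")
}

unclass_matrix <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

#' @export
print.watershed_grid <- function(x, ...) {
  cat(sprintf("watershed_grid: %d x %d cells of %g m (%.3f km^2), %d stream cells, %d sub-watershed(s)\n",
              nrow(x$landuse), ncol(x$landuse), x$cell_size,
              length(x$landuse) * x$cell_size^2 / 1e6, sum(x$stream),
              length(setdiff(unique(as.vector(x$subwatershed)), c(0, NA)))))
  invisible(x)
}

#' Euclidean distance to the nearest stream cell
#'
#' For every cell, the distance (cell-centre to cell-centre, in metres)
#' to the nearest cell of the stream mask; stream cells get 0. Computed with
#' an exact Euclidean distance transform ([EBImage::distmap()]) scaled by the
#' cell size.
#'
#' @param grid a `watershed_grid`.
#' @return matrix of distances in metres, same shape as the grid.
#' @export
distance_to_stream <- function(grid) {
  stopifnot(inherits(grid, "watershed_grid"))
  if (!any(grid$stream))
    stop_swrisk("grid has no stream cells", "swrisk_domain_error")
  # distmap measures each pixel's distance to the nearest zero pixel
  d <- EBImage::distmap(1 - grid$stream, metric = "euclidean")
  matrix(as.numeric(d), nrow(grid$stream), ncol(grid$stream)) * grid$cell_size
}

#' Buffer zone of a distance to water
#'
#' Bins distances into the four riparian buffer zones. Bins are closed on
#' the upper edge: \[0, 50\], (50, 250\], (250, 1000\], (1000, Inf). The
#' published zone labels overlap at the shared endpoints; upper-inclusive is
#' fixed here as the documented convention.
#'
#' @param distance distances in metres, non-negative.
#' @return ordered factor with levels `r paste0('"', c("0-50 m", "50-250 m",
#'   "250-1000 m", ">1000 m"), '"', collapse = ", ")`.
#' @export
#' @examples
#' zone_of(c(0, 50, 50.001, 1200))
zone_of <- function(distance) {
  if (any(distance < 0, na.rm = TRUE))
    stop_swrisk("distance must be non-negative", "swrisk_domain_error")
  cut(distance, breaks = c(-0.5, .zone_breaks[-1]), labels = .zone_labels,
      ordered_result = TRUE)
}

#' Tabulate activity areas per buffer zone per sub-watershed
#'
#' Counts cells of one activity class inside each buffer zone of each
#' sub-watershed and converts counts to areas (`cells * cell_size^2`).
#' NODATA land-use cells are excluded from both activity and sub-watershed
#' areas. A class absent from a sub-watershed yields four zero-area rows, so
#' conservation (zone areas sum to the class total) holds trivially.
#'
#' @param grid a `watershed_grid`.
#' @param activity_class integer class code to tabulate.
#' @param distances optional precomputed [distance_to_stream()] matrix.
#' @return a `zone_exposure` data frame: `subwatershed`, `activity_class`,
#'   `zone`, `activity_area_m2`, `subwatershed_area_m2`.
#' @export
tabulate_zone_areas <- function(grid, activity_class, distances = NULL) {
  stopifnot(inherits(grid, "watershed_grid"))
  distances <- distances %||% distance_to_stream(grid)
  zones <- zone_of(as.vector(distances))
  lu <- as.vector(grid$landuse)
  sw <- as.vector(grid$subwatershed)
  keep <- !is.na(lu) & !is.na(sw) & sw != 0
  ids <- sort(unique(sw[keep]))
  cell_area <- grid$cell_size^2
  rows <- lapply(ids, function(id) {
    in_sw <- keep & sw == id
    hit <- in_sw & lu == activity_class
    counts <- table(factor(zones[hit], levels = .zone_labels))
    data.frame(subwatershed = id, activity_class = activity_class,
               zone = .zone_labels,
               activity_area_m2 = as.numeric(counts) * cell_area,
               subwatershed_area_m2 = sum(in_sw) * cell_area)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("zone_exposure", "data.frame")
  out
}

#' Construct a zone-exposure table from pre-tabulated areas
#'
#' Bypass for the raster path: published or GIS-derived zone areas (m^2) can
#' be fed straight to the qualitative assessment.
#'
#' @param subwatershed sub-watershed id.
#' @param activity_class class code or activity name.
#' @param zone_areas_m2 numeric vector of four areas, ordered from the 0-50 m
#'   zone outwards.
#' @param subwatershed_area_m2 total sub-watershed area (m^2, > 0).
#' @return a `zone_exposure` data frame.
#' @export
#' @examples
#' zone_exposure("A002", "tea", c(71267, 374034, 810881, 450905), 12012334)
zone_exposure <- function(subwatershed, activity_class, zone_areas_m2,
                          subwatershed_area_m2) {
  stopifnot(length(zone_areas_m2) == 4)
  if (subwatershed_area_m2 <= 0)
    stop_swrisk("subwatershed_area_m2 must be positive", "swrisk_domain_error")
  if (any(zone_areas_m2 < 0) || sum(zone_areas_m2) > subwatershed_area_m2)
    stop_swrisk("zone areas must be non-negative and sum to at most the sub-watershed area",
                "swrisk_domain_error")
  out <- data.frame(subwatershed = subwatershed, activity_class = activity_class,
                    zone = .zone_labels, activity_area_m2 = zone_areas_m2,
                    subwatershed_area_m2 = subwatershed_area_m2)
  class(out) <- c("zone_exposure", "data.frame")
  out
}

#' Read / write zone-exposure CSVs
#'
#' Columns: `subwatershed`, `activity_class`, `zone`, `activity_area_m2`,
#' `subwatershed_area_m2`.
#'
#' @param path file path.
#' @rdname zone_exposure_io
#' @export
read_zone_areas <- function(path) {
  df <- utils::read.csv(path, colClasses = c(subwatershed = "character"))
  stopifnot(all(c("subwatershed", "activity_class", "zone", "activity_area_m2",
                  "subwatershed_area_m2") %in% names(df)))
  class(df) <- c("zone_exposure", "data.frame")
  df
}

#' @param exposures a `zone_exposure` data frame.
#' @rdname zone_exposure_io
#' @export
write_zone_areas <- function(exposures, path) {
  utils::write.csv(as.data.frame(exposures), path, row.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Plain-text `.asc` raster: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`) followed by
#' rows of values, top row first. NODATA cells become `NA`. Integer layers
#' round-trip losslessly through [write_ascii_grid()].
#'
#' @param path `.asc` file path.
#' @return numeric matrix with attributes `xllcorner`, `yllcorner`,
#'   `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]]))
      stop_swrisk(paste("ASCII grid header missing", k), "swrisk_io_error")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop_swrisk("ASCII grid value count does not match header dimensions",
                "swrisk_io_error")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  attr(m, "xllcorner") <- hdr$xllcorner
  attr(m, "yllcorner") <- hdr$yllcorner
  attr(m, "cellsize") <- hdr$cellsize
  attr(m, "nodata") <- hdr$nodata_value %||% -9999
  m
}

#' Write an ESRI ASCII grid
#'
#' @param layer numeric matrix, optionally carrying the geometry attributes
#'   set by [read_ascii_grid()].
#' @param path output path.
#' @param xllcorner,yllcorner,cellsize grid geometry (defaults: attributes of
#'   `layer`, else 0/0/1).
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(layer, path,
                             xllcorner = attr(layer, "xllcorner") %||% 0,
                             yllcorner = attr(layer, "yllcorner") %||% 0,
                             cellsize = attr(layer, "cellsize") %||% 1,
                             nodata = attr(layer, "nodata") %||% -9999) {
  m <- layer
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", xllcorner),
           sprintf("yllcorner %.10g", yllcorner),
           sprintf("cellsize %.10g", cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Plot distance-to-stream bands of a watershed grid
#'
#' Quick-look image of the four buffer zones with stream cells overlaid.
#'
#' @param x a `watershed_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.watershed_grid <- function(x, ...) {
  z <- matrix(as.integer(zone_of(distance_to_stream(x))),
              nrow(x$stream), ncol(x$stream))
  z[x$stream] <- 0L
  graphics::image(t(z)[, nrow(z):1],
                  col = c("#2166ac", "#b2182b", "#ef8a62", "#fddbc7", "#f7f7f7"),
                  axes = FALSE, ...)
  invisible(x)
}
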