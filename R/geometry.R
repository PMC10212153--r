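# Exact planar geometry for infrastructure covariates, plus GeoJSON line IO
# and the local equirectangular projection used to move between geographic
# degrees and planar meters.
#
# Line layers are represented as lists of polylines, each an n x 2 numeric
# matrix of vertices (columns x, y in meters, or lon, lat in degrees before
# projection).

EARTH_RADIUS_M <- 6371008.8  # mean Earth radius

#' Local equirectangular projection
#'
#' Projects geographic degrees to planar meters (and back) in a local frame
#' anchored at a reference point; exact inverse of itself at any distance,
#' adequate for study extents of tens of kilometers.
#'
#' @param lat,lon degrees.
#' @param ref_lat,ref_lon anchor in degrees.
#' @return `local_project`: data frame with `x`, `y` meters.
#' @export
local_project <- function(lat, lon, ref_lat, ref_lon) {
  k <- pi / 180 * EARTH_RADIUS_M
  data.frame(x = (lon - ref_lon) * k * cos(ref_lat * pi / 180),
             y = (lat - ref_lat) * k)
}

#' @rdname local_project
#' @param x,y planar meters.
#' @return `local_unproject`: data frame with `lat`, `lon` degrees.
#' @export
local_unproject <- function(x, y, ref_lat, ref_lon) {
  k <- pi / 180 * EARTH_RADIUS_M
  data.frame(lat = ref_lat + y / k,
             lon = ref_lon + x / (k * cos(ref_lat * pi / 180)))
}

# total length of one polyline's segments clipped to the closed disk
# centered at (cx, cy) with radius r; exact segment-circle intersection
polyline_length_in_disk <- function(line, cx, cy, r) {
  if (is.null(dim(line)) || nrow(line) < 2L) return(0)
  ax <- line[-nrow(line), 1]; ay <- line[-nrow(line), 2]
  bx <- line[-1L, 1];         by <- line[-1L, 2]
  dx <- bx - ax; dy <- by - ay
  L2 <- dx^2 + dy^2
  fx <- ax - cx; fy <- ay - cy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx^2 + fy^2 - r^2
  disc <- b^2 - 4 * L2 * cc
  ok <- L2 > 0 & disc > 0
  len <- numeric(length(L2))
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax((-b[ok] - sq) / (2 * L2[ok]), 0)
    t2 <- pmin((-b[ok] + sq) / (2 * L2[ok]), 1)
    len[ok] <- pmax(t2 - t1, 0) * sqrt(L2[ok])
  }
  sum(len)
}

#' Line density within a circular buffer
#'
#' Total length of line features clipped to the closed disk of radius
#' `radius_m` around a station, divided by the disk area (m/m^2), via exact
#' segment-circle intersection. This is the recreation-trail / road density
#' predictor evaluated in a 500 m buffer.
#'
#' @param lines list of polylines (n x 2 matrices, planar meters); an empty
#'   list gives density 0.
#' @param x,y station coordinates in meters (vectors allowed).
#' @param radius_m buffer radius, default 500.
#' @return numeric vector of densities, one per station.
#' @export
line_density_in_buffer <- function(lines, x, y, radius_m = 500) {
  stopifnot(radius_m > 0, length(x) == length(y))
  area <- pi * radius_m^2
  vapply(seq_along(x), function(i) {
    sum(vapply(lines, polyline_length_in_disk, 0, cx = x[i], cy = y[i],
               r = radius_m)) / area
  }, 0)
}

#' Minimum distance from stations to a boundary line layer
#'
#' Euclidean point-to-segment distance, minimized over every segment of every
#' boundary polyline (the urban-wildland boundary predictor).
#'
#' @param x,y station coordinates in meters.
#' @param boundary_lines non-empty list of polylines (n x 2 matrices).
#' @return numeric vector of distances in meters.
#' @export
distance_to_boundary <- function(x, y, boundary_lines) {
  if (length(boundary_lines) == 0L) {
    stop("distance_to_boundary: empty boundary geometry")
  }
  segs <- do.call(rbind, lapply(boundary_lines, function(line) {
    if (is.null(dim(line)) || nrow(line) < 2L) {
      return(cbind(line[1], line[2], line[1], line[2]))
    }
    cbind(line[-nrow(line), 1], line[-nrow(line), 2],
          line[-1L, 1], line[-1L, 2])
  }))
  ax <- segs[, 1]; ay <- segs[, 2]
  dx <- segs[, 3] - ax; dy <- segs[, 4] - ay
  L2 <- dx^2 + dy^2
  vapply(seq_along(x), function(i) {
    t <- ifelse(L2 > 0, ((x[i] - ax) * dx + (y[i] - ay) * dy) / L2, 0)
    t <- pmin(pmax(t, 0), 1)
    min(sqrt((x[i] - (ax + t * dx))^2 + (y[i] - (ay + t * dy))^2))
  }, 0)
}

#' Read line geometries from GeoJSON
#'
#' Reads `LineString` and `MultiLineString` features (a bare geometry, a
#' Feature, a FeatureCollection, or a GeometryCollection) into a list of
#' vertex matrices with columns (lon, lat) — or (x, y) if the file was
#' written from planar coordinates.
#'
#' @param path GeoJSON file.
#' @return list of n x 2 matrices.
#' @export
read_lines_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  grab <- function(geom) {
    if (is.null(geom)) return()
    ty <- geom$type
    if (identical(ty, "LineString")) {
      out[[length(out) + 1L]] <<-
        do.call(rbind, lapply(geom$coordinates,
                              function(p) c(p[[1]], p[[2]])))
    } else if (identical(ty, "MultiLineString")) {
      for (ls in geom$coordinates) {
        out[[length(out) + 1L]] <<-
          do.call(rbind, lapply(ls, function(p) c(p[[1]], p[[2]])))
      }
    } else if (identical(ty, "GeometryCollection")) {
      for (gg in geom$geometries) grab(gg)
    }
  }
  ty <- g$type
  if (identical(ty, "FeatureCollection")) {
    for (f in g$features) grab(f$geometry)
  } else if (identical(ty, "Feature")) {
    grab(g$geometry)
  } else {
    grab(g)
  }
  out
}

#' Write line geometries to GeoJSON
#'
#' @param lines list of n x 2 matrices, columns (lon, lat).
#' @param path output file.
#' @export
write_lines_geojson <- function(lines, path) {
  feats <- lapply(lines, function(line) {
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(
           type = "LineString",
           coordinates = lapply(seq_len(nrow(line)),
                                function(i) as.numeric(line[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# project a list of lon/lat polylines into planar meters
project_lines <- function(lines, ref_lat, ref_lon) {
  lapply(lines, function(line) {
    p <- local_project(line[, 2], line[, 1], ref_lat, ref_lon)
    cbind(p$x, p$y)
  })
}

# inverse: planar meters -> lon/lat polylines (for GeoJSON export)
unproject_lines <- function(lines, ref_lat, ref_lon) {
  lapply(lines, function(line) {
    p <- local_unproject(line[, 1], line[, 2], ref_lat, ref_lon)
    cbind(p$lon, p$lat)
  })
}
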