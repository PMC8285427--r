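#' Spatial units with adjacency and populations
#'
#' A `region_map` holds the spatial units the model operates on: ids,
#' at-risk populations, a symmetric adjacency structure, the original units
#' each region is composed of (regions start as single units and grow by
#' merging), and optionally polygons and areas.
#'
#' @param ids character vector of unique region ids.
#' @param population numeric vector of nonnegative populations, one per id.
#' @param adjacency named list (by id) of character vectors of neighbour
#'   ids, or a 2-column matrix/data.frame of undirected edges; symmetrized.
#' @param polygons optional named list of 2-column coordinate matrices
#'   (closed or open rings), one per id.
#' @param area optional numeric vector of region areas; computed from
#'   polygons (shoelace formula) when absent and polygons are given.
#' @param members optional named list mapping each region id to the original
#'   unit ids it contains; defaults to each region containing itself.
#' @return an object of class `region_map`.
#' @export
region_map <- function(ids, population, adjacency, polygons = NULL,
                       area = NULL, members = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated region ids")
  if (length(population) != length(ids)) stop("population/id length mismatch")
  population <- as.numeric(population)
  if (any(!is.finite(population)) || any(population < 0)) {
    stop("populations must be finite and nonnegative")
  }
  adj <- normalize_adjacency(adjacency, ids)
  if (is.null(members)) members <- stats::setNames(as.list(ids), ids)
  if (!is.null(polygons)) {
    polygons <- polygons[ids]
    if (is.null(area)) area <- vapply(polygons, polygon_area, numeric(1))
  }
  structure(list(ids = ids,
                 population = stats::setNames(population, ids),
                 adjacency = adj,
                 polygons = polygons,
                 area = if (is.null(area)) NULL else stats::setNames(as.numeric(area), ids),
                 members = members),
            class = "region_map")
}

# Accept edge matrix/data.frame or adjacency list; return symmetric,
# irreflexive named list covering every id.
normalize_adjacency <- function(adjacency, ids) {
  adj <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  if (is.matrix(adjacency) || is.data.frame(adjacency)) {
    if (ncol(adjacency) != 2L) stop("edge list must have 2 columns")
    if (is.data.frame(adjacency)) {
      a <- as.character(adjacency[[1L]]); b <- as.character(adjacency[[2L]])
    } else {
      a <- as.character(adjacency[, 1L]); b <- as.character(adjacency[, 2L])
    }
    bad <- setdiff(unique(c(a, b)), ids)
    if (length(bad)) stop("edge list references unknown ids: ",
                          paste(bad, collapse = ", "))
    for (k in seq_along(a)) {
      if (a[k] == b[k]) next
      adj[[a[k]]] <- union(adj[[a[k]]], b[k])
      adj[[b[k]]] <- union(adj[[b[k]]], a[k])
    }
  } else if (is.list(adjacency)) {
    bad <- setdiff(names(adjacency), ids)
    if (length(bad)) stop("adjacency references unknown ids: ",
                          paste(bad, collapse = ", "))
    for (id in names(adjacency)) {
      nb <- setdiff(as.character(adjacency[[id]]), id)
      bad <- setdiff(nb, ids)
      if (length(bad)) stop("adjacency references unknown ids: ",
                            paste(bad, collapse = ", "))
      for (j in nb) {
        adj[[id]] <- union(adj[[id]], j)
        adj[[j]] <- union(adj[[j]], id)
      }
    }
  } else stop("adjacency must be an edge matrix/data.frame or a list")
  lapply(adj, sort)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.region_map <- function(x, ...) {
  ne <- sum(lengths(x$adjacency)) / 2
  cat("region_map:", length(x$ids), "regions,", ne, "adjacencies\n")
  cat("  total population:", format(sum(x$population), big.mark = ","), "\n")
  iso <- sum(lengths(x$adjacency) == 0)
  if (iso) cat("  isolated regions:", iso, "\n")
  invisible(x)
}

#' Number of regions in a map
#' @param map a `region_map`.
#' @export
n_regions <- function(map) length(map$ids)

#' Read a region map from geometry or an edge list plus populations
#'
#' Builds a `region_map` either from a GeoJSON FeatureCollection of polygons
#' (adjacency derived by queen contiguity: any shared boundary point,
#' corners included) or from an explicit undirected edge-list CSV with
#' columns `id_a,id_b`. Populations come from a table with columns
#' `region_id, population` (optional `area`). Units present in the geometry
#' but missing from the population table (or with missing population) are
#' dropped with a message, mirroring the exclusion of units without a census
#' population count; a population-table id absent from the geometry is an
#' error.
#'
#' @param geometry_file path to a GeoJSON FeatureCollection whose features
#'   carry a `region_id` property, or `NULL`.
#' @param adjacency_file path to an edge-list CSV (`id_a,id_b`), used when
#'   `geometry_file` is `NULL`.
#' @param population_table data.frame with `region_id` and `population`
#'   columns (optional `area`), or path to such a CSV.
#' @return a `region_map`.
#' @export
read_region_map <- function(geometry_file = NULL, adjacency_file = NULL,
                            population_table) {
  if (is.character(population_table)) {
    population_table <- utils::read.csv(population_table,
                                        stringsAsFactors = FALSE)
  }
  if (!all(c("region_id", "population") %in% names(population_table))) {
    stop("population table needs region_id and population columns")
  }
  pt_ids <- as.character(population_table$region_id)
  if (anyDuplicated(pt_ids)) stop("duplicated region ids in population table")

  if (!is.null(geometry_file)) {
    gj <- jsonlite::fromJSON(geometry_file, simplifyVector = FALSE)
    if (is.null(gj$features)) stop("GeoJSON must be a FeatureCollection")
    polys <- list()
    for (f in gj$features) {
      id <- as.character(f$properties$region_id)
      if (!nzchar(id)) stop("feature without region_id property")
      coords <- f$geometry$coordinates
      if (identical(f$geometry$type, "Polygon")) {
        ring <- coords[[1L]]
      } else if (identical(f$geometry$type, "MultiPolygon")) {
        ring <- coords[[1L]][[1L]]
      } else stop("unsupported geometry type: ", f$geometry$type)
      polys[[id]] <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    }
    geo_ids <- names(polys)
    adj_mat <- queen_adjacency(polys)
    adjacency <- stats::setNames(
      lapply(seq_along(geo_ids),
             function(i) geo_ids[which(adj_mat[i, ])]), geo_ids)
  } else if (!is.null(adjacency_file)) {
    edges <- utils::read.csv(adjacency_file, stringsAsFactors = FALSE)
    if (!all(c("id_a", "id_b") %in% names(edges))) {
      stop("edge list needs id_a and id_b columns")
    }
    geo_ids <- sort(unique(c(as.character(edges$id_a),
                             as.character(edges$id_b))))
    adjacency <- edges[, c("id_a", "id_b")]
    polys <- NULL
  } else stop("provide geometry_file or adjacency_file")

  unknown <- setdiff(pt_ids, geo_ids)
  if (length(unknown)) {
    stop("population table lists regions absent from geometry: ",
         paste(unknown, collapse = ", "))
  }
  pop <- stats::setNames(as.numeric(population_table$population), pt_ids)
  no_pop <- setdiff(geo_ids, pt_ids[!is.na(pop)])
  if (length(no_pop)) {
    message("dropping ", length(no_pop),
            " region(s) without a population count: ",
            paste(no_pop, collapse = ", "))
    geo_ids <- setdiff(geo_ids, no_pop)
    if (is.list(adjacency)) {
      adjacency <- lapply(adjacency[geo_ids], intersect, geo_ids)
    } else {
      keep <- adjacency$id_a %in% geo_ids & adjacency$id_b %in% geo_ids
      adjacency <- adjacency[keep, , drop = FALSE]
    }
    if (!is.null(polys)) polys <- polys[geo_ids]
  }
  area <- NULL
  if ("area" %in% names(population_table)) {
    area <- stats::setNames(as.numeric(population_table$area), pt_ids)[geo_ids]
  }
  map <- region_map(geo_ids, pop[geo_ids], adjacency, polygons = polys,
                    area = area)
  iso <- map$ids[lengths(map$adjacency) == 0]
  if (length(iso)) {
    warning("isolated region(s) retained: ", paste(iso, collapse = ", "))
  }
  map
}

## --- minimal planar geometry -------------------------------------------
## No spatial geometry package is assumed; these routines only need to
## handle the simple (non-self-intersecting) rings used for region
## boundaries and lattice cells.

polygon_area <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1L] - x[-1L] * y[-n])) / 2
}

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!all(ring[1L, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1L, ])
  ring
}

# TRUE when segments p1-p2 and p3-p4 intersect, endpoints and collinear
# overlap included (queen contiguity counts a corner touch).
segments_intersect <- function(p1, p2, p3, p4, eps = 1e-9) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < eps) 0 else sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - eps <= c[1] && c[1] <= max(a[1], b[1]) + eps &&
      min(a[2], b[2]) - eps <= c[2] && c[2] <= max(a[2], b[2]) + eps
  }
  d1 <- orient(p3, p4, p1); d2 <- orient(p3, p4, p2)
  d3 <- orient(p1, p2, p3); d4 <- orient(p1, p2, p4)
  if (d1 != d2 && d3 != d4) return(TRUE)
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# Queen contiguity matrix for a named list of rings: polygons are adjacent
# when their boundaries share at least one point (edge or corner).
queen_adjacency <- function(polys) {
  n <- length(polys)
  rings <- lapply(polys, close_ring)
  bbox <- t(vapply(rings, function(r) {
    c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2]))
  }, numeric(4)))
  adj <- matrix(FALSE, n, n)
  eps <- 1e-9
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (bbox[i, 1] > bbox[j, 2] + eps || bbox[j, 1] > bbox[i, 2] + eps ||
          bbox[i, 3] > bbox[j, 4] + eps || bbox[j, 3] > bbox[i, 4] + eps) next
      if (rings_touch(rings[[i]], rings[[j]], eps)) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  adj
}

rings_touch <- function(ra, rb, eps = 1e-9) {
  na <- nrow(ra) - 1L; nb <- nrow(rb) - 1L
  for (a in seq_len(na)) {
    for (b in seq_len(nb)) {
      if (segments_intersect(ra[a, ], ra[a + 1L, ], rb[b, ], rb[b + 1L, ], eps)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Ray-casting point-in-polygon; points on the boundary count as inside.
point_in_polygon <- function(pt, ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  x <- pt[1]; y <- pt[2]
  inside <- FALSE
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1L, 1]; y2 <- ring[k + 1L, 2]
    # boundary check
    if (segments_intersect(c(x1, y1), c(x2, y2), pt, pt)) return(TRUE)
    if ((y1 > y) != (y2 > y)) {
      xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      if (x < xint) inside <- !inside
    }
  }
  inside
}

polygon_centroid <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- nrow(ring)
  cr <- x[-n] * y[-1L] - x[-1L] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x[-n]), mean(y[-n])))
  c(sum((x[-n] + x[-1L]) * cr) / (6 * a),
    sum((y[-n] + y[-1L]) * cr) / (6 * a))
}
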