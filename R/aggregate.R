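#' One step of population-driven region merging
#'
#' Implements the greedy rule used to build analysis regions from small
#' spatial units: select the region with the smallest population, identify
#' its neighbours (regions sharing at least one boundary point), and merge
#' it with the neighbour that itself has the smallest population. The merged
#' region's population is the sum, its member set is the union, and its
#' neighbourhood is the union of both neighbourhoods minus the pair.
#' Population ties are broken by lexicographic region id, both for the seed
#' region and the neighbour. The merged region keeps the lexicographically
#' smaller of the two ids.
#'
#' @param map a `region_map` with at least two regions.
#' @return list with elements `map` (the reduced map) and `event` (a one-row
#'   data.frame recording seed id, absorbed id, populations before, and the
#'   combined population).
#' @export
merge_step <- function(map) {
  stopifnot(inherits(map, "region_map"))
  if (length(map$ids) < 2L) stop("need at least 2 regions to merge")
  pop <- map$population
  ord <- order(pop, names(pop))
  seed_id <- names(pop)[ord[1L]]
  nb <- map$adjacency[[seed_id]]
  if (!length(nb)) stop("isolated region; cannot merge: ", seed_id)
  nb_pop <- pop[nb]
  other_id <- nb[order(nb_pop, nb)][1L]

  new_id <- min(seed_id, other_id)
  drop_id <- max(seed_id, other_id)
  new_pop <- unname(pop[seed_id] + pop[other_id])
  new_nb <- sort(setdiff(union(map$adjacency[[seed_id]],
                               map$adjacency[[other_id]]),
                         c(seed_id, other_id)))

  ids <- setdiff(map$ids, drop_id)
  population <- map$population[ids]
  population[new_id] <- new_pop
  adjacency <- map$adjacency[ids]
  adjacency[[new_id]] <- new_nb
  # rewire neighbours of the dropped id to the kept id
  for (j in ids) {
    if (j == new_id) next
    a <- adjacency[[j]]
    if (drop_id %in% a || (new_id %in% a)) {
      a <- setdiff(a, drop_id)
      if (j %in% new_nb) a <- union(a, new_id)
      adjacency[[j]] <- sort(a)
    }
  }
  members <- map$members[ids]
  members[[new_id]] <- c(map$members[[seed_id]], map$members[[other_id]])
  area <- if (is.null(map$area)) NULL else {
    ar <- map$area[ids]
    ar[new_id] <- map$area[[seed_id]] + map$area[[other_id]]
    ar
  }
  polygons <- if (is.null(map$polygons)) NULL else {
    # polygon dissolve is not needed downstream; keep the seed's ring as a
    # representative and rely on `members` for exact composition
    p <- map$polygons[ids]
    p[[new_id]] <- map$polygons[[new_id]] %||% map$polygons[[seed_id]]
    p
  }
  out <- structure(list(ids = ids,
                        population = population,
                        adjacency = adjacency,
                        polygons = polygons,
                        area = area,
                        members = members),
                   class = "region_map")
  event <- data.frame(seed_id = seed_id,
                      seed_population = unname(pop[seed_id]),
                      absorbed_id = other_id,
                      absorbed_population = unname(pop[other_id]),
                      new_id = new_id,
                      combined_population = new_pop,
                      stringsAsFactors = FALSE)
  list(map = out, event = event)
}

#' Aggregate spatial units into a target number of regions
#'
#' Repeats [merge_step()] until exactly `n_target` regions remain, recording
#' every merge. Mirrors the data-driven strategy that collapsed postal
#' geography units into 100 analysis regions to achieve sufficient case
#' density.
#'
#' @param map a `region_map`.
#' @param n_target number of regions to stop at (>= 1).
#' @return list with `map` (aggregated), `trace` (data.frame of merge
#'   events, one row per step, `n_initial - n_target` rows) and `mapping`
#'   (data.frame unit_id -> region_id for every original unit).
#' @export
aggregate_regions <- function(map, n_target) {
  stopifnot(inherits(map, "region_map"))
  n_target <- as.integer(n_target)
  if (n_target < 1L) stop("n_target must be >= 1")
  if (n_target > length(map$ids)) {
    stop("n_target (", n_target, ") exceeds current region count (",
         length(map$ids), ")")
  }
  events <- vector("list", length(map$ids) - n_target)
  step <- 0L
  while (length(map$ids) > n_target) {
    step <- step + 1L
    res <- merge_step(map)
    map <- res$map
    events[[step]] <- res$event
  }
  trace <- if (step) cbind(step = seq_len(step), do.call(rbind, events))
           else data.frame(step = integer(0))
  mapping <- data.frame(
    unit_id = unlist(map$members, use.names = FALSE),
    region_id = rep(names(map$members), lengths(map$members)),
    stringsAsFactors = FALSE)
  list(map = map, trace = trace, mapping = mapping)
}

#' Exclude regions below a population-density threshold
#'
#' Removes regions whose population density (population / area) is below
#' `threshold` before aggregation, mirroring the exclusion of very sparsely
#' populated northern regions. Removals are reported via `message()`.
#'
#' @param map a `region_map` with areas available.
#' @param threshold nonnegative density threshold; regions with density
#'   strictly below it are dropped.
#' @return the reduced `region_map`.
#' @export
exclude_low_density <- function(map, threshold) {
  stopifnot(inherits(map, "region_map"))
  if (threshold < 0) stop("threshold must be >= 0")
  if (is.null(map$area)) stop("region areas are required to compute density")
  density <- map$population / map$area
  drop <- map$ids[density < threshold]
  if (!length(drop)) return(map)
  message("excluding ", length(drop), " low-density region(s): ",
          paste(drop, collapse = ", "))
  keep <- setdiff(map$ids, drop)
  structure(list(ids = keep,
                 population = map$population[keep],
                 adjacency = lapply(map$adjacency[keep], intersect, keep),
                 polygons = if (is.null(map$polygons)) NULL else map$polygons[keep],
                 area = map$area[keep],
                 members = map$members[keep]),
            class = "region_map")
}
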