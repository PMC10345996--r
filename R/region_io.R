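#' Study region: areas, centroids and adjacency
#'
#' A `study_region` holds the ordered area identifiers, one planar centroid
#' per area (used directly as the two covariates of the spatial smooth), and
#' the symmetric neighbourhood relation from which the intrinsic spatial
#' precision matrix is built. Areas are kept in lexicographic order of their
#' identifiers so that every downstream matrix uses one canonical indexing.
#'
#' @param area_ids character vector of unique area identifiers.
#' @param centroids numeric matrix or data.frame with one row per area and
#'   two columns (longitude `x1`, latitude `x2`), in planar or geographic
#'   units; values are used as raw covariates.
#' @param adjacency two-column character matrix (or data.frame) of unordered
#'   neighbour pairs; may be `NULL` for a region without adjacency (spatial
#'   interaction structures then require it to be added later).
#' @return An object of class `study_region` with elements `area_ids`,
#'   `centroids` (I x 2 matrix, rownames = area ids) and `adjacency`
#'   (matrix of id pairs, each pair stored once with ids sorted).
#' @export
study_region <- function(area_ids, centroids, adjacency = NULL) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) stop("duplicate area ids")
  ord <- order(area_ids)
  area_ids <- area_ids[ord]
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != length(area_ids) || ncol(centroids) != 2)
    stop("centroids must be an I x 2 matrix")
  storage.mode(centroids) <- "double"
  if (!all(is.finite(centroids))) stop("centroids must be finite")
  centroids <- centroids[ord, , drop = FALSE]
  rownames(centroids) <- area_ids
  colnames(centroids) <- c("x1", "x2")
  adjacency <- canonical_pairs(adjacency, area_ids)
  structure(list(area_ids = area_ids, centroids = centroids,
                 adjacency = adjacency),
            class = "study_region")
}

# Deduplicate, sort within pair, drop self pairs, validate ids.
canonical_pairs <- function(adjacency, area_ids) {
  if (is.null(adjacency) || NROW(adjacency) == 0)
    return(matrix(character(0), 0, 2))
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2) stop("adjacency must have two columns")
  mode(adjacency) <- "character"
  unknown <- setdiff(unique(c(adjacency)), area_ids)
  if (length(unknown))
    stop("unknown area: ", paste(unknown, collapse = ", "))
  if (any(adjacency[, 1] == adjacency[, 2])) stop("self-adjacency not allowed")
  pairs <- t(apply(adjacency, 1, sort))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(pairs) <- NULL
  pairs
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf("study_region: %d areas, %d adjacency pairs\n",
              length(x$area_ids), nrow(x$adjacency)))
  invisible(x)
}

#' Panel of observed counts and populations
#'
#' Validates and stores a complete (area, time, outcome) grid of observed
#' counts together with the population at risk per (area, time). The
#' canonical vectorization order used by every matrix in the package is
#' area fastest, then time, then outcome, matching the stacking of the
#' outcome-wise coefficient and risk vectors.
#'
#' @param df data.frame with columns `area_id`, `time`, `outcome`, `count`,
#'   `population`.
#' @return An object of class `panel_counts` with `I`, `T`, `J`, ordered
#'   `area_ids`, numeric `times`, `outcome_ids`, count array `O` (I x T x J)
#'   and population matrix `n` (I x T).
#' @export
panel_counts <- function(df) {
  need <- c("area_id", "time", "outcome", "count", "population")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df$area_id <- as.character(df$area_id)
  df$outcome <- as.character(df$outcome)
  df$time <- as.numeric(df$time)
  area_ids <- sort(unique(df$area_id))
  times <- sort(unique(df$time))
  outcome_ids <- sort(unique(df$outcome))
  I <- length(area_ids); T <- length(times); J <- length(outcome_ids)
  key <- paste(df$area_id, df$time, df$outcome, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate record")
  if (nrow(df) != I * T * J) stop("incomplete panel")
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("invalid value: counts must be non-negative integers")
  if (any(df$population <= 0))
    stop("invalid value: populations must be strictly positive")
  ii <- match(df$area_id, area_ids)
  tt <- match(df$time, times)
  jj <- match(df$outcome, outcome_ids)
  O <- array(NA_real_, c(I, T, J),
             dimnames = list(area_ids, times, outcome_ids))
  O[cbind(ii, tt, jj)] <- df$count
  n <- matrix(NA_real_, I, T, dimnames = list(area_ids, times))
  n[cbind(ii, tt)] <- df$population
  # populations must agree across outcomes for the same (i, t)
  chk <- df$population - n[cbind(ii, tt)]
  if (any(chk != 0)) stop("invalid value: population differs across outcomes")
  structure(list(I = I, T = T, J = J, area_ids = area_ids, times = times,
                 outcome_ids = outcome_ids, O = O, n = n),
            class = "panel_counts")
}

#' @export
print.panel_counts <- function(x, ...) {
  cat(sprintf("panel_counts: I=%d areas x T=%d times x J=%d outcomes (%d cells)\n",
              x$I, x$T, x$J, x$I * x$T * x$J))
  invisible(x)
}

#' Linear cell index for the canonical (area, time, outcome) order
#'
#' @param i,t,j 1-based area, time and outcome indices (vectorized).
#' @param I,T number of areas and time points.
#' @return integer index into the stacked vector of length `I*T*J`.
#' @export
cell_index <- function(i, t, j, I, T) {
  as.integer(i + (t - 1L) * I + (j - 1L) * I * T)
}

#' Read a panel of counts from CSV
#'
#' Expects columns `area_id,time,outcome,count,population` and a complete
#' (area, time, outcome) grid. Rows are reordered canonically (area fastest,
#' then time, then outcome).
#'
#' @param path CSV file path.
#' @return A [panel_counts] object.
#' @export
read_panel_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel_counts(df)
}

#' Write a panel of counts to CSV in canonical order
#'
#' Inverse of [read_panel_counts()]; reading then writing a valid file is
#' idempotent (canonical row order, plain integer counts).
#'
#' @param panel a [panel_counts] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_counts <- function(panel, path) {
  g <- expand.grid(area_id = panel$area_ids, time = panel$times,
                   outcome = panel$outcome_ids,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$count <- as.integer(panel$O)
  g$population <- as.vector(panel$n)[rep(seq_len(panel$I * panel$T), panel$J)]
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an adjacency list into a study region
#'
#' One line per area, `id: id1 id2 ...`. Listings are symmetrized: if A
#' lists B but B does not list A the pair is kept and a warning is issued.
#'
#' @param path adjacency-list file path.
#' @param region a [study_region] whose `area_ids` validate the file.
#' @return `region` with the `adjacency` field replaced.
#' @export
read_adjacency <- function(path, region) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  listed <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    id <- trimws(parts[1])
    nbrs <- if (length(parts) > 1) strsplit(trimws(parts[2]), "[[:space:]]+")[[1]] else character(0)
    nbrs <- nbrs[nzchar(nbrs)]
    listed[[id]] <- union(listed[[id]] %||% character(0), nbrs)
  }
  unknown <- setdiff(c(names(listed), unlist(listed)), region$area_ids)
  if (length(unknown)) stop("unknown area: ", paste(unknown, collapse = ", "))
  pairs <- do.call(rbind, lapply(names(listed), function(id) {
    if (length(listed[[id]])) cbind(id, listed[[id]]) else NULL
  }))
  asym <- 0L
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (!(a %in% (listed[[b]] %||% character(0)))) asym <- asym + 1L
    }
  }
  if (asym > 0)
    warning(sprintf("adjacency list asymmetric for %d pair(s); symmetrized", asym))
  region$adjacency <- canonical_pairs(pairs, region$area_ids)
  region
}

#' Write an adjacency list
#'
#' @param region a [study_region].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(region, path) {
  nb <- neighbour_list(region)
  lines <- vapply(region$area_ids, function(id)
    paste0(id, ": ", paste(nb[[id]], collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

neighbour_list <- function(region) {
  nb <- stats::setNames(vector("list", length(region$area_ids)), region$area_ids)
  for (id in region$area_ids) nb[[id]] <- character(0)
  if (nrow(region$adjacency)) {
    for (r in seq_len(nrow(region$adjacency))) {
      a <- region$adjacency[r, 1]; b <- region$adjacency[r, 2]
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
  }
  lapply(nb, sort)
}

#' Connectivity report for a study region
#'
#' Counts connected components of the adjacency graph (the rank of the
#' intrinsic spatial precision is `I - components`) and lists isolated areas.
#'
#' @param region a [study_region].
#' @return list with `components` (count), `membership` (integer label per
#'   area) and `isolates` (ids with no neighbours).
#' @export
validate_region <- function(region) {
  ids <- region$area_ids
  I <- length(ids)
  nb <- neighbour_list(region)
  label <- stats::setNames(rep(NA_integer_, I), ids)
  comp <- 0L
  for (s in ids) {
    if (!is.na(label[s])) next
    comp <- comp + 1L
    queue <- s
    label[s] <- comp
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[v]]) if (is.na(label[w])) { label[w] <- comp; queue <- c(queue, w) }
    }
  }
  isolates <- ids[vapply(nb, length, 1L) == 0L]
  list(components = comp, membership = label, isolates = isolates)
}

#' Build a study region from GeoJSON polygons
#'
#' Minimal GeoJSON support: centroids are vertex means (a representative
#' point, not an area-weighted centroid) and queen adjacency connects
#' features sharing at least one vertex.
#'
#' @param path GeoJSON file with a `FeatureCollection` of (Multi)Polygons;
#'   the feature property named by `id_property` supplies area ids.
#' @param id_property property name holding the area identifier.
#' @return A [study_region].
#' @export
region_from_geojson <- function(path, id_property = "id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a FeatureCollection")
  ids <- character(0); cents <- NULL; verts <- list()
  for (ft in gj$features) {
    id <- as.character(ft$properties[[id_property]])
    if (!length(id)) stop("feature without id property '", id_property, "'")
    coords <- ft$geometry$coordinates
    rings <- switch(ft$geometry$type,
                    Polygon = coords,
                    MultiPolygon = unlist(coords, recursive = FALSE),
                    stop("unsupported geometry type: ", ft$geometry$type))
    pts <- do.call(rbind, lapply(rings, function(r)
      do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))))
    ids <- c(ids, id)
    cents <- rbind(cents, colMeans(pts))
    verts[[id]] <- unique(paste(signif(pts[, 1], 12), signif(pts[, 2], 12)))
  }
  pairs <- NULL
  for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
    if (length(intersect(verts[[ids[a]]], verts[[ids[b]]])))
      pairs <- rbind(pairs, c(ids[a], ids[b]))
  }
  study_region(ids, cents, pairs)
}
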