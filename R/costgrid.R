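#' Cost grids for least-cost marine distances
#'
#' A raster of water (conductance 1) and land (blocked) cells on which
#' shortest water paths are computed: the standard proxy for connectivity
#' between coastal sampling sites, where straight-line distance is
#' meaningless across land or breakwaters. Cell (1, 1) is the north-west
#' corner; rows run south, columns east.
#'
#' @param water logical matrix: TRUE = water, FALSE = land
#' @param cell_km cell edge length in km
#' @param sites optional data.frame `site`, `row`, `col` anchoring sites
#' @return an object of class `cost_grid`
#' @export
cost_grid <- function(water, cell_km, sites = NULL) {
  stopifnot(is.matrix(water), is.logical(water), cell_km > 0)
  if (!any(water)) stop("cost grid needs at least one water cell")
  structure(list(water = water, cell_km = cell_km, sites = sites),
            class = "cost_grid")
}

#' @export
print.cost_grid <- function(x, ...) {
  cat(sprintf("<cost_grid> %d x %d cells (%.2f km), %.0f%% water\n",
              nrow(x$water), ncol(x$water), x$cell_km,
              100 * mean(x$water)))
  invisible(x)
}

#' Toy cost grids with known shortest water paths
#'
#' Three scenarios with analytically known least-cost distances between the
#' two probe sites attached to the result:
#' \describe{
#'   \item{open_channel}{all water; probes at the middle row's two ends, so
#'     the shortest path is the straight row.}
#'   \item{wall}{a land wall down the middle column with a one-cell gap in
#'     the top row; probes as above, forcing a detour over the wall.}
#'   \item{island}{a land ring enclosing the centre cell; probes at the
#'     centre and the north-west corner -- no water path exists.}
#' }
#'
#' @param scenario one of `"open_channel"`, `"wall"`, `"island"`
#' @param shape integer(2), grid rows and columns (both >= 3; >= 5 for
#'   `island`)
#' @param cell_km cell size in km
#' @return a `cost_grid` with a two-row `sites` table of probe points
#' @export
make_cost_grid <- function(scenario = c("open_channel", "wall", "island"),
                           shape = c(5L, 5L), cell_km = 1) {
  scenario <- match.arg(scenario)
  stopifnot(length(shape) == 2, all(shape >= 3))
  nr <- shape[1]; nc <- shape[2]
  water <- matrix(TRUE, nr, nc)
  mid_row <- (nr + 1L) %/% 2L
  if (scenario == "open_channel") {
    sites <- data.frame(site = c("west", "east"),
                        row = c(mid_row, mid_row), col = c(1L, nc))
  } else if (scenario == "wall") {
    wall_col <- (nc + 1L) %/% 2L
    water[2:nr, wall_col] <- FALSE  # gap stays open in row 1
    sites <- data.frame(site = c("west", "east"),
                        row = c(mid_row, mid_row), col = c(1L, nc))
  } else {
    stopifnot(all(shape >= 5))
    cr <- (nr + 1L) %/% 2L; ccol <- (nc + 1L) %/% 2L
    water[(cr - 1L):(cr + 1L), (ccol - 1L):(ccol + 1L)] <- FALSE
    water[cr, ccol] <- TRUE  # enclosed lagoon
    sites <- data.frame(site = c("lagoon", "outside"),
                        row = c(cr, 1L), col = c(ccol, 1L))
  }
  cost_grid(water, cell_km, sites)
}

#' Least-cost water distances between sites
#'
#' Shortest water paths under 8-neighbour adjacency (orthogonal step =
#' `cell_km`, diagonal = `sqrt(2) * cell_km`), computed on the water-cell
#' graph with igraph. Sites on land are snapped to the nearest water cell;
#' snapping beyond `snap_max_km` fails, naming the site. Unreachable pairs
#' get `Inf`.
#'
#' @param grid a `cost_grid`
#' @param sites data.frame `site`, `row`, `col` (defaults to `grid$sites`)
#' @param snap_max_km maximum allowed snap distance in km (default `Inf`)
#' @return symmetric distance matrix in km with zero diagonal; snap distances
#'   are recorded in the `snap_km` attribute
#' @export
least_cost_distances <- function(grid, sites = grid$sites,
                                 snap_max_km = Inf) {
  stopifnot(!is.null(sites), all(c("site", "row", "col") %in% names(sites)))
  w <- grid$water
  nr <- nrow(w); nc <- ncol(w)
  cell_id <- function(r, c) (c - 1L) * nr + r
  water_idx <- which(w)
  # snap each site to its nearest water cell (Euclidean, in km)
  wrc <- arrayInd(water_idx, dim(w))
  anchors <- integer(nrow(sites))
  snap_km <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    d2 <- (wrc[, 1] - sites$row[i])^2 + (wrc[, 2] - sites$col[i])^2
    j <- which.min(d2)
    snap_km[i] <- sqrt(d2[j]) * grid$cell_km
    if (snap_km[i] > snap_max_km) {
      stop(sprintf("site '%s' is %.2f km from water (cap %.2f km)",
                   sites$site[i], snap_km[i], snap_max_km))
    }
    anchors[i] <- water_idx[j]
  }
  # 8-neighbour edges between water cells
  steps <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  rc <- arrayInd(water_idx, dim(w))
  for (s in seq_len(nrow(steps))) {
    r2 <- rc[, 1] + steps[s, 1]
    c2 <- rc[, 2] + steps[s, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- w[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    from <- c(from, water_idx[ok])
    to <- c(to, cell_id(r2[ok], c2[ok]))
    wt <- c(wt, rep(if (all(steps[s, ] != 0)) sqrt(2) * grid$cell_km
                    else grid$cell_km, sum(ok)))
  }
  # vertices named by cell index so lookups are direct
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(water_idx))
  )
  dm <- igraph::distances(g, v = as.character(anchors),
                          to = as.character(anchors), weights = wt)
  dimnames(dm) <- list(sites$site, sites$site)
  attr(dm, "snap_km") <- stats::setNames(snap_km, sites$site)
  dm
}
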