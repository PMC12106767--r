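#' Skeletonize a vessel mask into a branch graph
#'
#' The binary mask is reduced to a 26-connected medial curve skeleton
#' (iterative removal of simple border points, endpoints preserved). Skeleton
#' voxels are then classified following the ImageJ AnalyzeSkeleton
#' convention: slab voxels have exactly 2 neighbours, end voxels 1, junction
#' voxels 3 or more (26-adjacent junction voxels are clustered into a single
#' node). A branch is a maximal slab path between two non-slab voxels; an
#' isolated voxel is a degenerate branch of length 0. Per-branch radius is
#' the median local radius (distance transform of the input mask) sampled
#' along the path.
#'
#' @param mask a [vessel_mask()].
#' @param prune_um when positive, terminal branches shorter than this length
#'   (um) that hang off a junction are removed iteratively (with chain
#'   re-merging); such spurs are voxelization artifacts of the tube surface
#'   rather than vessels. 0 (default) keeps the raw skeleton.
#' @return An object of class `skeleton_graph` with fields:
#'   `branches` (list of ordered voxel-coordinate matrices, 1-based),
#'   `branch_radius` (um, per branch), `nodes` (data.frame of node voxels
#'   with degree), `dims`, `voxel_size`.
#' @export
skeletonize <- function(mask, prune_um = 0) {
  stopifnot(inherits(mask, "vessel_mask"))
  dims <- dim(mask$data)
  h <- mask$voxel_size
  out <- structure(list(branches = list(), branch_radius = numeric(0),
                        nodes = data.frame(i = integer(0), j = integer(0),
                                           k = integer(0), degree = integer(0)),
                        dims = dims, voxel_size = h),
                   class = "skeleton_graph")
  if (!any(mask$data)) return(out)

  skel <- thin3d_cpp(as.integer(mask$data), dims)
  edt <- edt_voxels(mask$data)
  lin <- which(skel == 1L)
  for (pass in 1:5) {
    g <- skeleton_graph_from_voxels(lin, dims, h, edt)
    if (prune_um <= 0) return(g)
    drop <- prune_candidates(g, prune_um, dims)
    if (length(drop) == 0L) return(g)
    lin <- setdiff(lin, drop)
    if (length(lin) == 0L) return(out)
  }
  g
}

# spur voxels to delete: slab+end voxels of terminal branches shorter than
# prune_um whose other end is a junction
prune_candidates <- function(g, prune_um, dims) {
  if (length(g$branches) < 2L) return(integer(0))
  nd <- g$nodes
  deg <- new.env(hash = TRUE)
  for (r in seq_len(nrow(nd)))
    assign(paste(nd$i[r], nd$j[r], nd$k[r]), nd$degree[r], envir = deg)
  degree_of <- function(v) {
    d <- deg[[paste(v[1], v[2], v[3])]]
    if (is.null(d)) 2L else d
  }
  drop <- integer(0)
  for (b in g$branches) {
    n <- nrow(b)
    len <- branch_arc_length(b, g$voxel_size)
    if (len >= prune_um) next
    d1 <- degree_of(b[1, ])
    d2 <- degree_of(b[n, ])
    if ((d1 == 1L && d2 >= 3L)) {
      drop <- c(drop, vox_to_lin(b[-n, , drop = FALSE], dims))
    } else if (d2 == 1L && d1 >= 3L) {
      drop <- c(drop, vox_to_lin(b[-1, , drop = FALSE], dims))
    }
  }
  unique(drop)
}

# branch/node extraction from skeleton voxel indices (AnalyzeSkeleton-style)
skeleton_graph_from_voxels <- function(lin, dims, h, edt) {
  co <- lin_to_vox(lin, dims)
  nv <- length(lin)
  # adjacency via 26 coordinate offsets, boundary-safe
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  pos <- integer(0); nbr <- integer(0)
  in_skel <- array(FALSE, dims)
  in_skel[lin] <- TRUE
  for (r in seq_len(nrow(g))) {
    ci <- co[, 1] + g$dx[r]; cj <- co[, 2] + g$dy[r]; ck <- co[, 3] + g$dz[r]
    ok <- ci >= 1L & ci <= dims[1] & cj >= 1L & cj <= dims[2] &
      ck >= 1L & ck <= dims[3]
    if (!any(ok)) next
    nl <- ci[ok] + dims[1] * (cj[ok] - 1L) + dims[1] * dims[2] * (ck[ok] - 1L)
    hit <- in_skel[nl]
    pos <- c(pos, which(ok)[hit])
    nbr <- c(nbr, nl[hit])
  }
  # map neighbour linear indices to local ids
  nbr_id <- match(nbr, lin)
  adj <- split(nbr_id, factor(pos, levels = seq_len(nv)))
  degree <- lengths(adj)

  is_slab <- degree == 2L
  terminal <- which(!is_slab) # ends, junctions, isolated

  # cluster 26-adjacent junction voxels into single nodes (union-find)
  parent <- uf_new(nv)
  jn <- degree >= 3L
  if (any(jn)) {
    for (v in which(jn)) {
      for (w in adj[[v]]) if (jn[w] && w > v) parent <- uf_union(parent, v, w)
    }
  }
  cluster <- vapply(seq_len(nv), function(v) uf_find(parent, v), integer(1))

  branches <- list()
  radii <- numeric(0)
  visited <- logical(nv) # slab voxels consumed
  used_tt <- new.env(hash = TRUE) # terminal-terminal direct edges consumed

  add_branch <- function(path_ids) {
    coords <- co[path_ids, , drop = FALSE]
    branches[[length(branches) + 1L]] <<- coords
    r <- radius_from_edt(edt[lin[path_ids]], h)
    radii[length(radii) + 1L] <<- median(r)
  }

  for (t in terminal) {
    for (nb in adj[[t]]) {
      if (is_slab[nb]) {
        if (visited[nb]) next
        path <- c(t, nb)
        visited[nb] <- TRUE
        prev <- t; cur <- nb
        repeat {
          nxt <- adj[[cur]]
          nxt <- nxt[nxt != prev]
          if (length(nxt) != 1L) break # defensive; slab has 2 neighbours
          nx <- nxt[1]
          if (is_slab[nx]) {
            if (visited[nx]) break # closed loop through a slab already taken
            path <- c(path, nx)
            visited[nx] <- TRUE
            prev <- cur; cur <- nx
          } else {
            path <- c(path, nx)
            break
          }
        }
        add_branch(path)
      } else {
        # direct terminal-terminal adjacency: a 2-voxel branch, unless both
        # voxels belong to the same junction cluster
        if (cluster[t] == cluster[nb]) next
        key <- paste(min(t, nb), max(t, nb))
        if (!is.null(used_tt[[key]])) next
        assign(key, TRUE, envir = used_tt)
        add_branch(c(t, nb))
      }
    }
    if (degree[t] == 0L) add_branch(t) # isolated voxel: degenerate branch
  }
  # pure cycles (all slab voxels): trace remaining loops
  for (s in which(is_slab & !visited)) {
    if (visited[s]) next
    path <- s
    visited[s] <- TRUE
    prev <- s; cur <- adj[[s]][1]
    while (!visited[cur]) {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nxt <- adj[[cur]]
      nxt <- nxt[nxt != prev]
      if (length(nxt) < 1L) break
      prev <- cur; cur <- nxt[1]
    }
    add_branch(path)
  }

  nodes <- data.frame(i = co[terminal, 1], j = co[terminal, 2],
                      k = co[terminal, 3], degree = as.integer(degree[terminal]))
  structure(list(branches = branches, branch_radius = radii, nodes = nodes,
                 dims = dims, voxel_size = h),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d branches, %d nodes (%d junctions, %d ends)\n",
              length(x$branches), nrow(x$nodes), sum(x$nodes$degree >= 3),
              sum(x$nodes$degree == 1)))
  invisible(x)
}

#' Number of branches in a skeleton graph
#' @param graph a [skeletonize()] result.
#' @return integer count.
#' @export
n_branches <- function(graph) length(graph$branches)

#' Branch diameter distribution
#'
#' Per-branch diameter is twice the median local radius along the branch
#' path; the histogram uses bins of `bin_width` micrometres starting at 0.
#'
#' @param graph a [skeletonize()] result.
#' @param bin_width histogram bin width in micrometres (default 0.5).
#' @return A list with `diameters` (um per branch), `histogram`
#'   (data.frame: `bin_center_um`, `count`, `frequency`) and `mode_um`
#'   (center of the modal bin). Empty graph gives empty components.
#' @export
diameter_distribution <- function(graph, bin_width = 0.5) {
  stopifnot(inherits(graph, "skeleton_graph"))
  diam <- 2 * graph$branch_radius
  hist_with_mode(diam, bin_width,
                 value_name = "diameters", unit = "um")
}

# shared histogram/mode helper (normalized to unit total)
hist_with_mode <- function(values, bin_width, value_name = "values",
                           unit = "um") {
  if (length(values) == 0L) {
    out <- list(values = numeric(0),
                histogram = data.frame(bin_center_um = numeric(0),
                                       count = integer(0),
                                       frequency = numeric(0)),
                mode_um = NA_real_)
    names(out)[1] <- value_name
    return(out)
  }
  breaks <- seq(0, (floor(max(values) / bin_width) + 1) * bin_width,
                by = bin_width)
  cnt <- tabulate(findInterval(values, breaks, rightmost.closed = FALSE,
                               left.open = TRUE) + 1L,
                  nbins = length(breaks))
  # findInterval with left.open: bins are (b[k], b[k+1]]; values==0 fall in bin 1
  cnt <- cnt[-1] + c(sum(values == 0), rep(0L, length(breaks) - 2L))
  centers <- breaks[-length(breaks)] + bin_width / 2
  out <- list(values = values,
              histogram = data.frame(bin_center_um = centers, count = cnt,
                                     frequency = cnt / sum(cnt)),
              mode_um = centers[which.max(cnt)])
  names(out)[1] <- value_name
  out
}
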