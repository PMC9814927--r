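# Disconnectivity graphs (superbasin trees). A node at grid energy E
# represents a superbasin: the set of local minima mutually reachable by
# pathways that never exceed E. Sweeping the common lid grid from low to high
# energy, components merge whenever a connection lid falls at or below the
# level; an internal node is emitted whenever two or more components merge.
# Leaves are single minima at their own energies; merge energies are
# ultrametric by construction.

#' Build a disconnectivity graph
#'
#' @param minima data.frame with columns `id` and `energy`
#' @param connections data.frame with columns `a`, `b`, `lid` (connection lid
#'   energies, each on the grid)
#' @param grid increasing numeric vector of lid energies
#' @return a `disconnectivity_graph`: list with `leaves` (data.frame node,
#'   id, energy), `nodes` (data.frame node, energy, leaf flag), `children`
#'   (list: node -> child nodes), `parent` (vector), `roots`
#' @examples
#' g <- build_graph(data.frame(id = 1:2, energy = c(-10, -8)),
#'                  data.frame(a = 1, b = 2, lid = -4), seq(-10, 0, 2))
#' merge_energy(g, 1, 2)  # -4
#' @export
build_graph <- function(minima, connections, grid) {
  n <- nrow(minima)
  if (n == 0) stop("no minima")
  if (nrow(connections)) {
    if (!all(connections$a %in% minima$id) || !all(connections$b %in% minima$id)) {
      stop("connection references an unknown minimum id")
    }
    off <- vapply(connections$lid, function(l) min(abs(grid - l)), 0)
    if (any(off > 1e-6)) stop("connection lid energies must lie on the grid")
    emin <- minima$energy[match(connections$a, minima$id)]
    emin2 <- minima$energy[match(connections$b, minima$id)]
    if (any(connections$lid < pmax(emin, emin2) - 1e-9)) {
      stop("connection lid below a connected minimum's energy")
    }
  }
  grid <- sort(unique(grid))
  # nodes 1..n are leaves
  node_energy <- minima$energy
  is_leaf <- rep(TRUE, n)
  children <- vector("list", n)
  parent <- rep(NA_integer_, n)
  comp_node <- seq_len(n)       # current top node of each minimum's component
  uf <- seq_len(n)              # union-find over minima rows
  find <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  ai <- match(connections$a, minima$id)
  bi <- match(connections$b, minima$id)
  for (lev in grid) {
    sel <- which(connections$lid <= lev + 1e-9)
    # merge all components linked at or below this level
    merged_groups <- list()
    for (k in sel) {
      ra <- find(ai[k]); rb <- find(bi[k])
      if (ra != rb) uf[rb] <- ra
    }
    # group current top nodes by component root
    roots <- vapply(seq_len(n), function(i) find(i), 0L)
    tops <- tapply(comp_node, roots, function(x) unique(x))
    for (grp in tops) {
      if (length(grp) >= 2) {
        node <- length(node_energy) + 1L
        node_energy <- c(node_energy, lev)
        is_leaf <- c(is_leaf, FALSE)
        children[[node]] <- grp
        parent[grp] <- node
        parent <- c(parent, NA_integer_)
        for (i in seq_len(n)) if (comp_node[i] %in% grp) comp_node[i] <- node
      }
    }
  }
  roots_final <- unique(comp_node)
  structure(list(
    leaves = data.frame(node = seq_len(n), id = minima$id,
                        energy = minima$energy),
    nodes = data.frame(node = seq_along(node_energy), energy = node_energy,
                       leaf = is_leaf),
    children = children, parent = parent, roots = roots_final,
    grid = grid
  ), class = "disconnectivity_graph")
}

#' Merge energy of two minima
#'
#' The grid energy at which the two minima first belong to the same
#' superbasin; `Inf` when they are never connected.
#' @param g a `disconnectivity_graph`
#' @param id1,id2 minimum ids
#' @return merge energy
#' @export
merge_energy <- function(g, id1, id2) {
  n1 <- g$leaves$node[g$leaves$id == id1]
  n2 <- g$leaves$node[g$leaves$id == id2]
  if (!length(n1) || !length(n2)) stop("unknown minimum id")
  anc <- function(x) {
    path <- x
    while (!is.na(g$parent[x])) { x <- g$parent[x]; path <- c(path, x) }
    path
  }
  common <- intersect(anc(n1), anc(n2))
  if (!length(common)) return(Inf)
  min(g$nodes$energy[match(common, g$nodes$node)])
}

# keep only the given leaf nodes; drop empty internal nodes and (optionally)
# contract internal nodes left with a single child
prune_graph <- function(g, keep_ids, contract = FALSE) {
  keep_leaf <- g$leaves$node[g$leaves$id %in% keep_ids]
  alive <- rep(FALSE, nrow(g$nodes))
  alive[keep_leaf] <- TRUE
  ord <- order(g$nodes$energy[!g$nodes$leaf])
  internal <- g$nodes$node[!g$nodes$leaf][ord]
  children <- g$children
  for (nd in internal) {
    kids <- children[[nd]]
    kids <- kids[alive[kids]]
    children[[nd]] <- kids
    alive[nd] <- length(kids) >= 1
  }
  parent <- rep(NA_integer_, length(alive))
  if (contract) {
    # replace single-child chains by the child
    rep_node <- seq_along(alive)
    for (nd in internal) {
      if (!alive[nd]) next
      kids <- vapply(children[[nd]], function(k) rep_node[k], 0L)
      if (length(kids) == 1) {
        rep_node[nd] <- kids
        alive[nd] <- FALSE
      } else {
        children[[nd]] <- kids
      }
    }
    for (nd in internal) if (alive[nd]) {
      for (k in children[[nd]]) parent[k] <- nd
    }
  } else {
    for (nd in internal) if (alive[nd]) {
      for (k in children[[nd]]) parent[k] <- nd
    }
  }
  leaves <- g$leaves[g$leaves$id %in% keep_ids, , drop = FALSE]
  roots <- which(alive & is.na(parent))
  structure(list(
    leaves = leaves,
    nodes = g$nodes[alive[g$nodes$node], , drop = FALSE],
    children = children, parent = parent, roots = roots, grid = g$grid
  ), class = "disconnectivity_graph")
}

#' Truncate a graph for display
#'
#' The highest pairwise merge energy between the landmark minima is taken as
#' the display limit; minima connecting to every landmark only above that
#' limit are removed from the display graph. The untruncated graph is kept in
#' the `full_graph` attribute.
#' @param g a `disconnectivity_graph`
#' @param landmarks minimum ids (subset of the leaves); with fewer than two
#'   landmarks the graph is returned unchanged
#' @return truncated `disconnectivity_graph` with attribute `full_graph`
#' @export
truncate_display <- function(g, landmarks) {
  if (length(landmarks) < 2) return(g)
  if (!all(landmarks %in% g$leaves$id)) stop("landmarks must be leaves")
  pairs <- utils::combn(landmarks, 2)
  limit <- max(apply(pairs, 2, function(p) merge_energy(g, p[1], p[2])))
  keep <- vapply(g$leaves$id, function(id) {
    if (id %in% landmarks) return(TRUE)
    min(vapply(landmarks, function(l) merge_energy(g, id, l), 0)) <= limit + 1e-9
  }, TRUE)
  out <- prune_graph(g, g$leaves$id[keep], contract = FALSE)
  attr(out, "full_graph") <- g
  attr(out, "display_limit") <- limit
  out
}

#' Simplify a graph to landmark minima
#'
#' Hides all non-landmark leaves and contracts internal nodes left with a
#' single child; pairwise landmark merge energies are preserved exactly.
#' @param g a `disconnectivity_graph`
#' @param landmarks minimum ids to keep
#' @return simplified `disconnectivity_graph`
#' @export
simplify_to_landmarks <- function(g, landmarks) {
  if (!all(landmarks %in% g$leaves$id)) stop("landmarks must be leaves")
  prune_graph(g, landmarks, contract = TRUE)
}

# recursive leaf ordering: group low-barrier siblings adjacently
# (children sorted by subtree minimum energy, ties by energy then node id)
graph_layout <- function(g) {
  subtree_min <- function(nd) {
    if (g$nodes$leaf[g$nodes$node == nd]) {
      return(g$leaves$energy[g$leaves$node == nd])
    }
    min(vapply(g$children[[nd]], subtree_min, 0))
  }
  xpos <- numeric(max(g$nodes$node))
  nextx <- 0
  place <- function(nd) {
    if (g$nodes$leaf[g$nodes$node == nd]) {
      nextx <<- nextx + 1
      xpos[nd] <<- nextx
      return(nextx)
    }
    kids <- g$children[[nd]]
    key <- vapply(kids, subtree_min, 0)
    kids <- kids[order(key, g$nodes$energy[match(kids, g$nodes$node)], kids)]
    xs <- vapply(kids, place, 0)
    xpos[nd] <<- mean(xs)
    mean(xs)
  }
  roots <- g$roots[order(vapply(g$roots, subtree_min, 0))]
  for (r in roots) place(r)
  xpos
}

#' Plot a disconnectivity graph
#'
#' Vertical branches run from each node's energy down to its children; leaves
#' end at their minimum energies. Horizontal placement groups structures
#' separated by low barriers and is presentation-only.
#' @param x a `disconnectivity_graph`
#' @param color_by optional named vector (by minimum id) of a scalar property
#'   used to colour leaf branches
#' @param main plot title
#' @param ... passed to `plot`
#' @return invisibly, the leaf x-positions
#' @export
plot.disconnectivity_graph <- function(x, color_by = NULL, main = "", ...) {
  g <- x
  xpos <- graph_layout(g)
  eleaf <- g$leaves$energy
  etop <- max(g$nodes$energy) + 0.05 * diff(range(c(eleaf, g$nodes$energy)))
  graphics::plot(NULL, xlim = c(0.5, nrow(g$leaves) + 0.5),
                 ylim = c(min(eleaf), etop), xlab = "minima",
                 ylab = "energy [kJ/mol]", xaxt = "n", main = main, ...)
  cols <- rep("black", nrow(g$leaves))
  if (!is.null(color_by)) {
    v <- color_by[as.character(g$leaves$id)]
    pal <- grDevices::hcl.colors(64, "viridis")
    idx <- as.integer(cut(v, breaks = 64))
    cols <- pal[idx]
  }
  for (i in seq_len(nrow(g$leaves))) {
    nd <- g$leaves$node[i]
    top <- if (!is.na(g$parent[nd])) g$nodes$energy[g$nodes$node == g$parent[nd]] else etop
    graphics::segments(xpos[nd], g$leaves$energy[i], xpos[nd], top, col = cols[i])
  }
  for (nd in g$nodes$node[!g$nodes$leaf]) {
    kids <- g$children[[nd]]
    e <- g$nodes$energy[g$nodes$node == nd]
    graphics::segments(min(xpos[kids]), e, max(xpos[kids]), e)
    top <- if (!is.na(g$parent[nd])) g$nodes$energy[g$nodes$node == g$parent[nd]] else etop
    graphics::segments(xpos[nd], e, xpos[nd], top)
  }
  invisible(xpos)
}

#' Serialize a graph to JSON-ready lists
#'
#' Decouples plotting and downstream analysis from simulation: leaves, nodes
#' and parent/child relations as plain lists.
#' @param g a `disconnectivity_graph`
#' @return nested list (leaves, nodes, edges)
#' @export
graph_to_list <- function(g) {
  list(
    leaves = lapply(seq_len(nrow(g$leaves)), function(i) {
      list(node = g$leaves$node[i], id = g$leaves$id[i],
           energy = g$leaves$energy[i])
    }),
    nodes = lapply(which(!g$nodes$leaf), function(i) {
      nd <- g$nodes$node[i]
      list(node = nd, energy = g$nodes$energy[i], children = g$children[[nd]])
    })
  )
}

#' @export
print.disconnectivity_graph <- function(x, ...) {
  cat(sprintf("disconnectivity graph: %d minima, %d superbasin nodes, %d root(s)\n",
              nrow(x$leaves), sum(!x$nodes$leaf), length(x$roots)))
  invisible(x)
}
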