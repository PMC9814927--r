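# HDBSCAN*: hierarchical density-based clustering. Core distances (k-th
# nearest neighbour), mutual-reachability distances, a minimum spanning tree,
# a condensed cluster tree at the chosen minimum cluster size, and
# excess-of-mass cluster selection. Points never absorbed into a selected
# cluster are labelled 0 (noise).

#' HDBSCAN* clustering from a distance matrix
#'
#' @param D symmetric distance matrix
#' @param min_cluster_size smallest cluster size considered a true split
#' @param min_samples smoothing parameter for core distances (default:
#'   `min_cluster_size`); a point's core distance is the distance to its
#'   `min_samples`-th nearest neighbour counting itself
#' @return list with `labels` (0 = noise), `n_clusters`, `cluster_stability`
#' @export
hdbscan_cluster <- function(D, min_cluster_size = 5,
                            min_samples = min_cluster_size) {
  n <- nrow(D)
  if (n < 2) stop("need at least 2 points")
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  k <- min(min_samples, n)
  core <- vapply(seq_len(n), function(i) sort(D[i, ])[k], 0)
  mreach <- pmax(D, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(mreach) <- 0
  # Prim MST on mutual reachability
  intree <- logical(n); intree[1] <- TRUE
  best <- mreach[1, ]; bestfrom <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (e in seq_len(n - 1)) {
    cand <- which(!intree)
    j <- cand[which.min(best[cand])]
    edges[e, ] <- c(bestfrom[j], j, best[j])
    intree[j] <- TRUE
    upd <- !intree & mreach[j, ] < best
    best[upd] <- mreach[j, upd]
    bestfrom[upd] <- j
  }
  edges <- edges[order(edges[, 3]), , drop = FALSE]
  # single-linkage merge tree from sorted MST edges
  parent <- integer(2 * n - 1)
  height <- numeric(2 * n - 1)
  children <- vector("list", 2 * n - 1)
  uf <- seq_len(2 * n - 1)
  find <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  top <- seq_len(n) # current tree node of each component root
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    nxt <- nxt + 1L
    children[[nxt]] <- c(top[ra], top[rb])
    height[nxt] <- edges[e, 3]
    uf[rb] <- ra
    top[ra] <- nxt
  }
  root <- nxt
  # subtree sizes and point lists
  sizes <- integer(2 * n - 1)
  pts <- vector("list", 2 * n - 1)
  for (v in seq_len(2 * n - 1)) {
    if (v <= n) { sizes[v] <- 1L; pts[v] <- list(v) }
  }
  for (v in (n + 1):root) {
    ch <- children[[v]]
    sizes[v] <- sum(sizes[ch])
    pts[[v]] <- c(pts[[ch[1]]], pts[[ch[2]]])
  }
  # condensed tree: clusters with birth lambda, fallout points, child clusters
  clusters <- list()
  new_cluster <- function(birth, parent_cl) {
    clusters[[length(clusters) + 1]] <<- list(
      birth = birth, parent = parent_cl, children = integer(0),
      fallout = numeric(0), fallout_pts = integer(0), members = integer(0))
    length(clusters)
  }
  # zero merge heights (duplicate points) are capped so lambdas stay finite
  lam <- function(h) 1 / max(h, 1e-9)
  condense <- function(node, cl) {
    repeat {
      if (node <= n) { # lone point falls out when its cluster dies
        clusters[[cl]]$fallout <<- c(clusters[[cl]]$fallout, Inf)
        clusters[[cl]]$fallout_pts <<- c(clusters[[cl]]$fallout_pts, node)
        return(invisible())
      }
      ch <- children[[node]]
      l <- lam(height[node])
      big <- sizes[ch] >= min_cluster_size
      if (all(big)) { # true split: two child clusters born at this level
        for (c2 in ch) {
          sub <- new_cluster(l, cl)
          clusters[[cl]]$children <<- c(clusters[[cl]]$children, sub)
          condense(c2, sub)
        }
        return(invisible())
      }
      # shed small side(s) as fallout at this lambda, continue into the rest
      keep <- NULL
      for (c2 in ch) {
        if (sizes[c2] >= min_cluster_size && is.null(keep)) {
          keep <- c2
        } else {
          p <- pts[[c2]]
          clusters[[cl]]$fallout <<- c(clusters[[cl]]$fallout, rep(l, length(p)))
          clusters[[cl]]$fallout_pts <<- c(clusters[[cl]]$fallout_pts, p)
        }
      }
      if (is.null(keep)) return(invisible())
      node <- keep
    }
  }
  root_cl <- new_cluster(lam(height[root]), 0L)
  condense(root, root_cl)
  nc <- length(clusters)
  # members and stability
  all_members <- function(cl) {
    m <- clusters[[cl]]$fallout_pts
    for (c2 in clusters[[cl]]$children) m <- c(m, all_members(c2))
    m
  }
  stability <- numeric(nc)
  for (cl in seq_len(nc)) {
    birth <- clusters[[cl]]$birth
    lamout <- clusters[[cl]]$fallout
    # points leaving via child splits leave at the child birth lambda
    for (c2 in clusters[[cl]]$children) {
      lamout <- c(lamout, rep(clusters[[c2]]$birth, length(all_members(c2))))
    }
    cap <- max(c(lamout[is.finite(lamout)], birth))
    lamfin <- pmin(lamout, cap)
    stability[cl] <- sum(pmax(0, lamfin - birth))
    if (!is.finite(stability[cl])) stability[cl] <- 0
  }
  # excess-of-mass selection (root excluded)
  selected <- logical(nc)
  score <- numeric(nc)
  order_depth <- rev(seq_len(nc)) # children always created after parents
  for (cl in order_depth) {
    ch <- clusters[[cl]]$children
    child_score <- sum(score[ch])
    if (cl == root_cl) { score[cl] <- child_score; next }
    if (!length(ch) || stability[cl] >= child_score) {
      score[cl] <- stability[cl]
      selected[cl] <- TRUE
      # deselect descendants
      desc <- ch
      while (length(desc)) {
        selected[desc] <- FALSE
        desc <- unlist(lapply(desc, function(d) clusters[[d]]$children))
      }
    } else {
      score[cl] <- child_score
    }
  }
  labels <- integer(n)
  lab <- 0L
  for (cl in which(selected)) {
    lab <- lab + 1L
    labels[all_members(cl)] <- lab
  }
  list(labels = labels, n_clusters = lab,
       cluster_stability = stability[selected])
}
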