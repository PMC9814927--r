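# Analytic multi-well toy landscapes with exactly known minima and barrier
# heights. These are the unit-test surface for the threshold engine and the
# disconnectivity layer: wells sit at integer positions, saddles at
# half-integer positions, and monotone cubic interpolation between control
# points guarantees there are no other stationary points, so every barrier is
# known in closed form.

#' Create an analytic multi-well landscape
#'
#' Wells are placed at x = 0, 1, ..., n-1 with the requested energies; the
#' saddle between adjacent wells sits at the half-integer position with the
#' requested barrier energy. `barriers` may be given either as the n-1
#' adjacent saddle energies or as a full n x n pairwise barrier matrix, which
#' must be ultrametric (for any three wells the two largest pairwise barriers
#' are equal); the matrix is realized as a 1-D arrangement via single-linkage
#' ordering and an error is raised when no arrangement reproduces it.
#'
#' @param wells numeric vector (length >= 2) of minimum energies
#' @param barriers adjacent saddle energies (length n-1) or an n x n
#'   ultrametric barrier matrix
#' @return a `toy_landscape`: list with `fn` (vectorized energy function),
#'   `wells` (data.frame x, energy, well = original index), `saddles`,
#'   `barrier_matrix` (pairwise minimax barrier energies, original indexing)
#' @examples
#' tl <- make_toy_landscape(c(-10, -8), barriers = -4)
#' tl$barrier_matrix[1, 2]  # -4
#' @export
make_toy_landscape <- function(wells, barriers) {
  n <- length(wells)
  if (n < 2) stop("a toy landscape needs at least 2 wells")
  if (is.matrix(barriers)) {
    ord <- ultrametric_order(barriers)
    wells_o <- wells[ord]
    adj <- vapply(seq_len(n - 1), function(k) barriers[ord[k], ord[k + 1]], 0)
    # validate: the 1-D minimax closure must reproduce the input matrix
    B <- adjacent_to_pairwise(adj)
    Bin <- barriers[ord, ord]
    if (max(abs(B - Bin), na.rm = TRUE) > 1e-9) {
      stop("inconsistent barrier spec: matrix is not ultrametric")
    }
  } else {
    if (length(barriers) != n - 1) {
      stop("need n-1 adjacent barriers or an n x n matrix")
    }
    ord <- seq_len(n)
    wells_o <- wells
    adj <- as.numeric(barriers)
  }
  if (any(adj <= pmax(wells_o[-n], wells_o[-1]))) {
    stop("every saddle must lie above both adjacent wells")
  }
  wall <- max(adj) + 50
  cx <- c(-0.5, as.numeric(rbind(seq_len(n) - 1, c(seq_len(n - 1) - 0.5, n - 0.5))))
  cy <- c(wall, as.numeric(rbind(wells_o, c(adj, wall))))
  sp <- stats::splinefun(cx, cy, method = "monoH.FC")
  fn <- function(x) {
    y <- sp(pmin(pmax(x, -0.5), n - 0.5))
    # linear walls outside the control range
    y + 100 * pmax(0, -0.5 - x) + 100 * pmax(0, x - (n - 0.5))
  }
  Badj <- adjacent_to_pairwise(adj)
  # report in original well indexing
  Bm <- matrix(NA_real_, n, n)
  Bm[ord, ord] <- Badj
  diag(Bm) <- wells
  structure(list(
    fn = fn, n = n,
    wells = data.frame(x = seq_len(n) - 1, energy = wells_o, well = ord),
    saddles = data.frame(x = seq_len(n - 1) - 0.5, energy = adj),
    barrier_matrix = Bm
  ), class = "toy_landscape")
}

# pairwise minimax barriers of a 1-D chain from adjacent saddle energies
adjacent_to_pairwise <- function(adj) {
  n <- length(adj) + 1
  B <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    B[i, j] <- B[j, i] <- max(adj[i:(j - 1)])
  }
  B
}

# leaf ordering realizing an ultrametric matrix on a line (single linkage)
ultrametric_order <- function(B) {
  if (nrow(B) != ncol(B) || max(abs(B - t(B)), na.rm = TRUE) > 1e-12) {
    stop("barrier matrix must be square and symmetric")
  }
  d <- stats::as.dist(B - min(B, na.rm = TRUE) + 1)
  stats::hclust(d, method = "single")$order
}

#' Analytic basin minimization on a toy landscape
#'
#' Wells attract exactly the interval between their flanking saddles, so the
#' local minimum of any point is known in closed form.
#' @param tl a `toy_landscape`
#' @param x coordinate
#' @return list(state = well position, energy, well = original well index,
#'   converged = TRUE)
#' @export
toy_minimize <- function(tl, x) {
  i <- round(pmin(pmax(x, 0), tl$n - 1))
  list(state = i, energy = tl$wells$energy[i + 1],
       well = tl$wells$well[i + 1], converged = TRUE)
}

#' Oracle barrier between two wells
#' @param tl a `toy_landscape`
#' @param i,j original well indices
#' @return exact saddle energy of the lowest path between the wells
#' @export
toy_barrier <- function(tl, i, j) tl$barrier_matrix[i, j]

#' @export
print.toy_landscape <- function(x, ...) {
  cat(sprintf("toy landscape: %d wells at energies [%s]\n", x$n,
              paste(signif(x$wells$energy, 4), collapse = ", ")))
  invisible(x)
}
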