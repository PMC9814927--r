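# Atom-centred descriptors for landscape featurization: element-resolved
# atom-centred symmetry functions (ACSF, radial G2 + angular G4 on an
# ANI-style parameter grid) and a compact SOAP (Gaussian radial basis x real
# spherical harmonics to l = 3, power spectrum per element pair). Structure
# similarity aggregates per-atom environment kernels through the
# regularized-entropy match (REMatch) kernel: entropy-regularized optimal
# transport over the environment-similarity matrix.

#' Descriptor configuration
#'
#' @param kind "acsf" or "soap"
#' @param elements element symbols resolved in the channels; structures must
#'   contain no others
#' @param rc_radial,n_rs_radial,eta_radial radial G2 grid (ANI-style defaults)
#' @param rc_angular,n_rs_angular,n_theta,zeta,eta_angular angular G4 grid
#' @param soap_n,soap_sigma,soap_l SOAP radial basis size, Gaussian width and
#'   maximum angular momentum (l <= 3)
#' @param gamma REMatch entropy regularization
#' @return a `descriptor_config`
#' @export
descriptor_config <- function(kind = c("acsf", "soap"), elements,
                              rc_radial = 4.6, n_rs_radial = 16,
                              eta_radial = 16,
                              rc_angular = 3.1, n_rs_angular = 4,
                              n_theta = 8, zeta = 8, eta_angular = 8,
                              soap_n = 5, soap_sigma = 0.5, soap_l = 3,
                              gamma = 0.1) {
  kind <- match.arg(kind)
  if (rc_radial <= 0 || rc_angular <= 0) stop("cutoffs must be positive")
  structure(list(kind = kind, elements = sort(elements),
                 rc_radial = rc_radial,
                 rs_radial = seq(0.5, rc_radial - 0.25, length.out = n_rs_radial),
                 eta_radial = eta_radial,
                 rc_angular = rc_angular,
                 rs_angular = seq(0.5, rc_angular - 0.25, length.out = n_rs_angular),
                 thetas = seq(0, pi, length.out = n_theta),
                 zeta = zeta, eta_angular = eta_angular,
                 soap_n = soap_n, soap_sigma = soap_sigma, soap_l = soap_l,
                 gamma = gamma), class = "descriptor_config")
}

cutoff_fn <- function(r, rc) ifelse(r < rc, 0.5 * (cos(pi * r / rc) + 1), 0)

# periodic neighbour list: for each atom, data.frame(vec x 3, dist, element)
neighbour_lists <- function(s, dmax) {
  sites <- to_cartesian(s)
  n <- nrow(sites$coords)
  cl <- cpp_contact_list(sites$coords, seq_len(n), cell_matrix(s$lattice), dmax)
  A <- cell_matrix(s$lattice)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- list(vec = NULL, dist = numeric(0),
                                         element = character(0))
  if (nrow(cl)) {
    sh <- cl[, c("sa", "sb", "sc")] %*% t(A)
    vec <- sites$coords[cl[, "j"], , drop = FALSE] + sh -
      sites$coords[cl[, "i"], , drop = FALSE]
    for (i in seq_len(n)) {
      ix <- which(cl[, "i"] == i)
      out[[i]] <- list(vec = vec[ix, , drop = FALSE], dist = cl[ix, "dist"],
                       element = sites$element[cl[ix, "j"]])
    }
  }
  attr(out, "elements") <- sites$element
  out
}

acsf_atom <- function(nb, config) {
  els <- config$elements
  rad <- numeric(0)
  for (el in els) {
    sel <- nb$element == el & nb$dist <= config$rc_radial
    r <- nb$dist[sel]
    fc <- cutoff_fn(r, config$rc_radial)
    g <- vapply(config$rs_radial, function(rs) {
      sum(exp(-config$eta_radial * (r - rs)^2) * fc)
    }, 0)
    rad <- c(rad, g)
  }
  ang <- numeric(0)
  sel <- nb$dist <= config$rc_angular
  v <- nb$vec[sel, , drop = FALSE]; r <- nb$dist[sel]; e <- nb$element[sel]
  fc <- cutoff_fn(r, config$rc_angular)
  m <- length(r)
  pair_idx <- if (m >= 2) utils::combn(m, 2) else matrix(0, 2, 0)
  for (a in seq_along(els)) for (b in a:length(els)) {
    gsum <- numeric(length(config$rs_angular) * length(config$thetas))
    if (ncol(pair_idx)) {
      keep <- (e[pair_idx[1, ]] == els[a] & e[pair_idx[2, ]] == els[b]) |
        (e[pair_idx[1, ]] == els[b] & e[pair_idx[2, ]] == els[a])
      for (pidx in which(keep)) {
        j <- pair_idx[1, pidx]; k <- pair_idx[2, pidx]
        cth <- sum(v[j, ] * v[k, ]) / (r[j] * r[k])
        th <- acos(pmin(1, pmax(-1, cth)))
        ravg <- (r[j] + r[k]) / 2
        gs <- outer(config$rs_angular, config$thetas, function(rs, ts) {
          (1 + cos(th - ts))^config$zeta *
            exp(-config$eta_angular * (ravg - rs)^2)
        }) * fc[j] * fc[k] * 2^(1 - config$zeta)
        gsum <- gsum + as.numeric(gs)
      }
    }
    ang <- c(ang, gsum)
  }
  c(rad, ang)
}

# real spherical harmonics up to l = 3 for unit vectors (rows)
real_sph_harm <- function(u, lmax) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  out <- cbind(Y00 = rep(0.28209479, nrow(u)))
  if (lmax >= 1) {
    out <- cbind(out, 0.48860251 * y, 0.48860251 * z, 0.48860251 * x)
  }
  if (lmax >= 2) {
    out <- cbind(out, 1.09254843 * x * y, 1.09254843 * y * z,
                 0.31539157 * (3 * z^2 - 1), 1.09254843 * x * z,
                 0.54627422 * (x^2 - y^2))
  }
  if (lmax >= 3) {
    out <- cbind(out, 0.59004359 * y * (3 * x^2 - y^2),
                 2.89061144 * x * y * z,
                 0.45704579 * y * (5 * z^2 - 1),
                 0.37317633 * (5 * z^3 - 3 * z),
                 0.45704579 * x * (5 * z^2 - 1),
                 1.44530572 * z * (x^2 - y^2),
                 0.59004359 * x * (x^2 - 3 * y^2))
  }
  out
}

soap_atom <- function(nb, config) {
  rc <- config$rc_radial
  sel <- nb$dist <= rc & nb$dist > 1e-9
  v <- nb$vec[sel, , drop = FALSE]; r <- nb$dist[sel]; e <- nb$element[sel]
  rn <- seq(0.5, rc, length.out = config$soap_n)
  lmax <- config$soap_l
  nlm <- (lmax + 1)^2
  els <- config$elements
  cmat <- array(0, c(length(els), config$soap_n, nlm))
  if (nrow(v)) {
    u <- v / r
    Y <- real_sph_harm(u, lmax)
    fc <- cutoff_fn(r, rc)
    for (ei in seq_along(els)) {
      ix <- e == els[ei]
      if (!any(ix)) next
      for (n in seq_len(config$soap_n)) {
        g <- exp(-(r[ix] - rn[n])^2 / (2 * config$soap_sigma^2)) * fc[ix]
        cmat[ei, n, ] <- colSums(Y[ix, , drop = FALSE] * g)
      }
    }
  }
  # power spectrum over (element, n) pairs per l
  loff <- c(0, 1, 4, 9)[1:(lmax + 1)]
  lsz <- c(1, 3, 5, 7)[1:(lmax + 1)]
  comb <- expand.grid(ei = seq_along(els), n = seq_len(config$soap_n))
  p <- numeric(0)
  for (i in seq_len(nrow(comb))) for (j in i:nrow(comb)) {
    ci <- cmat[comb$ei[i], comb$n[i], ]
    cj <- cmat[comb$ei[j], comb$n[j], ]
    for (l in 0:lmax) {
      ix <- loff[l + 1] + seq_len(lsz[l + 1])
      p <- c(p, sum(ci[ix] * cj[ix]))
    }
  }
  nrm <- sqrt(sum(p^2))
  if (nrm > 1e-12) p <- p / nrm
  p
}

#' Featurize structures
#'
#' Computes per-atom descriptors, orders atoms canonically (by element, then
#' lexicographically by descriptor values, so the flattened vector is
#' invariant under atom permutations within element classes) and flattens
#' them into one fixed-length vector per structure.
#'
#' @param structures list of [crystal_structure()]s with identical
#'   composition
#' @param config a [descriptor_config()]
#' @return matrix (structures x features)
#' @export
featurize <- function(structures, config) {
  rows <- lapply(structures, function(s) {
    nb <- neighbour_lists(s, max(config$rc_radial, config$rc_angular))
    els <- attr(nb, "elements")
    if (!all(els %in% config$elements)) {
      stop("element(s) absent from descriptor config: ",
           paste(setdiff(unique(els), config$elements), collapse = ", "))
    }
    per_atom <- t(vapply(nb, function(nbi) {
      if (config$kind == "acsf") acsf_atom(nbi, config) else soap_atom(nbi, config)
    }, numeric(if (config$kind == "acsf") acsf_length(config) else soap_length(config))))
    ord <- do.call(order, c(list(els),
                            lapply(seq_len(ncol(per_atom)),
                                   function(j) per_atom[, j])))
    as.numeric(t(per_atom[ord, , drop = FALSE]))
  })
  len <- unique(vapply(rows, length, 0L))
  if (length(len) != 1) stop("structures have inconsistent composition")
  do.call(rbind, rows)
}

acsf_length <- function(config) {
  ne <- length(config$elements)
  ne * length(config$rs_radial) +
    ne * (ne + 1) / 2 * length(config$rs_angular) * length(config$thetas)
}

soap_length <- function(config) {
  m <- length(config$elements) * config$soap_n
  m * (m + 1) / 2 * (config$soap_l + 1)
}

#' Per-atom SOAP environments of a structure
#' @param s a [crystal_structure()]
#' @param config a [descriptor_config()]
#' @return matrix (atoms x features), rows unit-normalized
#' @export
soap_environments <- function(s, config) {
  nb <- neighbour_lists(s, config$rc_radial)
  t(vapply(nb, function(nbi) soap_atom(nbi, config),
           numeric(soap_length(config))))
}

#' REMatch similarity of two environment sets
#'
#' Entropy-regularized optimal transport over the environment-similarity
#' matrix K (Sinkhorn iteration with uniform marginals): the similarity is
#' sum(P * K) at the optimal transport plan P. As `gamma -> Inf` this tends
#' to `mean(K)`; as `gamma -> 0` it approaches the best-match (assignment)
#' kernel. With `normalize = TRUE` the result is divided by the geometric
#' mean of the self-similarities, so self-similarity is exactly 1.
#'
#' @param env1,env2 environment matrices (rows are unit-normalized atomic
#'   environments)
#' @param gamma entropy regularization (> 0)
#' @param normalize normalize by self-similarities
#' @param max_iter,tol Sinkhorn iteration controls
#' @return similarity in [0, 1]
#' @export
rematch_similarity <- function(env1, env2, gamma = 0.1, normalize = TRUE,
                               max_iter = 20000, tol = 1e-8) {
  raw <- rematch_raw(env1 %*% t(env2), gamma, max_iter, tol)
  if (!normalize) return(raw)
  s11 <- rematch_raw(env1 %*% t(env1), gamma, max_iter, tol)
  s22 <- rematch_raw(env2 %*% t(env2), gamma, max_iter, tol)
  max(0, min(1, raw / sqrt(s11 * s22)))
}

# log-domain Sinkhorn: numerically stable for small gamma
rematch_raw <- function(K, gamma, max_iter = 20000, tol = 1e-8) {
  n <- nrow(K); m <- ncol(K)
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  A <- K / gamma
  lu <- rep(0, n); lv <- rep(0, m)
  for (it in seq_len(max_iter)) {
    lu <- log(1 / n) - vapply(seq_len(n), function(i) lse(A[i, ] + lv), 0)
    lv_new <- log(1 / m) - vapply(seq_len(m), function(j) lse(A[, j] + lu), 0)
    err <- max(abs(exp(lv_new) - exp(lv)) * 1) # potential change
    rowsum_err <- max(abs(vapply(seq_len(n), function(i) {
      exp(lse(A[i, ] + lv_new) + lu[i])
    }, 0) - 1 / n))
    lv <- lv_new
    if (rowsum_err < tol) {
      lP <- A + outer(lu, lv, "+")
      return(sum(exp(lP) * K))
    }
  }
  stop(sprintf("Sinkhorn iteration did not converge in %d iterations", max_iter))
}

#' REMatch kernel matrix over a structure set
#' @param structures list of [crystal_structure()]s
#' @param config a [descriptor_config()] (kind "soap")
#' @return normalized kernel matrix (diagonal 1)
#' @export
rematch_kernel <- function(structures, config) {
  envs <- lapply(structures, soap_environments, config = config)
  n <- length(envs)
  selfs <- vapply(envs, function(e) rematch_raw(e %*% t(e), config$gamma), 0)
  K <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r <- rematch_raw(envs[[i]] %*% t(envs[[j]]), config$gamma)
      K[i, j] <- K[j, i] <- r / sqrt(selfs[i] * selfs[j])
    }
  }
  K
}

#' Kernel distance
#'
#' `d = sqrt(2 - 2 k)` for a normalized kernel (standard kernel-induced
#' distance).
#' @param K normalized kernel matrix
#' @return dissimilarity matrix
#' @export
kernel_distance <- function(K) {
  D <- sqrt(pmax(0, 2 - 2 * K))
  diag(D) <- 0
  D
}

#' Adjusted Rand index
#' @param a,b two label vectors (noise label 0 is treated as its own class)
#' @return ARI in [-1, 1]
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- ai * bj / n2
  max_idx <- (ai + bj) / 2
  if (abs(max_idx - exp_idx) < 1e-12) return(1) # degenerate: identical trivial partitions
  (nij - exp_idx) / (max_idx - exp_idx)
}

#' PCA projection and density-based clustering against basin labels
#'
#' PCA of mean-centred descriptor vectors (or kernel PCA of a normalized
#' kernel), plus HDBSCAN* in the original high-dimensional space over a swept
#' grid of minimum cluster sizes; reports the adjusted Rand index between
#' each clustering and the basin labels. No automatic size selection is
#' performed — results are reported per size.
#'
#' @param x descriptor matrix (structures x features) or, with
#'   `is_kernel = TRUE`, a normalized kernel matrix
#' @param basin_labels vector of basin labels per structure
#' @param min_cluster_sizes swept HDBSCAN* minimum cluster sizes
#' @param is_kernel whether `x` is a kernel
#' @param ncomp number of principal components to return
#' @return list(projection, eigenvalues, clusterings (per size), ari (per
#'   size), distance)
#' @export
project_and_cluster <- function(x, basin_labels,
                                min_cluster_sizes = c(3, 5, 8, 12),
                                is_kernel = FALSE, ncomp = 2) {
  n <- if (is_kernel) nrow(x) else nrow(x)
  if (n < 3) stop("need at least 3 structures")
  if (length(basin_labels) != n) stop("label length mismatch")
  if (is_kernel) {
    J <- diag(n) - matrix(1 / n, n, n)
    Kc <- J %*% x %*% J
    eg <- eigen(Kc, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    proj <- eg$vectors[, seq_len(ncomp), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(ncomp)]), ncomp)
    D <- kernel_distance(x)
  } else {
    xc <- scale(x, center = TRUE, scale = FALSE)
    sv <- svd(xc)
    ev <- sv$d^2 / (n - 1)
    if (ev[1] < 1e-12) warning("degenerate PCA: zero total variance")
    proj <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
      diag(sv$d[seq_len(ncomp)], ncomp)
    D <- as.matrix(stats::dist(x))
  }
  clusterings <- list(); ari <- numeric(0)
  for (mcs in min_cluster_sizes) {
    cl <- hdbscan_cluster(D, min_cluster_size = mcs)
    clusterings[[as.character(mcs)]] <- cl
    ari[as.character(mcs)] <- adjusted_rand_index(cl$labels, basin_labels)
  }
  list(projection = proj, eigenvalues = ev, clusterings = clusterings,
       ari = ari, distance = D)
}

#' Within- and between-basin distance distributions
#'
#' @param D dissimilarity matrix
#' @param basin_labels labels with at least two distinct basins; pairs
#'   involving other labels (e.g. "outside") are ignored
#' @param basins the two basin labels to compare (default: two most frequent)
#' @return list(within1, within2, between, overlap) where `overlap` is the
#'   common-language statistic P(within < between) (0.5 = indistinguishable
#'   distributions, 1 = perfectly separated)
#' @export
basin_distance_distributions <- function(D, basin_labels, basins = NULL) {
  if (is.null(basins)) {
    tb <- sort(table(basin_labels), decreasing = TRUE)
    basins <- names(tb)[1:2]
  }
  i1 <- which(basin_labels == basins[1])
  i2 <- which(basin_labels == basins[2])
  if (length(i1) < 2 || length(i2) < 2) stop("each basin needs >= 2 structures")
  up <- function(ix) {
    M <- D[ix, ix, drop = FALSE]
    M[upper.tri(M)]
  }
  within1 <- up(i1); within2 <- up(i2)
  between <- as.numeric(D[i1, i2])
  within <- c(within1, within2)
  overlap <- mean(outer(within, between, "<")) +
    0.5 * mean(outer(within, between, "=="))
  list(within1 = within1, within2 = within2, between = between,
       overlap = overlap)
}
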