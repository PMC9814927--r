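# Buckingham (exp-6) force field: per-type-pair parameters A [kJ/mol],
# B [1/Angstrom], C [kJ/mol Angstrom^6], plus element radii used by the
# close-contact rule and the matching/motif machinery. Electrostatics are
# point charges carried by the molecules (rank 0, Ewald-summed); the
# distributed-multipole ranks >= 1 of full CSP force fields are external
# quantum-chemistry products and are not computed here.

#' Create an exp-6 force field
#'
#' @param types character vector of atom type labels
#' @param A,B,C square matrices (ntype x ntype, symmetric) of pair parameters;
#'   scalars and per-type vectors are expanded with combining rules
#'   (geometric mean for A and C, arithmetic mean for B)
#' @param cov_radii,vdw_radii named per-element radii [Angstrom]; defaults from
#'   the built-in tables
#' @param rank electrostatic rank (0 = point charges; the only rank evaluated)
#' @return an object of class `force_field`
#' @examples
#' ff <- force_field("C", A = 369743, B = 3.6, C = 2439.8)
#' @export
force_field <- function(types, A, B, C,
                        cov_radii = COVALENT_RADII, vdw_radii = VDW_RADII,
                        rank = 0) {
  nt <- length(types)
  expand <- function(x, rule) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == nt, ncol(x) == nt)
      if (max(abs(x - t(x))) > 1e-9) stop("pair parameters must be symmetric")
      return(x)
    }
    v <- rep_len(x, nt)
    if (rule == "geom") outer(v, v, function(a, b) sqrt(a * b))
    else outer(v, v, function(a, b) (a + b) / 2)
  }
  A <- expand(A, "geom"); B <- expand(B, "arith"); C <- expand(C, "geom")
  if (any(B <= 0)) stop("exp-6 B parameters must be positive")
  dimnames(A) <- dimnames(B) <- dimnames(C) <- list(types, types)
  ff <- structure(list(
    types = types, A = A, B = B, C = C,
    cov_radii = cov_radii, vdw_radii = vdw_radii, rank = rank
  ), class = "force_field")
  cl <- exp6_clamp(ff)
  ff$rcat <- cl$rcat
  ff$fcat <- cl$fcat
  ff$clamp_slope <- 500 # kJ/mol/Angstrom, repulsive continuation below rcat
  # radius beyond which the exponential term is numerically zero
  ff$rexp <- ifelse(A > 0, log(pmax(A, 1e-300) / 1e-12) / B, 0)
  ff
}

# Location and value of the inner maximum of the exp-6 pair potential.
# Below it, -C r^-6 diverges to -infinity; the energy code continues the
# potential linearly upward from the inner maximum so minimizations cannot
# fall into the unphysical branch (Monte Carlo already rejects such contacts
# through the covalent-radius rule).
exp6_clamp <- function(ff) {
  nt <- length(ff$types)
  rcat <- matrix(0, nt, nt); fcat <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    A <- ff$A[i, j]; B <- ff$B[i, j]; C <- ff$C[i, j]
    if (A <= 0 || C <= 0) next
    g <- function(r) -A * B * exp(-B * r) + 6 * C / r^7 # derivative of pair fn
    rmid <- 7 / B
    if (g(rmid) <= 0) next # no inner maximum: monotone branch, nothing to clamp
    lo <- 1e-3
    while (g(lo) <= 0 && lo < rmid) lo <- lo * 2
    # g > 0 on the inner branch just above lo? inner root is where g crosses 0
    # from below as r decreases: g(r->0+) = +Inf, g(rmid) > 0 means the inner
    # max is below rmid only if g dips negative first; scan for a sign change
    rs <- seq(1e-2, rmid, length.out = 400)
    gs <- vapply(rs, g, 0)
    ix <- which(gs[-1] > 0 & gs[-length(gs)] <= 0)
    if (length(ix) == 0) next
    root <- stats::uniroot(g, c(rs[ix[1]], rs[ix[1] + 1]), tol = 1e-10)$root
    rcat[i, j] <- root
    fcat[i, j] <- A * exp(-B * root) - C / root^6
  }
  list(rcat = rcat, fcat = fcat)
}

#' Read a force field from its key-value text format
#'
#' Format (one directive per line, `#` comments):
#' \preformatted{
#' types C O H
#' pair C C 369743 3.60 2439.8
#' pair C O 305000 3.65 1300.0
#' radius O covalent 0.66 vdw 1.52
#' rank 0
#' }
#' Unlisted pairs are filled by combining rules from the homo-atomic pairs;
#' unlisted radii fall back to the built-in element tables.
#' @param path file path
#' @return a `force_field`
#' @export
read_forcefield <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  types <- NULL; pairs <- list(); rads <- list(); rank <- 0
  for (tk in toks) {
    switch(tk[1],
      types = { types <- tk[-1] },
      pair = {
        pairs[[length(pairs) + 1]] <- list(t1 = tk[2], t2 = tk[3],
                                           v = as.numeric(tk[4:6]))
      },
      radius = {
        kv <- tk[-(1:2)]
        r <- stats::setNames(as.numeric(kv[seq(2, length(kv), 2)]),
                             kv[seq(1, length(kv), 2)])
        rads[[tk[2]]] <- r
      },
      rank = { rank <- as.integer(tk[2]) },
      stop("unknown force-field directive: ", tk[1])
    )
  }
  if (is.null(types)) stop("force-field file declares no types")
  nt <- length(types)
  A <- B <- C <- matrix(NA_real_, nt, nt, dimnames = list(types, types))
  for (p in pairs) {
    i <- match(p$t1, types); j <- match(p$t2, types)
    if (is.na(i) || is.na(j)) stop("pair references undeclared type")
    A[i, j] <- A[j, i] <- p$v[1]
    B[i, j] <- B[j, i] <- p$v[2]
    C[i, j] <- C[j, i] <- p$v[3]
  }
  if (anyNA(diag(A))) stop("homo-atomic pair parameters required for all types")
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (is.na(A[i, j])) {
      A[i, j] <- sqrt(A[i, i] * A[j, j])
      B[i, j] <- (B[i, i] + B[j, j]) / 2
      C[i, j] <- sqrt(C[i, i] * C[j, j])
    }
  }
  cov <- COVALENT_RADII; vdw <- VDW_RADII
  for (el in names(rads)) {
    if ("covalent" %in% names(rads[[el]])) cov[el] <- rads[[el]][["covalent"]]
    if ("vdw" %in% names(rads[[el]])) vdw[el] <- rads[[el]][["vdw"]]
  }
  force_field(types, A, B, C, cov_radii = cov, vdw_radii = vdw, rank = rank)
}

#' Write a force field in the key-value text format
#' @param ff a `force_field`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_forcefield <- function(ff, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("types", paste(ff$types, collapse = " ")), con)
  nt <- length(ff$types)
  for (i in seq_len(nt)) for (j in i:nt) {
    writeLines(sprintf("pair %s %s %.10g %.10g %.10g", ff$types[i], ff$types[j],
                       ff$A[i, j], ff$B[i, j], ff$C[i, j]), con)
  }
  writeLines(sprintf("rank %d", ff$rank), con)
  invisible(path)
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("exp-6 force field: %d type(s) [%s], electrostatic rank %d\n",
              length(x$types), paste(x$types, collapse = ", "), x$rank))
  invisible(x)
}
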