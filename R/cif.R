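# Minimal CIF reader/writer for the subset the package produces and consumes:
# cell parameters, symmetry operators (_symmetry_equiv_pos_as_xyz), and
# fractional atom sites. Atom-site labels follow the convention
# <molname>.<instance>.<atomindex>, which lets a structure written by the
# package be reassembled into rigid-molecule placements on read (the molecule
# definitions themselves travel separately — CIF stores atoms, not bodies).

symop_to_xyz <- function(W, w) {
  axes <- c("x", "y", "z")
  comp <- function(row) {
    terms <- character(0)
    for (j in 1:3) {
      c_ <- W[row, j]
      if (abs(c_) > 1e-9) {
        sgn <- if (c_ > 0) "+" else "-"
        terms <- c(terms, paste0(sgn, axes[j]))
      }
    }
    tr <- w[row] %% 1
    if (abs(tr) > 1e-9) {
      fr <- c("1/2" = 0.5, "1/3" = 1 / 3, "2/3" = 2 / 3, "1/4" = 0.25,
              "3/4" = 0.75, "1/6" = 1 / 6, "5/6" = 5 / 6)
      nm <- names(fr)[which.min(abs(fr - tr))]
      if (abs(fr[[nm]] - tr) > 1e-6) nm <- format(tr)
      terms <- c(terms, paste0("+", nm))
    }
    s <- paste(terms, collapse = "")
    sub("^\\+", "", s)
  }
  paste(comp(1), comp(2), comp(3), sep = ",")
}

parse_symop_xyz <- function(txt) {
  comps <- strsplit(gsub("\\s", "", tolower(txt)), ",")[[1]]
  if (length(comps) != 3) stop("malformed symmetry operator: ", txt)
  W <- matrix(0, 3, 3)
  w <- numeric(3)
  for (i in 1:3) {
    expr <- comps[i]
    # split into signed terms
    expr <- gsub("-", "+-", expr)
    terms <- strsplit(expr, "\\+")[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      neg <- startsWith(tm, "-")
      body <- sub("^-", "", tm)
      if (body %in% c("x", "y", "z")) {
        j <- match(body, c("x", "y", "z"))
        W[i, j] <- W[i, j] + if (neg) -1 else 1
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        parts <- as.numeric(strsplit(body, "/")[[1]])
        w[i] <- w[i] + (if (neg) -1 else 1) * parts[1] / parts[2]
      } else if (grepl("^[0-9.]+$", body)) {
        w[i] <- w[i] + (if (neg) -1 else 1) * as.numeric(body)
      } else {
        stop("cannot parse symmetry term '", tm, "' in: ", txt)
      }
    }
  }
  list(W = W, w = w %% 1)
}

#' Write a crystal structure as CIF
#'
#' Cell, explicit symmetry operators, and the fractional coordinates of the
#' asymmetric unit's atoms (labels encode molecule name, placement index and
#' atom index, so [read_cif()] can rebuild placements given the molecule
#' set).
#' @param s a [crystal_structure()]
#' @param path output path
#' @param data_name CIF data block name
#' @return `path`, invisibly
#' @export
write_cif <- function(s, path, data_name = "xtalmc") {
  con <- file(path, "w"); on.exit(close(con))
  lat <- s$lattice
  out <- c(
    paste0("data_", data_name),
    sprintf("_cell_length_a %.6f", lat$a),
    sprintf("_cell_length_b %.6f", lat$b),
    sprintf("_cell_length_c %.6f", lat$c),
    sprintf("_cell_angle_alpha %.6f", lat$alpha),
    sprintf("_cell_angle_beta %.6f", lat$beta),
    sprintf("_cell_angle_gamma %.6f", lat$gamma),
    sprintf("_symmetry_space_group_name_H-M '%s'", s$setting$label),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    vapply(s$setting$ops, function(o) {
      sprintf("'%s'", symop_to_xyz(o$W, o$w))
    }, ""),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z"
  )
  A <- cell_matrix(lat)
  Ainv <- solve(A)
  for (ip in seq_along(s$placements)) {
    p <- s$placements[[ip]]
    m <- s$molecules[[p$mol]]
    R <- quat_to_matrix(p$quat)
    xyz <- (m$local * p$inv) %*% t(R)
    fr <- t(Ainv %*% t(xyz)) + matrix(p$frac, nrow(xyz), 3, byrow = TRUE)
    for (a in seq_len(nrow(fr))) {
      out <- c(out, sprintf("%s.%d.%d %s %.8f %.8f %.8f",
                            p$mol, ip, a, m$elements[a],
                            fr[a, 1], fr[a, 2], fr[a, 3]))
    }
  }
  writeLines(out, con)
  invisible(path)
}

#' Read a CIF file
#'
#' Parses cell, symmetry operators and fractional atom sites. When
#' `molecules` is supplied and the atom labels follow the
#' `<mol>.<placement>.<atom>` convention written by [write_cif()], the full
#' rigid-body placements are reconstructed (orientation by Kabsch
#' superposition onto the molecule's local frame). Otherwise a list of raw
#' sites is returned.
#'
#' @param path CIF file path
#' @param molecules optional named list of [rigid_molecule()]s for placement
#'   reconstruction
#' @param expand_p1 with `molecules`: return the structure with its read
#'   symmetry operators (`FALSE`, default) or expanded to P1 (`TRUE`)
#' @return a `crystal_structure` (with `molecules`) or a list with `lattice`,
#'   `ops`, `sites`
#' @export
read_cif <- function(path, molecules = NULL, expand_p1 = FALSE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  getval <- function(key) {
    ix <- grep(paste0("^", key, "\\b"), lines)
    if (!length(ix)) stop("CIF parse error: missing ", key)
    val <- sub(paste0("^", key, "\\s+"), "", lines[ix[1]])
    as.numeric(val)
  }
  lat <- lattice(getval("_cell_length_a"), getval("_cell_length_b"),
                 getval("_cell_length_c"), getval("_cell_angle_alpha"),
                 getval("_cell_angle_beta"), getval("_cell_angle_gamma"))
  # symmetry loop
  ops <- list(list(W = diag(3), w = c(0, 0, 0)))
  symix <- grep("^_symmetry_equiv_pos_as_xyz", lines)
  if (length(symix)) {
    ops <- list()
    i <- symix[1] + 1
    while (i <= length(lines) && !startsWith(lines[i], "_") &&
           !startsWith(lines[i], "loop_") && !startsWith(lines[i], "data_")) {
      txt <- gsub("^'|'$", "", lines[i])
      ops[[length(ops) + 1]] <- parse_symop_xyz(txt)
      i <- i + 1
    }
    if (!length(ops)) stop("CIF parse error: empty symmetry loop")
  }
  # atom site loop: find the loop_ that declares _atom_site_fract_x
  aix <- grep("^_atom_site_fract_x", lines)
  if (!length(aix)) stop("CIF parse error: no atom sites")
  # header block around aix
  hstart <- aix[1]
  while (hstart > 1 && startsWith(lines[hstart - 1], "_atom_site")) {
    hstart <- hstart - 1
  }
  hend <- aix[1]
  while (hend < length(lines) && startsWith(lines[hend + 1], "_atom_site")) {
    hend <- hend + 1
  }
  headers <- lines[hstart:hend]
  rows <- list()
  i <- hend + 1
  while (i <= length(lines) && !startsWith(lines[i], "_") &&
         !startsWith(lines[i], "loop_") && !startsWith(lines[i], "data_")) {
    rows[[length(rows) + 1]] <- strsplit(lines[i], "\\s+")[[1]]
    i <- i + 1
  }
  if (!length(rows)) stop("CIF parse error: empty atom site loop")
  ncol_ok <- vapply(rows, length, 0L) >= length(headers)
  if (!all(ncol_ok)) stop("CIF parse error: malformed atom site row at line ",
                          which(!ncol_ok)[1])
  col <- function(key) match(key, headers)
  lab_c <- col("_atom_site_label")
  el_c <- col("_atom_site_type_symbol")
  fx <- col("_atom_site_fract_x"); fy <- col("_atom_site_fract_y")
  fz <- col("_atom_site_fract_z")
  sites <- data.frame(
    label = vapply(rows, `[[`, "", lab_c),
    element = vapply(rows, `[[`, "", el_c),
    x = vapply(rows, function(r) as.numeric(r[fx]), 0),
    y = vapply(rows, function(r) as.numeric(r[fy]), 0),
    z = vapply(rows, function(r) as.numeric(r[fz]), 0)
  )
  label_ix <- grep("^_symmetry_space_group_name", lines)
  sg_label <- if (length(label_ix)) {
    gsub("'", "", sub("^\\S+\\s+", "", lines[label_ix[1]]))
  } else "P1"
  if (is.null(molecules)) {
    return(list(lattice = lat, ops = ops, sites = sites, label = sg_label))
  }
  # reconstruct placements from the label convention
  parts <- strsplit(sites$label, "\\.")
  if (any(vapply(parts, length, 0L) != 3)) {
    stop("atom labels do not follow the <mol>.<placement>.<atom> convention; ",
         "cannot rebuild placements")
  }
  molname <- vapply(parts, `[[`, "", 1)
  pid <- as.integer(vapply(parts, `[[`, "", 2))
  aid <- as.integer(vapply(parts, `[[`, "", 3))
  A <- cell_matrix(lat)
  placements <- list()
  for (ip in sort(unique(pid))) {
    sel <- pid == ip
    nm <- unique(molname[sel])
    if (length(nm) != 1 || !nm %in% names(molecules)) {
      stop("placement ", ip, " references unknown molecule")
    }
    m <- molecules[[nm]]
    ord <- order(aid[sel])
    fr <- as.matrix(sites[sel, c("x", "y", "z")])[ord, , drop = FALSE]
    cart <- fr %*% t(A)
    com <- colSums(cart * m$masses) / sum(m$masses)
    loc <- sweep(cart, 2, com)
    if (nrow(loc) >= 2) {
      fit <- kabsch(m$local, loc)
      inv <- 1L
      if (fit$rmsd > 1e-3) {
        fit_inv <- kabsch(-m$local, loc)
        if (fit_inv$rmsd < fit$rmsd) { fit <- fit_inv; inv <- -1L }
      }
      q <- quat_from_matrix(fit$R)
    } else {
      q <- c(1, 0, 0, 0); inv <- 1L
    }
    placements[[length(placements) + 1]] <- placement(
      nm, as.numeric(solve(A) %*% com), q, inv)
  }
  setting <- tryCatch(builtin_setting(sg_label), error = function(e) NULL)
  if (is.null(setting)) {
    setting <- spacegroup_setting(sg_label, ops)
  }
  s <- crystal_structure(lat, molecules, placements, setting = setting)
  if (expand_p1) s <- as_p1(s)
  s
}
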