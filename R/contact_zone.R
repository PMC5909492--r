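## Contact-zone construction and sliding-cylinder diversity maps.

#' Orient a two-subunit complex along the Z axis
#'
#' Applies one rigid transform to both subunits so that the axis through the
#' two centroids is the Z axis (subunit `b` above), the origin is the
#' midpoint between centroids, and, for determinism, the first principal
#' axis of the pooled atoms is rotated about Z so that its XY projection
#' points along +X.
#'
#' @param a,b `protein_structure` objects of the two subunits.
#' @return list with the transformed `a` and `b`, plus the applied
#'   `rotation` and `shift`.
#' @export
orient_complex <- function(a, b) {
  ca <- centroid(a); cb <- centroid(b)
  axis <- cb - ca
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) stop("subunit centroids coincide; cannot define the complex axis")
  ez <- axis / len
  ## orthonormal frame with ez as third axis
  ref <- if (abs(ez[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ex <- ref - sum(ref * ez) * ez
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  R1 <- rbind(ex, ey, ez)                      # world -> complex frame
  mid <- (ca + cb) / 2
  rot_all <- function(R) {
    sh <- -as.vector(R %*% mid)
    list(a = transform_structure(a, R, sh), b = transform_structure(b, R, sh),
         rotation = R, shift = sh)
  }
  o <- rot_all(R1)
  ## fix the XY orientation from the pooled first principal axis
  xyz <- rbind(coords(o$a), coords(o$b))
  pc1 <- eigen(stats::cov(xyz), symmetric = TRUE)$vectors[, 1]
  ## eigenvector sign is arbitrary: orient pc1 by the third moment of the
  ## atom projections so the frame is reproducible under rigid pre-motions
  t3 <- sum((scale(xyz %*% pc1, scale = FALSE))^3)
  if (t3 < 0) pc1 <- -pc1
  lat <- sqrt(pc1[1]^2 + pc1[2]^2)
  if (lat > 1e-9) {
    cth <- pc1[1] / lat; sth <- pc1[2] / lat
    Rz <- rbind(c(cth, sth, 0), c(-sth, cth, 0), c(0, 0, 1))
    o <- rot_all(Rz %*% R1)
  }
  o
}

#' Build the gridded midpoint contact surface between two subunits
#'
#' On a square XY grid, each column's z value is the midpoint between the
#' highest atom of the lower subunit and the lowest atom of the upper
#' subunit among atoms within `capture` lateral distance of the column.
#' Nodes where either side has no atoms, where the subunits interpenetrate,
#' or where the vertical protein-protein gap exceeds `gap_threshold` are
#' undefined.
#'
#' @param a,b oriented `protein_structure` subunits (see [orient_complex()]).
#' @param step grid step in Angstrom (default 1).
#' @param gap_threshold maximal vertical gap in Angstrom (default 8).
#' @param capture lateral capture radius for the vertical ray, default
#'   `step * sqrt(2) / 2` so every atom is seen by at least one column.
#' @return object of class `contact_surface`: data.frame `nodes` with
#'   `x`, `y`, `z`, `lower`, `upper`, `gap`, `defined`, plus `step`,
#'   `gap_threshold` and the label of the upper subunit.
#' @export
build_surface <- function(a, b, step = 1, gap_threshold = 8,
                          capture = step * sqrt(2) / 2) {
  xa <- coords(a); xb <- coords(b)
  if (mean(xa[, 3]) <= mean(xb[, 3])) { lo <- xa; hi <- xb; upper <- b$label }
  else { lo <- xb; hi <- xa; upper <- a$label }
  all_xy <- rbind(lo[, 1:2, drop = FALSE], hi[, 1:2, drop = FALSE])
  gx <- seq(floor(min(all_xy[, 1])), ceiling(max(all_xy[, 1])), by = step)
  gy <- seq(floor(min(all_xy[, 2])), ceiling(max(all_xy[, 2])), by = step)
  nodes <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(nodes)
  lower <- upper_z <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dlo <- sqrt((lo[, 1] - nodes$x[i])^2 + (lo[, 2] - nodes$y[i])^2)
    dhi <- sqrt((hi[, 1] - nodes$x[i])^2 + (hi[, 2] - nodes$y[i])^2)
    if (any(dlo <= capture)) lower[i] <- max(lo[dlo <= capture, 3])
    if (any(dhi <= capture)) upper_z[i] <- min(hi[dhi <= capture, 3])
  }
  gap <- upper_z - lower
  defined <- !is.na(gap) & gap > 0 & gap <= gap_threshold
  z <- ifelse(defined, (lower + upper_z) / 2, NA_real_)
  if (!any(defined))
    stop("no contact-zone nodes defined: subunits are not in contact ",
         "at gap_threshold = ", gap_threshold, " A")
  nodes$z <- z; nodes$lower <- lower; nodes$upper <- upper_z
  nodes$gap <- gap; nodes$defined <- defined
  structure(list(nodes = nodes, step = step, gap_threshold = gap_threshold,
                 capture = capture, upper_subunit = upper),
            class = "contact_surface")
}

#' @export
print.contact_surface <- function(x, ...) {
  cat(sprintf("<contact_surface> %d/%d nodes defined, step %g A, gap <= %g A (upper: %s)\n",
              sum(x$nodes$defined), nrow(x$nodes), x$step, x$gap_threshold,
              if (nzchar(x$upper_subunit)) x$upper_subunit else "?"))
  invisible(x)
}

#' @export
plot.contact_surface <- function(x, ...) {
  nd <- x$nodes[x$nodes$defined, ]
  plot(nd$x, nd$y, pch = 15, col = gray(1 - (nd$z - min(nd$z)) /
         max(1e-9, diff(range(nd$z)))), xlab = "x (A)", ylab = "y (A)",
       asp = 1, main = "contact zone (z as gray level)", ...)
  invisible(x)
}

#' Mean subunit size
#'
#' Mean distance of atoms to the subunit centroid; used as the default
#' bandwidth scale of the sliding cylinder (`h = s^2 / 2`).
#'
#' @param s a `protein_structure`.
#' @export
mean_subunit_size <- function(s) {
  xyz <- coords(s)
  mean(sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
}

#' Residue weights inside one sliding-cylinder neighbourhood
#'
#' The cylinder has radius `r`, axis through the node parallel to Z, and is
#' unbounded vertically.  For every residue with at least one atom inside,
#' `f` is the fraction of its atoms inside, `d` its mean 3D atom distance to
#' the node centre C, and the Gauss-decay weight is
#' `w = f * exp(-(d - min_j d_j)^2 / h)`.
#'
#' @param s a `protein_structure` (one subunit, oriented frame).
#' @param node length-3 numeric: the surface node (x, y, z).
#' @param r cylinder radius in Angstrom (default 4).
#' @param h bandwidth in squared Angstrom; default `mean_subunit_size(s)^2/2`.
#' @return data.frame with `res_key`, `f`, `d`, `w` (possibly 0 rows).
#' @export
cylinder_neighborhood <- function(s, node, r = 4, h = NULL) {
  if (is.null(h)) h <- mean_subunit_size(s)^2 / 2
  a <- s$atoms
  lat <- sqrt((a$x - node[1])^2 + (a$y - node[2])^2)
  inside <- lat <= r
  if (!any(inside))
    return(data.frame(res_key = character(0), f = numeric(0),
                      d = numeric(0), w = numeric(0)))
  keys <- unique(a$res_key[inside])
  d3 <- sqrt((a$x - node[1])^2 + (a$y - node[2])^2 + (a$z - node[3])^2)
  f <- d <- numeric(length(keys))
  for (i in seq_along(keys)) {
    sel <- a$res_key == keys[i]
    f[i] <- sum(sel & inside) / sum(sel)
    d[i] <- mean(d3[sel])
  }
  w <- f * exp(-(d - min(d))^2 / h)
  data.frame(res_key = keys, f = f, d = d, w = w, stringsAsFactors = FALSE)
}

#' Sliding-cylinder diversity map of one subunit over the contact surface
#'
#' For every defined surface node, collects the subunit residues inside a
#' vertical cylinder of radius `r` centred at the node, maps them to
#' alignment columns, and evaluates the residue-weighted diversity: either
#' pi ([pi_sites()]) or dN/dS ([dnds_region()]).  Residues without an
#' alignment column are dropped (one warning).  Nodes with an empty
#' neighbourhood stay undefined.
#'
#' @param surface a `contact_surface`.
#' @param s the subunit `protein_structure` (oriented frame).
#' @param aln the subunit's `population_alignment`.
#' @param map a `residue_column_map` for `s` and `aln`.
#' @param measure "pi" or "dnds".
#' @param r cylinder radius (default 4 A).
#' @param h bandwidth, default `mean_subunit_size(s)^2 / 2`.
#' @return object of class `diversity_map`: per-node `value` (NA where
#'   undefined), `status` ("ok", "undefined", and for dN/dS the sentinels
#'   "undefined-high"/"no-variation"), the surface, measure and label.
#' @export
diversity_map <- function(surface, s, aln, map, measure = c("pi", "dnds"),
                          r = 4, h = NULL) {
  measure <- match.arg(measure)
  if (is.null(h)) h <- mean_subunit_size(s)^2 / 2
  col_of <- stats::setNames(map$pairs$column, map$pairs$res_key)
  nd <- surface$nodes
  n <- nrow(nd)
  value <- rep(NA_real_, n)
  status <- rep("undefined", n)
  warned <- FALSE
  for (i in which(nd$defined)) {
    nb <- cylinder_neighborhood(s, c(nd$x[i], nd$y[i], nd$z[i]), r = r, h = h)
    if (!nrow(nb)) next
    mapped <- nb$res_key %in% names(col_of)
    if (any(!mapped) && !warned) {
      warning(sum(!mapped), " cylinder residues have no alignment column; dropped")
      warned <- TRUE
    }
    nb <- nb[mapped, , drop = FALSE]
    if (!nrow(nb)) next
    cols <- unname(col_of[nb$res_key])
    if (measure == "pi") {
      value[i] <- pi_sites(aln, cols, nb$w)
      status[i] <- "ok"
    } else {
      est <- dnds_region(aln, cols, nb$w)
      value[i] <- est$ratio
      status[i] <- est$status
    }
  }
  if (!any(status != "undefined"))
    stop("no surface node obtained a diversity value")
  structure(list(value = value, status = status, surface = surface,
                 measure = measure, subunit = s$label, r = r, h = h),
            class = "diversity_map")
}

#' @export
print.diversity_map <- function(x, ...) {
  ok <- x$status != "undefined"
  cat(sprintf("<diversity_map> %s of %s: %d nodes, range [%.4g, %.4g]\n",
              x$measure, if (nzchar(x$subunit)) x$subunit else "subunit",
              sum(ok), min(x$value[ok], na.rm = TRUE),
              max(x$value[ok], na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.diversity_map <- function(x, ...) {
  nd <- x$surface$nodes
  ok <- which(x$status == "ok")
  v <- x$value[ok]
  rng <- diff(range(v)); if (rng == 0) rng <- 1
  plot(nd$x[ok], nd$y[ok], pch = 15,
       col = gray(1 - (v - min(v)) / rng), asp = 1,
       xlab = "x (A)", ylab = "y (A)",
       main = paste(x$measure, "map:", x$subunit), ...)
  invisible(x)
}

#' Export a diversity map (or surface) as TSV
#'
#' Columns x, y, z, value, status for defined nodes.
#'
#' @param x a `diversity_map` or `contact_surface`.
#' @param path output TSV path.
#' @export
write_map_tsv <- function(x, path) {
  if (inherits(x, "diversity_map")) {
    nd <- x$surface$nodes
    out <- data.frame(x = nd$x, y = nd$y, z = nd$z,
                      value = x$value, status = x$status)[nd$defined, ]
  } else {
    nd <- x$nodes
    out <- nd[nd$defined, c("x", "y", "z", "gap")]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
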