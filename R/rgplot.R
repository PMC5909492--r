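## RG-plots: two diversity maps as red/green channels, four-way filter,
## area fractions, ligand projection and colocalization.

same_surface <- function(s1, s2) {
  isTRUE(all.equal(s1$nodes[, c("x", "y")], s2$nodes[, c("x", "y")])) &&
    identical(s1$nodes$defined, s2$nodes$defined)
}

channel_intensity <- function(map) {
  v <- map$value
  if (map$measure == "dnds") {
    ## sentinel-aware: no synonymous variation saturates the channel,
    ## no variation at all means zero intensity
    v[map$status == "undefined-high"] <- Inf
    v[map$status == "no-variation"] <- 0
  }
  num <- v[is.finite(v)]
  mx <- if (length(num) && max(num) > 0) max(num) else 1
  out <- v / mx
  out[is.infinite(v)] <- 1
  pmin(pmax(out, 0), 1)
}

#' Normalise two diversity maps into red/green intensities
#'
#' Each channel is divided by its own maximum over defined numeric nodes, so
#' intensities lie in [0, 1] and are invariant to positive rescaling of the
#' raw maps.  An all-zero channel stays zero.  dN/dS sentinels map to
#' intensity 1 ("undefined-high") and 0 ("no-variation").
#'
#' @param mapR,mapG `diversity_map` objects on the same surface.
#' @return list with `R`, `G` intensity vectors (NA on undefined nodes) and
#'   the shared `surface`.
#' @export
normalize_channels <- function(mapR, mapG) {
  if (!same_surface(mapR$surface, mapG$surface))
    stop("the two maps are not on the same contact surface")
  list(R = channel_intensity(mapR), G = channel_intensity(mapG),
       surface = mapR$surface)
}

#' Four-way RG classification of the contact zone
#'
#' Precedence: black (both intensities below `black_frac`), then green
#' (G > ratio * R), then red (R > ratio * G), remainder yellow.  Black marks
#' mutual conservatism, yellow mutual polymorphism, red/green one-sided
#' polymorphism.
#'
#' @param channels list from [normalize_channels()] (or a list with `R`,
#'   `G`, `surface`).
#' @param black_frac mutual-conservatism intensity cutoff (default 0.2).
#' @param ratio one-sidedness ratio (default 2).
#' @return object of class `rg_classification`: per-node `label` (NA on
#'   undefined nodes), intensities, the surface and the filter parameters.
#' @export
classify_rg <- function(channels, black_frac = 0.2, ratio = 2) {
  R <- channels$R; G <- channels$G
  ok <- !is.na(R) & !is.na(G)
  lab <- rep(NA_character_, length(R))
  lab[ok] <- "yellow"
  lab[ok & R > ratio * G] <- "red"
  lab[ok & G > ratio * R] <- "green"
  lab[ok & R < black_frac & G < black_frac] <- "black"
  structure(list(label = lab, R = R, G = G, surface = channels$surface,
                 black_frac = black_frac, ratio = ratio),
            class = "rg_classification")
}

#' @export
print.rg_classification <- function(x, ...) {
  fr <- area_fractions(x)
  cat("<rg_classification> ", sum(!is.na(x$label)), " nodes: ",
      paste(sprintf("%s %.1f%%", names(fr), fr), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Area fractions of the four RG classes
#'
#' @param cls an `rg_classification`.
#' @return named numeric vector of percentages for black, yellow, red,
#'   green, plus `black_yellow` (mutual zones combined); the four class
#'   entries sum to 100.
#' @export
area_fractions <- function(cls) {
  lab <- cls$label[!is.na(cls$label)]
  if (!length(lab)) stop("classification has no defined nodes")
  lev <- c("black", "yellow", "red", "green")
  pc <- 100 * vapply(lev, function(l) mean(lab == l), 0)
  c(pc, black_yellow = unname(pc["black"] + pc["yellow"]))
}

#' Project a ligand onto the contact surface
#'
#' A defined node is included iff some ligand atom lies within `capture`
#' lateral (XY) distance of it.
#'
#' @param ligand a `protein_structure` in the oriented frame.
#' @param surface a `contact_surface`.
#' @param capture lateral capture distance, default the grid step.
#' @return integer vector of node indices (rows of `surface$nodes`); empty
#'   with a warning when the ligand misses the grid.
#' @export
project_ligand <- function(ligand, surface, capture = surface$step) {
  xy <- coords(ligand)[, 1:2, drop = FALSE]
  nd <- surface$nodes
  idx <- which(nd$defined)
  hit <- vapply(idx, function(i) {
    any((xy[, 1] - nd$x[i])^2 + (xy[, 2] - nd$y[i])^2 <= capture^2)
  }, NA)
  out <- idx[hit]
  if (!length(out)) warning("ligand projects onto no defined surface node")
  out
}

#' Class composition of a projected node set
#'
#' @param cls an `rg_classification`.
#' @param nodes node indices, e.g. from [project_ligand()]; indices outside
#'   the defined surface are dropped with a warning.
#' @return named fractions over the projected nodes (sum 1).
#' @export
colocalization <- function(cls, nodes) {
  if (!length(nodes)) stop("empty node set")
  ok <- nodes[!is.na(cls$label[nodes])]
  if (length(ok) < length(nodes))
    warning(length(nodes) - length(ok), " projected nodes are undefined; dropped")
  if (!length(ok)) stop("no projected node lies on the defined surface")
  lab <- cls$label[ok]
  lev <- c("black", "yellow", "red", "green")
  vapply(lev, function(l) mean(lab == l), 0)
}

rg_palette <- c(black = "#000000", yellow = "#FFD700",
                red = "#FF0000", green = "#00B000")

#' Plot an RG classification (filtered plot) or raw RG image
#'
#' @param x an `rg_classification`.
#' @param raw plot raw RG intensities instead of filtered labels.
#' @param ligand_nodes optional node indices to outline (ligand projection).
#' @param ... passed to `plot`.
#' @export
plot.rg_classification <- function(x, raw = FALSE, ligand_nodes = NULL, ...) {
  nd <- x$surface$nodes
  ok <- which(!is.na(x$label))
  colv <- if (raw) rgb(x$R[ok], x$G[ok], 0) else rg_palette[x$label[ok]]
  plot(nd$x[ok], nd$y[ok], pch = 15, col = colv, asp = 1,
       xlab = "x (A)", ylab = "y (A)",
       main = if (raw) "RG-plot (raw)" else "RG-plot (filtered)", ...)
  if (length(ligand_nodes))
    points(nd$x[ligand_nodes], nd$y[ligand_nodes], pch = 0, cex = 1.3,
           col = "blue")
  invisible(x)
}

#' Export an RG classification as TSV (x, y, R, G, label)
#'
#' @param cls an `rg_classification`.
#' @param path output path.
#' @export
write_rg_tsv <- function(cls, path) {
  nd <- cls$surface$nodes
  ok <- !is.na(cls$label)
  out <- data.frame(x = nd$x[ok], y = nd$y[ok], R = cls$R[ok], G = cls$G[ok],
                    label = cls$label[ok])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
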