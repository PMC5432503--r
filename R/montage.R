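# Electrode montages: names, 2-D scalp coordinates, adjacency graph.

# Idealised top-down 2-D projection (nose up, x = right, y = anterior) of the
# 10-20/10-10 positions used here. Circumference electrodes sit on the unit
# circle; the low posterior row (P9/P10, PO9/PO10) sits outside it, as in
# standard extended layouts.
.montage_coords <- local({
  deg <- function(a) a * pi / 180
  circ <- function(a) c(sin(deg(a)), cos(deg(a)))  # a = azimuth cw from nose
  pos <- list(
    Fpz = circ(0),
    F7  = circ(-54), F8 = circ(54),
    T7  = circ(-90), T8 = circ(90),
    P7  = circ(-126), P8 = circ(126),
    PO7 = circ(-144), PO8 = circ(144),
    Oz  = circ(180),
    Fz  = c(0, 0.5), Cz = c(0, 0), Pz = c(0, -0.5),
    F3  = c(-0.39, 0.53), F4 = c(0.39, 0.53),
    FC5 = c(-0.69, 0.28), FC6 = c(0.69, 0.28),
    C3  = c(-0.5, 0), C4 = c(0.5, 0),
    CP5 = c(-0.69, -0.28), CP6 = c(0.69, -0.28),
    P3  = c(-0.39, -0.53), P4 = c(0.39, -0.53),
    P9  = 1.25 * circ(-126), P10  = 1.25 * circ(126),
    PO9 = 1.25 * circ(-144), PO10 = 1.25 * circ(144)
  )
  m <- do.call(rbind, pos)
  colnames(m) <- c("x", "y")
  m
})

.exp1_names <- c("Fpz", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC6", "T7",
                 "C3", "Cz", "C4", "T8", "CP5", "CP6", "P7", "P3", "Pz",
                 "P4", "P8", "PO7", "PO8", "Oz")
.exp2_names <- c(.exp1_names, "P9", "P10", "PO9", "PO10")

#' Construct an electrode montage
#'
#' Builds the set of named electrodes with 2-D scalp coordinates and a
#' symmetric adjacency graph (electrodes closer than `neighbour_dist` are
#' neighbours). Two concrete layouts are provided, matching the 23-electrode
#' and 27-electrode recording setups used for the four-position and
#' eight-position search display experiments, plus a generic ring layout for
#' toy examples.
#'
#' @param layout one of `"exp1_23"` (23 scalp sites), `"exp2_27"` (the same
#'   plus low posterior sites P9/P10 and PO9/PO10) or `"ring_n"` (n electrodes
#'   evenly spaced on a circle).
#' @param n electrode count, only used for `"ring_n"`.
#' @param neighbour_dist electrodes within this Euclidean distance (head-radius
#'   units) are adjacent.
#' @return an object of class `eeg_montage`: a list with `names`, an
#'   `n x 2` coordinate matrix `coords`, and a symmetric logical adjacency
#'   matrix `adjacency` (no self-loops).
#' @examples
#' m <- make_montage("exp2_27")
#' nrow(m$coords)
#' @export
make_montage <- function(layout = c("exp1_23", "exp2_27", "ring_n"), n = NULL,
                         neighbour_dist = 0.6) {
  if (!is.character(layout) || length(layout) != 1L ||
      !layout %in% c("exp1_23", "exp2_27", "ring_n"))
    stopf("unknown montage layout '%s'", as.character(layout)[1])
  if (layout == "ring_n") {
    if (!is_count(n, min = 2))
      stopf("ring_n layout needs an electrode count n >= 2")
    ang <- 2 * pi * (seq_len(n) - 1) / n
    coords <- cbind(x = sin(ang), y = cos(ang))
    nms <- paste0("E", seq_len(n))
    # keep immediate ring neighbours adjacent regardless of n
    neighbour_dist <- max(neighbour_dist, 2.05 * sin(pi / n))
  } else {
    nms <- if (layout == "exp1_23") .exp1_names else .exp2_names
    coords <- .montage_coords[nms, , drop = FALSE]
  }
  rownames(coords) <- nms
  d <- as.matrix(stats::dist(coords))
  adjacency <- d <= neighbour_dist & d > 0
  structure(list(names = nms, coords = coords, adjacency = adjacency,
                 neighbour_dist = neighbour_dist, layout = layout),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> layout %s: %d electrodes, %d adjacency edges\n",
              x$layout, length(x$names), sum(x$adjacency) / 2))
  invisible(x)
}

#' Write / read a montage as CSV (name,x,y)
#'
#' @param montage an `eeg_montage`.
#' @param path CSV file path.
#' @return `read_montage` returns an `eeg_montage` rebuilt from the
#'   coordinates (adjacency recomputed with `neighbour_dist`).
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(name = montage$names,
                   x = montage$coords[, "x"], y = montage$coords[, "y"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @param neighbour_dist adjacency distance threshold.
#' @export
read_montage <- function(path, neighbour_dist = 0.6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y")
  if (!all(need %in% names(df)))
    stopf("montage CSV must have columns name,x,y; missing: %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  coords <- cbind(x = df$x, y = df$y)
  rownames(coords) <- df$name
  d <- as.matrix(stats::dist(coords))
  structure(list(names = df$name, coords = coords,
                 adjacency = d <= neighbour_dist & d > 0,
                 neighbour_dist = neighbour_dist, layout = "custom"),
            class = "eeg_montage")
}
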