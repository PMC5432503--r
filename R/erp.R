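# Condition-balanced ERP averaging and the N2pc contralateral-minus-
# ipsilateral difference waveform.

#' Balanced ERP average
#'
#' Averages trials within each design cell first, then averages the cell
#' means with equal weight, so that unequal cell sizes (e.g. digit vs letter
#' targets, first vs second display) do not bias the ERP.
#'
#' @param epochs an `eeg_epochs`.
#' @param cells per-trial grouping tags (factor/character/integer); trials
#'   sharing a tag form one cell. Default: a single cell (plain mean).
#' @return an object of class `eeg_erp`: electrodes x samples matrix
#'   `values`, `times`, `electrodes`, per-cell counts `n_per_cell`, and a
#'   `condition` tag.
#' @export
balanced_erp <- function(epochs, cells = NULL, condition = NA_character_) {
  n <- n_trials(epochs)
  if (is.null(cells)) cells <- rep(1L, n)
  if (length(cells) != n) stopf("cells must have one tag per trial")
  cells <- as.factor(cells)
  counts <- table(cells)
  if (any(counts == 0))
    stopf("empty ERP cell(s): %s",
          paste(names(counts)[counts == 0], collapse = ", "))
  cellmeans <- lapply(levels(cells), function(lv) {
    idx <- which(cells == lv)
    apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  })
  values <- Reduce(`+`, cellmeans) / length(cellmeans)
  rownames(values) <- epochs$electrodes
  structure(list(values = values, times = epochs$times,
                 electrodes = epochs$electrodes,
                 n_per_cell = as.integer(counts), condition = condition),
            class = "eeg_erp")
}

#' @export
print.eeg_erp <- function(x, ...) {
  cat(sprintf("<eeg_erp> '%s': %d electrodes x %d samples, cells n = %s\n",
              x$condition, nrow(x$values), ncol(x$values),
              paste(x$n_per_cell, collapse = "/")))
  invisible(x)
}

#' N2pc difference wave
#'
#' Computes the contralateral-minus-ipsilateral difference at a lateral
#' posterior electrode pair (conventionally PO7/PO8): the mean of
#' right-electrode-minus-left-electrode for left-hemifield targets and
#' left-minus-right for right-hemifield targets, per time sample.
#'
#' @param erp_left_target `eeg_erp` for targets in the left hemifield.
#' @param erp_right_target `eeg_erp` for targets in the right hemifield.
#' @param pair (left, right) electrode names; default `c("PO7", "PO8")`.
#' @return an object of class `eeg_diffwave`: per-sample `values` (uV),
#'   `times`, and the `electrode_pair`.
#' @export
n2pc <- function(erp_left_target, erp_right_target, pair = c("PO7", "PO8")) {
  for (e in list(erp_left_target, erp_right_target))
    if (!all(pair %in% e$electrodes))
      stopf("electrode(s) %s missing from ERP",
            paste(setdiff(pair, e$electrodes), collapse = ", "))
  if (!identical(erp_left_target$times, erp_right_target$times))
    stopf("ERPs have mismatching time axes")
  l <- pair[1]; r <- pair[2]
  contra_left <- erp_left_target$values[r, ] - erp_left_target$values[l, ]
  contra_right <- erp_right_target$values[l, ] - erp_right_target$values[r, ]
  structure(list(values = (contra_left + contra_right) / 2,
                 times = erp_left_target$times, electrode_pair = pair),
            class = "eeg_diffwave")
}

#' @export
print.eeg_diffwave <- function(x, ...) {
  cat(sprintf("<eeg_diffwave> %s-%s contra-ipsi, %d samples\n",
              x$electrode_pair[1], x$electrode_pair[2], length(x$values)))
  invisible(x)
}

#' N2pc from labelled epochs
#'
#' Convenience wrapper: splits trials into left- and right-hemifield target
#' sets by label, forms balanced ERPs and calls [n2pc()]. Labels whose
#' position angles lie on the vertical meridian (0 or 180 degrees) are
#' refused — the N2pc is undefined for midline targets because it relies on
#' the contralateral/ipsilateral hemispheric difference.
#'
#' @param epochs an `eeg_epochs` whose `meta$angle` (degrees clockwise from
#'   top) is populated, or pass `angles` explicitly per label.
#' @param left_labels,right_labels label values assigned to the left/right
#'   hemifield sets.
#' @param angles optional named vector mapping label -> angle (degrees).
#' @param pair electrode pair, default PO7/PO8.
#' @param cells optional balancing tags passed to [balanced_erp()].
#' @return an `eeg_diffwave`.
#' @export
n2pc_from_epochs <- function(epochs, left_labels, right_labels,
                             angles = NULL, pair = c("PO7", "PO8"),
                             cells = NULL) {
  labs <- c(left_labels, right_labels)
  if (is.null(angles) && !is.null(epochs$meta$angle))
    angles <- stats::setNames(
      epochs$meta$angle[match(labs, epochs$labels)], labs)
  if (!is.null(angles)) {
    a <- angles[as.character(labs)] %% 360
    bad <- labs[!is.na(a) & (a %% 180) == 0]
    if (length(bad))
      stopf(paste0("label(s) %s lie on the vertical meridian; the N2pc is ",
                   "undefined for non-lateralized targets"),
            paste(bad, collapse = ", "))
  }
  pick <- function(which_labels) {
    idx <- epochs$labels %in% which_labels
    if (!any(idx)) stopf("no trials with labels %s", toString(which_labels))
    balanced_erp(subset_trials(epochs, idx),
                 cells = if (is.null(cells)) NULL else cells[idx])
  }
  n2pc(pick(left_labels), pick(right_labels), pair = pair)
}

#' Elevation pairing table for per-elevation N2pcs
#'
#' Left/right hemifield label pairs at matched vertical elevation for the
#' eight-position display (positions clockwise from upper right): upper
#' (8 vs 1), upper-middle (7 vs 2), lower-middle (6 vs 3), lower (5 vs 4).
#' Shipped as data so analyses can iterate over rows rather than hard-coding
#' the pairing.
#'
#' @return a data.frame with columns `elevation`, `left`, `right`.
#' @export
elevation_pairs <- function() {
  data.frame(elevation = c("upper", "upper-middle", "lower-middle", "lower"),
             left = c(8L, 7L, 6L, 5L), right = c(1L, 2L, 3L, 4L))
}

#' Export a difference wave as tidy CSV
#'
#' @param wave an `eeg_diffwave`.
#' @param path CSV path.
#' @param condition condition tag written per row.
#' @export
write_diffwave <- function(wave, path, condition = "n2pc") {
  utils::write.csv(data.frame(time_ms = wave$times, value_uv = wave$values,
                              condition = condition),
                   path, row.names = FALSE)
  invisible(path)
}
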