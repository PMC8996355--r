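# Registration-quality metrics: label overlap (Dice), Jacobian-determinant
# folding statistics within a region mask, and direction-wise evaluation of
# a fitted registration.

#' Dice overlap between two label maps
#'
#' Per label `k`: `2|A∩B| / (|A| + |B|)`; the mean is the unweighted
#' average over the requested labels. Labels absent from both maps are
#' excluded from the mean.
#'
#' @param warped,reference integer 3-d arrays of identical shape
#'   (0 = background).
#' @param labels label values to score; default: all nonzero labels present
#'   in either map.
#' @return list with `per_label` (named numeric) and `mean`.
#' @export
dice_scores <- function(warped, reference, labels = NULL) {
  if (!identical(dim(warped), dim(reference)))
    stop("label maps must have identical shape", call. = FALSE)
  if (is.null(labels))
    labels <- sort(unique(c(warped[warped != 0], reference[reference != 0])))
  if (length(labels) == 0L) stop("empty label list", call. = FALSE)
  per <- vapply(labels, function(k) {
    a <- warped == k; b <- reference == k
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0L) return(NA_real_)
    2 * sum(a & b) / (na + nb)
  }, 0)
  names(per) <- as.character(labels)
  list(per_label = per, mean = mean(per, na.rm = TRUE))
}

#' Folding statistics of a displacement field
#'
#' Counts voxels inside the mask whose Jacobian determinant of
#' `x -> x + u(x)` is non-positive, the operational criterion for a
#' non-diffeomorphic (folded) deformation.
#'
#' @param u displacement field `(n1, n2, n3, 3)`.
#' @param mask logical or 0/1 3-d array (e.g. the nonzero support of the
#'   skull-stripped fixed image); non-empty.
#' @return list with `count` and `percent` (100 * count / mask voxels).
#' @export
folding_stats <- function(u, mask) {
  J <- jacobian_determinant(u)
  if (!identical(dim(J), dim(mask)))
    stop("mask shape must match the field grid", call. = FALSE)
  m <- mask > 0
  nm <- sum(m)
  if (nm == 0L) stop("empty mask", call. = FALSE)
  cnt <- sum(J[m] <= 0)
  list(count = as.integer(cnt), percent = 100 * cnt / nm)
}

#' Direction-wise evaluation of a registration result
#'
#' Forward: warp the moving labels by the forward field (nearest neighbour)
#' and compare with the fixed labels. Inverse: warp the fixed labels by the
#' inverse field and compare with the moving labels — the evaluation of the
#' deformation computed in the opposite direction from the same velocity
#' fields. Folding statistics are those of the field actually applied.
#'
#' @param result an [mdreg] object.
#' @param labels_fixed,labels_moving integer label maps matching the fixed
#'   and moving volumes.
#' @param direction `"forward"` or `"inverse"`.
#' @param mask optional region mask; default: nonzero support of the fixed
#'   (forward) or moving (inverse) volume.
#' @return an object of class `mdreg_eval` with `per_label_dice`,
#'   `mean_dice`, `folding_count`, `folding_percent`, `direction`.
#' @export
evaluate_direction <- function(result, labels_fixed, labels_moving,
                               direction = c("forward", "inverse"),
                               mask = NULL) {
  direction <- match.arg(direction)
  if (!identical(dim(labels_fixed), dim(result$fixed)) ||
      !identical(dim(labels_moving), dim(result$moving)))
    stop("label maps must match the registered volumes", call. = FALSE)
  if (direction == "forward") {
    warped <- warp_volume(labels_moving, result$forward_field, "nearest")
    ref <- labels_fixed
    u <- result$forward_field
    if (is.null(mask)) mask <- result$fixed > 0
  } else {
    warped <- warp_volume(labels_fixed, result$inverse_field, "nearest")
    ref <- labels_moving
    u <- result$inverse_field
    if (is.null(mask)) mask <- result$moving > 0
  }
  ds <- dice_scores(warped, ref)
  fs <- folding_stats(u, mask)
  structure(list(per_label_dice = ds$per_label, mean_dice = ds$mean,
                 folding_count = fs$count, folding_percent = fs$percent,
                 direction = direction), class = "mdreg_eval")
}

#' @export
print.mdreg_eval <- function(x, ...) {
  cat(sprintf("Registration evaluation (%s direction)\n", x$direction))
  cat(sprintf("  mean Dice over %d labels: %.4f\n",
              length(x$per_label_dice), x$mean_dice))
  cat(sprintf("  folding: %d voxels (%.4f%% of mask)\n",
              x$folding_count, x$folding_percent))
  invisible(x)
}
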