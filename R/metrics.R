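# Volume overlap metrics between a manual (reference) and an automatic
# segmentation.

check_same_grid <- function(manual, auto) {
  if (!identical(dim(manual), dim(auto)))
    stop("masks must share the same grid (got ",
         paste(dim(manual), collapse = "x"), " vs ",
         paste(dim(auto), collapse = "x"), ")")
}

#' Dice similarity coefficient (percent)
#'
#' \eqn{\mathrm{Dice} = 2|A \cap B| / (|A| + |B|) \times 100\%}.  Two empty
#' masks are in perfect agreement (100).
#'
#' @param manual,auto Logical (or 0/1) arrays on the same grid.
#' @return Dice coefficient in percent.
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE), c(3, 1)); dice(a, a)
#' @export
dice <- function(manual, auto) {
  check_same_grid(manual, auto)
  a <- manual > 0; b <- auto > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(100)
  200 * sum(a & b) / denom
}

#' Volumetric overlap (Jaccard / Tanimoto coefficient, percent)
#'
#' \eqn{|A \cap B| / |A \cup B| \times 100\%}: the Jaccard overlap in
#' percent (higher is better).  Users expecting the conventional overlap
#' *error* should use [voe_error()], its complement.
#'
#' @inheritParams dice
#' @return Jaccard overlap in percent.
#' @export
voe <- function(manual, auto) {
  check_same_grid(manual, auto)
  a <- manual > 0; b <- auto > 0
  u <- sum(a | b)
  if (u == 0) return(100)
  100 * sum(a & b) / u
}

#' @rdname voe
#' @export
voe_error <- function(manual, auto) 100 - voe(manual, auto)

#' Full overlap report between two masks
#'
#' @inheritParams dice
#' @return An `rw_overlap` list: `dice`, `voe`, `voe_error` (percent) and
#'   the voxel counts `voxels_manual`, `voxels_auto`, `voxels_intersection`,
#'   `voxels_union`.
#' @export
overlap_report <- function(manual, auto) {
  check_same_grid(manual, auto)
  a <- manual > 0; b <- auto > 0
  structure(list(dice = dice(a, b), voe = voe(a, b),
                 voe_error = voe_error(a, b),
                 voxels_manual = sum(a), voxels_auto = sum(b),
                 voxels_intersection = sum(a & b), voxels_union = sum(a | b)),
            class = "rw_overlap")
}

#' @export
print.rw_overlap <- function(x, ...) {
  cat(sprintf("Dice %.2f%%  |  Jaccard overlap %.2f%% (error %.2f%%)\n",
              x$dice, x$voe, x$voe_error))
  cat(sprintf("voxels: manual %d, auto %d, intersection %d, union %d\n",
              x$voxels_manual, x$voxels_auto, x$voxels_intersection,
              x$voxels_union))
  invisible(x)
}
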