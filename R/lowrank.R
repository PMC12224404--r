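# Low-rank spatiotemporal decomposition of the harmonic-field series and
# selection of the respiratory component.

#' Build the M x N measurement matrix
#'
#' Reshapes a harmonic-field series into a matrix `P` with one row per mask
#' voxel (fixed column-major scan order of the mask) and one column per
#' timepoint. [scatter_to_series()] is the exact inverse on the mask.
#'
#' @param harmonic [field_volume_series()] (kind "harmonic") valid on
#'   `eroded_mask`.
#' @param eroded_mask [brain_mask()].
#' @param tr_s sampling interval in seconds.
#' @return object of class `measurement_matrix`: list with `values` (M x N),
#'   `voxel_index` (M x 3 matrix of 1-based voxel coordinates) and `tr_s`.
#' @export
build_measurement_matrix <- function(harmonic, eroded_mask, tr_s) {
  v <- if (inherits(harmonic, "field_series")) harmonic$values else harmonic
  if (length(dim(v)) == 3L) dim(v) <- c(dim(v), 1L)
  if (!identical(dim(v)[1:3], dim(eroded_mask)))
    stop("field and mask grids differ")
  if (!any(eroded_mask)) stop("empty mask")
  nt <- dim(v)[4]
  flat <- matrix(v, ncol = nt)
  P <- flat[which(eroded_mask), , drop = FALSE]
  structure(list(values = P,
                 voxel_index = which(array(eroded_mask, dim(eroded_mask)),
                                     arr.ind = TRUE),
                 tr_s = tr_s),
            class = "measurement_matrix")
}

#' Scatter matrix rows back into a 4D field series
#'
#' @param values M x N matrix (or length-M vector) in mask scan order.
#' @param mask [brain_mask()] with M voxels.
#' @param kind field kind for the returned series.
#' @return [field_volume_series()].
#' @export
scatter_to_series <- function(values, mask, kind = "harmonic") {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (nrow(values) != sum(mask))
    stop("row count does not match the mask voxel count")
  nt <- ncol(values)
  out <- matrix(0, prod(dim(mask)), nt)
  out[which(mask), ] <- values
  field_volume_series(array(out, c(dim(mask), nt)), mask, kind = kind)
}

#' Truncated singular value decomposition of the measurement matrix
#'
#' Computes `P ~ U diag(S) V'` keeping the leading `rank` components; by the
#' Eckart-Young theorem this is the best rank-`rank` approximation of `P` in
#' the Frobenius norm. The scaled right vectors `V diag(S)` carry the temporal
#' dynamics of each spatial mode in ppb-scaled units.
#'
#' @param P [build_measurement_matrix()] output (or a plain matrix).
#' @param rank number of components to retain (default 5).
#' @param tr_s sampling interval, taken from `P` when available.
#' @return object of class `lowrank_model`: `left_vectors` (M x r),
#'   `singular_values` (length r), `right_vectors` (N x r), `scaled_right`
#'   (N x r), `rank`, `sv_full` (all min(M, N) singular values) and `tr_s`.
#' @export
truncated_svd <- function(P, rank = 5L, tr_s = NULL) {
  if (inherits(P, "measurement_matrix")) {
    if (is.null(tr_s)) tr_s <- P$tr_s
    P <- P$values
  }
  if (!is.matrix(P)) stop("`P` must be a matrix")
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(dim(P)))
    stop(sprintf("rank must be in [1, %d]", min(dim(P))))
  s <- svd(P, nu = rank, nv = rank)
  structure(list(left_vectors = s$u,
                 singular_values = s$d[seq_len(rank)],
                 right_vectors = s$v,
                 scaled_right = sweep(s$v, 2L, s$d[seq_len(rank)], `*`),
                 rank = rank,
                 sv_full = s$d,
                 tr_s = tr_s),
            class = "lowrank_model")
}

#' @export
print.lowrank_model <- function(x, ...) {
  cat(sprintf("<lowrank_model> rank %d, M = %d, N = %d\n", x$rank,
              nrow(x$left_vectors), nrow(x$right_vectors)))
  cat("  singular values:", format(signif(x$singular_values, 4)), "\n")
  invisible(x)
}

#' Select the respiratory component by maximal instantaneous variation
#'
#' Scores every scaled right singular vector by the L1 norm of its temporal
#' first difference, `score_i = sum_t |v~_i(t+1) - v~_i(t)| / tr_s`, and
#' returns the component with the largest score. A near-constant static
#' background loads onto a component with a large singular value but a tiny
#' derivative, so the criterion is not biased towards the first component.
#' Ties are broken towards the smallest index. The SVD's sign ambiguity is
#' resolved by flipping the component so the spatial map's mean is
#' non-negative; the physical inhale/exhale polarity is not identifiable from
#' the decomposition alone.
#'
#' @param model [truncated_svd()] output.
#' @param tr_s sampling interval (s); defaults to the model's.
#' @return object of class `resp_component`: `index`, `spatial_map` (length
#'   M), `temporal_trace` (length N, ppb-scaled), `scores` (length rank) and
#'   `sign_fixed = TRUE`.
#' @export
select_respiratory_component <- function(model, tr_s = model$tr_s) {
  if (is.null(tr_s)) tr_s <- 1
  V <- model$scaled_right
  if (nrow(V) < 2L) stop("need at least 2 timepoints to form a derivative")
  scores <- colSums(abs(diff(V))) / tr_s
  idx <- which.max(scores)          # ties resolve to the smallest index
  u <- model$left_vectors[, idx]
  v <- V[, idx]
  if (mean(u) < 0) {
    u <- -u
    v <- -v
  }
  structure(list(index = idx, spatial_map = u, temporal_trace = v,
                 scores = scores, sign_fixed = TRUE),
            class = "resp_component")
}

#' @export
print.resp_component <- function(x, ...) {
  cat(sprintf("<resp_component> index %d of %d, L1-derivative scores: %s\n",
              x$index, length(x$scores),
              paste(format(signif(x$scores, 4)), collapse = " ")))
  invisible(x)
}

#' Rank-1 field series of the selected component
#'
#' Voxel i at timepoint t is `spatial_map[i] * temporal_trace[t]`, scattered
#' back onto the mask.
#'
#' @param model [truncated_svd()] output.
#' @param comp [select_respiratory_component()] output.
#' @param mask [brain_mask()] with M voxels (the eroded mask the measurement
#'   matrix was built on).
#' @return [field_volume_series()] of kind "harmonic".
#' @export
component_field_series <- function(model, comp, mask) {
  if (comp$index < 1L || comp$index > model$rank)
    stop("component index out of range")
  scatter_to_series(outer(comp$spatial_map, comp$temporal_trace), mask,
                    kind = "harmonic")
}
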