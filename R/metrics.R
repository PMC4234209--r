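#' Dice overlap coefficient of two binary masks
#'
#' `D = 2 |A intersect B| / (|A| + |B|)`, computed on the voxel masks.
#' Ranges from 0 (complete lack of overlap) to 1 (perfect agreement).
#'
#' @param a,b [binary_mask()] objects of identical shape, not both empty.
#' @return The Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")), call. = FALSE)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0)
    stop("Dice is undefined for two empty masks", call. = FALSE)
  2 * sum(a$data & b$data) / (na + nb)
}

#' Summary of inter-surface point distances
#'
#' @param distances numeric vector of point-to-surface distances (mm).
#' @return An object of class `distance_summary` with fields `median`,
#'   `p90` (linear-interpolation percentile), `min`, `max`, `n_samples`.
#' @export
distance_summary <- function(distances) {
  if (!length(distances)) stop("no distances to summarize", call. = FALSE)
  structure(list(median = unname(median(distances)),
                 p90 = unname(quantile(distances, 0.9, type = 7)),
                 min = min(distances), max = max(distances),
                 n_samples = length(distances)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf(
    "<distance_summary> median %.3f mm, p90 %.3f mm, range [%.3f, %.3f] mm (n = %d)\n",
    x$median, x$p90, x$min, x$max, x$n_samples))
  invisible(x)
}

#' Surface distance map between two meshes
#'
#' Samples points on a mesh (vertices plus area-uniform face samples, see
#' [sample_mesh_points()]) and measures the distance from each sample to
#' the closest point on any triangle of the other mesh.  `"directed"`
#' measures `a -> b` only; `"symmetric"` (default) pools both directed
#' point-distance sets before summarizing, so the summary is invariant to
#' argument order.
#'
#' @param a,b [surface_mesh()] objects.
#' @param mode `"symmetric"` or `"directed"`.
#' @param samples_per_mm2 face sample density (plus all vertices).
#' @return A [distance_summary()]; the pooled per-point distances are
#'   attached as attribute `"distances"`.
#' @export
surface_distance <- function(a, b, mode = c("symmetric", "directed"),
                             samples_per_mm2 = 4) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "surface_mesh"), inherits(b, "surface_mesh"))
  d_ab <- cpp_point_mesh_distance(sample_mesh_points(a, samples_per_mm2),
                                  b$vertices, b$faces)
  d <- if (mode == "directed") d_ab
    else c(d_ab,
           cpp_point_mesh_distance(sample_mesh_points(b, samples_per_mm2),
                                   a$vertices, a$faces))
  out <- distance_summary(d)
  attr(out, "distances") <- d
  out
}

#' Rater-by-subject volume table
#'
#' @param values numeric matrix, one row per subject (condyle), one column
#'   per rater; all volumes positive, at least 2 x 2.
#' @param subjects,raters optional labels.
#' @return An object of class `volume_table`.
#' @export
volume_table <- function(values, subjects = rownames(values),
                         raters = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("volume table needs at least 2 subjects and 2 raters",
         call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all volumes must be positive and finite", call. = FALSE)
  if (is.null(subjects)) subjects <- paste0("subject", seq_len(nrow(values)))
  if (is.null(raters)) raters <- paste0("rater", seq_len(ncol(values)))
  dimnames(values) <- list(subjects, raters)
  structure(list(values = values), class = "volume_table")
}

#' Two-way absolute-agreement intraclass correlation (single measures)
#'
#' Decomposes the subject-by-rater table into between-subject (MSR),
#' between-rater (MSC) and residual (MSE) mean squares from the standard
#' two-way layout without replication, and returns
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` — ICC(A,1).  For
#' absolute agreement the mixed- and random-effects formulations give the
#' same value, so a single formula covers both.
#'
#' @param table a [volume_table()] or numeric matrix (subjects x raters).
#' @return The ICC, at most 1.
#' @export
icc_absolute_agreement <- function(table) {
  values <- if (inherits(table, "volume_table")) table$values
    else as.matrix(table)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L)
    stop("ICC needs at least 2 subjects and 2 raters", call. = FALSE)
  grand <- mean(values)
  sst <- sum((values - grand)^2)
  if (sst == 0) stop("ICC is undefined for a constant table", call. = FALSE)
  rm_ <- rowMeans(values); cm <- colMeans(values)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Paired volume-difference statistics
#'
#' Mean absolute difference between paired volume lists, in mm^3 and as a
#' percentage of the pairwise mean volume `(a_i + b_i)/2`, averaged over
#' pairs.
#'
#' @param a,b numeric vectors of volumes (mm^3), equal length >= 1.
#' @param paired kept for signature clarity; only paired comparison is
#'   implemented.
#' @return List with `mean_abs_diff` (mm^3) and `mean_abs_diff_percent`.
#' @export
volume_difference_stats <- function(a, b, paired = TRUE) {
  if (length(a) != length(b))
    stop("volume lists must have equal length", call. = FALSE)
  if (!length(a)) stop("volume lists must be non-empty", call. = FALSE)
  if (!paired) stop("only paired comparison is implemented", call. = FALSE)
  d <- abs(a - b)
  list(mean_abs_diff = mean(d),
       mean_abs_diff_percent = mean(d / ((a + b) / 2)) * 100)
}
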