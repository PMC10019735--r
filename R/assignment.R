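# Assigning latent components to samples: per-sample min-max scaling of the
# sample loadings, Gaussian-KDE CDF values, and thresholding at a CDF
# cutoff (default 0.6).

#' Min-max scale one sample's loading vector
#'
#' @param s_i numeric vector of a sample's loadings over the selected
#'   components (length >= 2, finite).
#' @param sample_id optional id used in error messages.
#' @return the vector rescaled so its minimum is 0 and maximum is 1.
#' @export
minmax_scale_sample <- function(s_i, sample_id = NULL) {
  if (length(s_i) < 2L) stopf("loading vector must have length >= 2")
  if (any(!is.finite(s_i))) stopf("loading vector must be finite")
  lo <- min(s_i); hi <- max(s_i)
  if (hi == lo)
    stopf("degenerate sample%s: constant loading vector cannot be min-max scaled",
          if (is.null(sample_id)) "" else paste0(" '", sample_id, "'"))
  (s_i - lo) / (hi - lo)
}

# Scott's rule bandwidth for a 1-d Gaussian KDE.
scott_bandwidth <- function(x) {
  h <- stats::sd(x) * length(x)^(-1 / 5)
  if (!is.finite(h) || h <= 0)
    stopf("cannot pick a KDE bandwidth for a constant vector")
  h
}

#' Gaussian-KDE cumulative probabilities of a scaled loading vector
#'
#' Fits a Gaussian kernel density to the vector and returns, for each
#' element v, the integral of that density from -Inf to v. With Gaussian
#' kernels the CDF has the closed form mean over kernels of
#' `pnorm((v - x_i)/h)`.
#'
#' @param scaled numeric vector in \[0, 1\], length >= 2.
#' @param bandwidth `"scott"` (default) or a positive number.
#' @return vector of CDF values in (0, 1), monotone in `scaled`.
#' @export
cdf_values <- function(scaled, bandwidth = "scott") {
  if (length(scaled) < 2L) stopf("need >= 2 values for a KDE-based CDF")
  if (any(scaled < 0 | scaled > 1)) stopf("scaled values must lie in [0, 1]")
  h <- if (identical(bandwidth, "scott")) scott_bandwidth(scaled)
       else {
         if (!is.numeric(bandwidth) || bandwidth <= 0)
           stopf("bandwidth must be 'scott' or a positive number")
         bandwidth
       }
  vapply(scaled, function(v) mean(stats::pnorm((v - scaled) / h)), numeric(1))
}

#' Assign latent components to samples by CDF threshold
#'
#' For each sample, its loadings over the selected components are min-max
#' scaled, a per-sample Gaussian-KDE CDF is evaluated at each scaled
#' loading, and the components with CDF >= `threshold` form the sample's
#' assigned set. A sample whose set would be empty receives its
#' maximum-loading component instead (with a warning), so every sample
#' carries at least one component.
#'
#' @param result a `mopa_decomp`.
#' @param threshold CDF cutoff in (0, 1); default 0.6.
#' @param bandwidth KDE bandwidth, see [cdf_values()].
#' @return an object of class `mopa_assignment` with elements `scaled`
#'   (samples x selected components), `cdf` (same shape), `assigned` (named
#'   list of integer component indices per sample), `threshold`, `features`
#'   (the selected component indices).
#' @export
assign_features <- function(result, threshold = 0.6, bandwidth = "scott") {
  stopifnot(inherits(result, "mopa_decomp"))
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  sel <- result$selected_features
  if (length(sel) < 2L)
    stopf("need >= 2 selected components to assign features")
  S <- result$S[, sel, drop = FALSE]
  n <- nrow(S)
  scaled <- matrix(0, n, length(sel), dimnames = dimnames(S))
  cdf <- scaled
  assigned <- vector("list", n)
  names(assigned) <- rownames(S)
  fellback <- character(0)
  for (i in seq_len(n)) {
    sc <- minmax_scale_sample(S[i, ], sample_id = rownames(S)[i])
    cv <- cdf_values(sc, bandwidth)
    scaled[i, ] <- sc
    cdf[i, ] <- cv
    hit <- which(cv >= threshold)
    if (length(hit) == 0L) {
      hit <- which.max(S[i, ])
      fellback <- c(fellback, rownames(S)[i])
    }
    assigned[[i]] <- sel[hit]
  }
  if (length(fellback) > 0L)
    warnf("%d sample(s) had no component above the CDF threshold; assigned their maximum-loading component instead",
          length(fellback))
  structure(list(scaled = scaled, cdf = cdf, assigned = assigned,
                 threshold = threshold, features = sel),
            class = "mopa_assignment")
}

#' @export
print.mopa_assignment <- function(x, ...) {
  sz <- lengths(x$assigned)
  cat(sprintf("<mopa_assignment> %d samples, threshold %.2f, %.1f components/sample (range %d-%d)\n",
              length(x$assigned), x$threshold, mean(sz), min(sz), max(sz)))
  invisible(x)
}

#' Scan CDF thresholds
#'
#' Reports the mean assigned-set size at each threshold; sizes are monotone
#' non-increasing in the threshold.
#'
#' @param result a `mopa_decomp`.
#' @param thresholds numeric vector in (0, 1).
#' @param bandwidth KDE bandwidth, see [cdf_values()].
#' @return data frame with columns `threshold` and `mean_size`.
#' @export
threshold_scan <- function(result, thresholds, bandwidth = "scott") {
  if (any(thresholds <= 0 | thresholds >= 1))
    stopf("thresholds must lie in (0, 1)")
  sizes <- vapply(thresholds, function(th) {
    a <- suppressWarnings(assign_features(result, th, bandwidth))
    mean(lengths(a$assigned))
  }, numeric(1))
  data.frame(threshold = thresholds, mean_size = sizes)
}
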