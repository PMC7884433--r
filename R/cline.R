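#' Per-individual allele-frequency points for a locus class
#'
#' Pairs each individual's transect location with its allele frequency over
#' one class of loci (mean allele-1 dosage over the class's loci divided
#' by 2): the input points for cline fitting.
#'
#' @param x a [population()], or one snapshot of a trajectory (a data frame
#'   with columns `location`, `mating_freq`, `neutral_freq`).
#' @param locus_class `"mating"` or `"neutral"`.
#' @return A data frame with columns `location` and `frequency` (class
#'   attribute `locus_class`).
#' @export
allele_frequency_points <- function(x, locus_class = c("mating", "neutral")) {
  locus_class <- match.arg(locus_class)
  if (inherits(x, "population")) {
    if (length(x$location) == 0L) stop("empty population")
    freq <- rowMeans(if (locus_class == "mating") x$mating else x$neutral) / 2
    out <- data.frame(location = x$location, frequency = freq)
  } else {
    stopifnot(is.data.frame(x), nrow(x) > 0)
    col <- paste0(locus_class, "_freq")
    if (!col %in% names(x)) stop("snapshot lacks column ", col)
    out <- data.frame(location = x$location, frequency = x[[col]])
  }
  attr(out, "locus_class") <- locus_class
  out
}

#' Construct a cline fit from grid predictions
#'
#' Low-level constructor used by [fit_cline()] and by analyses that already
#' have predicted frequencies on an even transect grid (e.g. an analytic
#' cline shape).
#'
#' @param grid strictly increasing locations spanning [0, 1].
#' @param predictions fitted allele frequencies; clamped to [0, 1].
#' @param model optional smoother object kept for inspection.
#' @return An object of class `cline_fit`.
#' @export
cline_fit <- function(grid, predictions, model = NULL) {
  stopifnot(length(grid) == length(predictions), length(grid) >= 2,
            all(diff(grid) > 0))
  structure(list(grid = as.numeric(grid),
                 predictions = pmin(1, pmax(0, as.numeric(predictions))),
                 model = model),
            class = "cline_fit")
}

#' Fit a smooth cline of allele frequency on transect location
#'
#' Penalized regression spline fit `frequency ~ s(location)` (thin-plate
#' spline with REML smoothness selection via [mgcv::gam()]), with
#' predictions on an even grid clamped to [0, 1]. The basis dimension
#' (default 20) gives the smooth enough flexibility to track clines as
#' narrow as a few percent of the transect; the penalty shrinks unused
#' flexibility away on smoother data.
#'
#' @param points a data frame with columns `location`, `frequency` (see
#'   [allele_frequency_points()]).
#' @param grid_size number of evenly spaced prediction locations on [0, 1].
#' @param k basis dimension of the spline smooth.
#' @return A [cline_fit()].
#' @export
#' @examples
#' pts <- simulate_transect_sample(center = 0.5, width = 0.2, n = 200, seed = 1)
#' fit <- fit_cline(pts)
#' cline_center(fit)
fit_cline <- function(points, grid_size = 1001L, k = 20L) {
  stopifnot(is.data.frame(points), all(c("location", "frequency") %in%
                                         names(points)))
  loc <- points$location; freq <- points$frequency
  if (length(loc) < 20L) stop("need at least 20 points to fit a cline")
  if (diff(range(loc)) < 0.5) {
    stop("points must span at least half of the transect")
  }
  grid <- seq(0, 1, length.out = grid_size)
  if (stats::var(freq) == 0) {
    # degenerate but valid: flat cline at the common frequency
    return(cline_fit(grid, rep(freq[1], grid_size), model = NULL))
  }
  fit <- mgcv::gam(frequency ~ s(location, k = k), data = points,
                   method = "REML")
  pred <- as.numeric(predict(fit, newdata = data.frame(location = grid)))
  cline_fit(grid, pred, model = fit)
}

# all locations where the prediction curve crosses `level`, by linear
# interpolation between grid points (exact grid hits included once)
crossing_locations <- function(fit, level) {
  p <- fit$predictions - level
  g <- fit$grid
  hits <- g[p == 0]
  s <- p[-length(p)] * p[-1]
  idx <- which(s < 0)
  interp <- g[idx] + (g[idx + 1] - g[idx]) * (-p[idx]) / (p[idx + 1] - p[idx])
  sort(unique(c(hits, interp)))
}

#' Cline center: the 0.5-crossing of the fitted cline
#'
#' Orientation convention: allele-1 (dominant-species) frequency increases
#' with location at generation 0. With several crossings the midpoint of the
#' first and last crossing is returned; if the fit exceeds 0.5 everywhere the
#' crossing exited toward the recessive side and the center is 0; if it is
#' below 0.5 everywhere the center is 1.
#'
#' @param fit a [cline_fit()].
#' @return Center position in [0, 1].
#' @export
cline_center <- function(fit) {
  cr <- crossing_locations(fit, 0.5)
  if (length(cr) == 0L) {
    return(if (all(fit$predictions > 0.5)) 0 else 1)
  }
  (cr[1] + cr[length(cr)]) / 2
}

#' Cline width: distance between the 0.1 and 0.9 crossings
#'
#' The transect distance between the
#' outermost location at which the fitted cline crosses frequency 0.1 and the
#' outermost location at which it crosses 0.9. If a threshold is never
#' crossed, the nearer transect boundary is substituted and the result is
#' flagged.
#'
#' @param fit a [cline_fit()].
#' @return A list with `width` (>= 0) and `flagged` (boundary substitution
#'   used).
#' @export
cline_width <- function(fit) {
  n <- length(fit$predictions)
  k <- max(2L, ceiling(n / 10))
  increasing <- mean(fit$predictions[seq(n - k + 1, n)]) >=
    mean(fit$predictions[seq_len(k)])
  flagged <- FALSE
  outermost <- function(level) {
    cr <- crossing_locations(fit, level)
    low_side <- (level < 0.5) == increasing  # crossing expected nearer 0?
    if (length(cr) == 0L) {
      flagged <<- TRUE
      above <- all(fit$predictions > level)
      # the missed crossing lies beyond the boundary the curve exited through
      if (increasing) return(if (above) 0 else 1)
      return(if (above) 1 else 0)
    }
    if (low_side) min(cr) else max(cr)
  }
  x10 <- outermost(0.1)
  x90 <- outermost(0.9)
  list(width = abs(x90 - x10), flagged = flagged)
}

#' Classify cline movement from the final center position
#'
#' Clines start at center 0.5; by the end of a simulation the center is
#' classified as displaced toward the recessive homozygote's side (RH,
#' center < 0.45), spatially stable (S, 0.45 <= center <= 0.55), or displaced
#' toward the dominant homozygote's side (DH, center > 0.55).
#'
#' @param center center position(s) in [0, 1] (vectorized).
#' @return Factor with levels `RH`, `S`, `DH`.
#' @export
#' @examples
#' classify_movement(c(0.30, 0.50, 0.80))
classify_movement <- function(center) {
  stopifnot(all(center >= 0 & center <= 1, na.rm = TRUE))
  factor(ifelse(center < 0.45, "RH", ifelse(center <= 0.55, "S", "DH")),
         levels = c("RH", "S", "DH"))
}

#' Signed displacement of the mating cline from the neutral background
#'
#' @param center_mating,center_neutral cline centers in [0, 1].
#' @return `center_mating - center_neutral`; positive values mean the mating
#'   cline is displaced toward the dominant-homozygote side.
#' @export
displacement <- function(center_mating, center_neutral) {
  center_mating - center_neutral
}

#' Paired one-sided Wilcoxon signed-rank test of center displacement
#'
#' Tests whether mating-trait cline centers are greater than the paired
#' neutral centers (alternative: mating > neutral). Uses the exact signed-rank
#' null distribution for n <= 25 pairs without ties or zero differences, and
#' the normal approximation with tie correction otherwise. If all paired
#' differences are zero there is no evidence and p = 1.
#'
#' @param centers_mating,centers_neutral equal-length paired center vectors
#'   (n >= 3).
#' @return One-sided p-value.
#' @export
wilcoxon_displacement_test <- function(centers_mating, centers_neutral) {
  stopifnot(length(centers_mating) == length(centers_neutral),
            length(centers_mating) >= 3)
  d <- centers_mating - centers_neutral
  if (all(d == 0)) return(1)
  nz <- d[d != 0]
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  suppressWarnings(
    wilcox.test(centers_mating, centers_neutral, paired = TRUE,
                alternative = "greater", exact = exact,
                correct = !exact)$p.value
  )
}

#' Summarize a fitted cline
#'
#' @param fit a [cline_fit()].
#' @return A list with `center`, `width`, `movement_class`, `width_flagged`.
#' @export
summarize_cline <- function(fit) {
  ctr <- cline_center(fit)
  w <- cline_width(fit)
  list(center = ctr, width = w$width,
       movement_class = classify_movement(ctr), width_flagged = w$flagged)
}
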