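#' Fit a P-value calibration curve
#'
#' Isotonic regression of the indicator `observed TM-score < threshold` on
#' the predicted global score, constrained nonincreasing: higher predicted
#' quality must never mean higher probability that the model is unrelated to
#' the native fold (TM-score below 0.2 is the conventional random-similarity
#' regime).  Fitted probabilities are clamped to `[1e-6, 1]`.
#'
#' @param predicted numeric vector of predicted global scores.
#' @param observed_tm matching observed TM-scores against the native.
#' @param threshold TM-score boundary of the random regime (default 0.2).
#' @return Object of class `calibration_curve` with knot vectors `score`
#'   (increasing) and `p` (nonincreasing).
#' @export
calibrate <- function(predicted, observed_tm, threshold = 0.2) {
  stopifnot(length(predicted) == length(observed_tm), length(predicted) >= 2)
  y <- as.numeric(observed_tm < threshold)
  ord <- order(predicted, decreasing = TRUE)   # fit nondecreasing in -score
  fit <- stats::isoreg(seq_along(ord), y[ord])$yf
  score <- predicted[ord]
  # collapse tied scores, then re-enforce monotonicity after averaging
  agg <- tapply(fit, score, mean)
  s <- as.numeric(names(agg))
  p <- as.numeric(agg)
  o <- order(s)
  s <- s[o]; p <- cummin(p[o])
  p <- pmin(pmax(p, 1e-6), 1)
  structure(list(score = s, p = p, threshold = threshold),
            class = "calibration_curve")
}

#' P-value for a predicted global score
#'
#' Interpolates the fitted [calibrate()] curve (constant beyond its ends):
#' the estimated probability that a model with this predicted score has
#' observed TM-score below the calibration threshold, i.e. that its
#' similarity to the native is no better than random.
#'
#' @param variant_score predicted global score(s).
#' @param calibration a `calibration_curve`.
#' @return P-values in `[1e-6, 1]`, monotone nonincreasing in the score.
#' @export
p_value <- function(variant_score, calibration) {
  if (!inherits(calibration, "calibration_curve")) {
    stop("calibration must be a calibration_curve (see calibrate())")
  }
  if (length(calibration$score) == 1L) {
    return(rep(calibration$p, length(variant_score)))
  }
  out <- stats::approx(calibration$score, calibration$p, xout = variant_score,
                       rule = 2, ties = "ordered")$y
  pmin(pmax(out, 1e-6), 1)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d knots, P[TM < %.2f], P range %.2g..%.2g\n",
              length(x$score), x$threshold, min(x$p), max(x$p)))
  invisible(x)
}

#' Write calibration curves to a text file
#'
#' One file can hold a curve per score variant; lines are
#' `variant score p` triples under a version header.
#'
#' @param curves named list of `calibration_curve` objects (names are score
#'   variants).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(curves, path) {
  lines <- c("modqa6-calibration 1")
  for (nm in names(curves)) {
    cc <- curves[[nm]]
    lines <- c(lines,
               sprintf("threshold %s %.6g", nm, cc$threshold),
               sprintf("%s %.10g %.10g", nm, cc$score, cc$p))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read calibration curves written by [write_calibration()]
#'
#' @param path path to a calibration file.
#' @return Named list of `calibration_curve` objects.
#' @export
read_calibration <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "modqa6-calibration")) {
    stop("not a calibration file: ", path)
  }
  lines <- lines[-1]
  thr <- grepl("^threshold ", lines)
  thresholds <- list()
  for (ln in lines[thr]) {
    f <- strsplit(ln, "\\s+")[[1]]
    thresholds[[f[2]]] <- as.numeric(f[3])
  }
  out <- list()
  dat <- do.call(rbind, strsplit(lines[!thr], "\\s+"))
  for (nm in unique(dat[, 1])) {
    sel <- dat[, 1] == nm
    out[[nm]] <- structure(list(score = as.numeric(dat[sel, 2]),
                                p = as.numeric(dat[sel, 3]),
                                threshold = thresholds[[nm]] %||% 0.2),
                           class = "calibration_curve")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to the frozen fixture-fitted calibration file
#'
#' @return File path of the bundled calibration curves.
#' @export
default_calibration_path <- function() {
  system.file("extdata", "calibration.txt", package = "modqa6",
              mustWork = TRUE)
}
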