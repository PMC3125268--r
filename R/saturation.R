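# Gene-detection saturation: random read drawing, saturating nonlinear
# regression, and the iteratively re-windowed fit for the detectable-gene
# asymptote.

#' Gene-detection saturation curve by random read drawing
#'
#' Reads are drawn uniformly at random without replacement. Every drawn read
#' that overlaps a condensed gene's exons increments that gene's count by 1;
#' a gene is detected once its count reaches `min_reads`. After each
#' increment of `step` drawn reads the number of detected genes is recorded.
#'
#' @param reads `GRanges` of alignments.
#' @param condensed `GRangesList` of condensed gene models.
#' @param step Reads drawn per increment.
#' @param min_reads Reads required for detection (default 5).
#' @param seed Optional integer seed for the draw order.
#' @return A `saturation_curve`: data.frame with `reads_drawn`,
#'   `genes_detected`, plus attributes `min_reads` and `seed`.
#' @export
detection_curve <- function(reads, condensed, step, min_reads = 5L,
                            seed = NULL) {
  stopifnot(step >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(reads)
  if (n == 0L) stop("no reads to draw")
  draw_order <- sample.int(n)            # draw_order[k] = read drawn at time k
  t_of_read <- integer(n)
  t_of_read[draw_order] <- seq_len(n)
  ov <- findOverlaps(condensed, reads, ignore.strand = TRUE)
  det_time <- rep(NA_integer_, length(condensed))
  if (length(ov) > 0L) {
    times <- split(t_of_read[subjectHits(ov)], queryHits(ov))
    for (g in names(times)) {
      tt <- times[[g]]
      if (length(tt) >= min_reads)
        det_time[as.integer(g)] <- sort(tt, partial = min_reads)[min_reads]
    }
  }
  xs <- if (step >= n) n else unique(c(seq(step, n, by = step), n))
  det_sorted <- sort(det_time[!is.na(det_time)])
  ys <- findInterval(xs, det_sorted)
  curve <- data.frame(reads_drawn = xs, genes_detected = as.integer(ys))
  attr(curve, "min_reads") <- min_reads
  attr(curve, "seed") <- seed
  class(curve) <- c("saturation_curve", "data.frame")
  curve
}

.sat_model <- function(model) {
  switch(model,
         hyperbolic = list(
           f = function(x, a, b) a * x / (b + x),
           formula = genes_detected ~ a * reads_drawn / (b + reads_drawn)),
         exponential = list(
           f = function(x, a, b) a * (1 - exp(-x / b)),
           formula = genes_detected ~ a * (1 - exp(-reads_drawn / b))),
         stop("unknown saturation model: ", model))
}

.sat_fit_once <- function(df, model) {
  m <- .sat_model(model)
  a_max <- max(df$genes_detected)
  starts <- list()
  if (model == "hyperbolic") {
    # linearized double-reciprocal start: 1/y = 1/a + (b/a) * 1/x
    pos <- df$genes_detected > 0
    if (sum(pos) >= 2L) {
      lf <- stats::lm(I(1 / genes_detected) ~ I(1 / reads_drawn),
                      data = df[pos, ])
      ic <- stats::coef(lf)[[1L]]; sl <- stats::coef(lf)[[2L]]
      if (is.finite(ic) && ic > 0 && is.finite(sl) && sl > 0)
        starts <- c(starts, list(list(a = 1 / ic, b = sl / ic)))
    }
  }
  half <- df$reads_drawn[which.min(abs(df$genes_detected - a_max / 2))]
  starts <- c(starts,
              list(list(a = a_max * 1.1 + 1, b = max(half, 1)),
                   list(a = a_max * 1.5 + 1,
                        b = stats::median(df$reads_drawn)),
                   list(a = a_max + 1,
                        b = min(df$reads_drawn) / 2 + 1)))
  fit <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(m$formula, data = df, start = s0,
                        lower = c(a = 1e-9, b = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("nonlinear saturation fit failed to initialize")
  co <- stats::coef(fit)
  fitted <- m$f(df$reads_drawn, co[["a"]], co[["b"]])
  r <- suppressWarnings(stats::cor(df$genes_detected, fitted))
  list(a = co[["a"]], b = co[["b"]], fitted = fitted, correlation = r)
}

# Index (within x order) of the k-th sign change of the residual sequence;
# NA if fewer exist. Zero residuals carry the previous sign.
.nth_sign_change <- function(resid, k = 2L) {
  s <- sign(resid)
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1L) s[i - 1L] else 1
  changes <- which(diff(s) != 0) + 1L
  if (length(changes) < k) NA_integer_ else changes[k]
}

#' Fit a saturating model with iterative re-windowing
#'
#' A saturating curve (hyperbolic `a*x/(b+x)` by default, exponential
#' `a*(1-exp(-x/b))` as an alternative) is least-squares fitted to all
#' points. If the Pearson correlation between observed and fitted values is
#' below `r_target`, the second crossing of the fitted curve with the
#' observed point sequence (second sign change of the residuals) is located
#' and the fit repeated on the points from that crossing onward. Rounds stop
#' at `r_target`, when no second crossing or fewer than 4 points remain, when
#' the correlation stops improving (delta < 1e-4), or at `max_rounds`.
#'
#' @param curve A `saturation_curve` (or data.frame with `reads_drawn`,
#'   `genes_detected`); at least 4 points.
#' @param model `"hyperbolic"` or `"exponential"`.
#' @param r_target Target Pearson correlation (default 0.99).
#' @param max_rounds Bound on refit rounds (default 20).
#' @return A `saturation_fit` list: `a` (asymptote, genes), `b`
#'   (half-saturation, reads), `model`, `correlation`, `refit_rounds`,
#'   `fit_window_start` (index of the first point used), `n_points_used`,
#'   `converged`.
#' @export
fit_saturation <- function(curve, model = c("hyperbolic", "exponential"),
                           r_target = 0.99, max_rounds = 20L) {
  model <- match.arg(model)
  df <- as.data.frame(curve)[, c("reads_drawn", "genes_detected")]
  if (nrow(df) < 4L) stop("at least 4 saturation points are required")
  if (all(df$genes_detected == 0)) stop("degenerate flat curve: no gene ever detected")
  window_start <- 1L
  rounds <- 0L
  last <- tryCatch(.sat_fit_once(df, model),
                   error = function(e) stop("saturation fit failed: ",
                                            conditionMessage(e)))
  while (!is.na(last$correlation) && last$correlation < r_target &&
         rounds < max_rounds) {
    resid <- df$genes_detected[window_start:nrow(df)] - last$fitted
    cross <- .nth_sign_change(resid, 2L)
    if (is.na(cross)) break
    new_start <- window_start + cross - 1L
    if (nrow(df) - new_start + 1L < 4L) break
    this <- tryCatch(.sat_fit_once(df[new_start:nrow(df), ], model),
                     error = function(e) NULL)
    if (is.null(this)) break   # degenerate window (e.g. fully saturated tail)
    window_start <- new_start
    rounds <- rounds + 1L
    if (!is.na(this$correlation) && !is.na(last$correlation) &&
        this$correlation - last$correlation < 1e-4 &&
        this$correlation < r_target) { last <- this; break }
    last <- this
  }
  out <- list(a = last$a, b = last$b, model = model,
              correlation = last$correlation, refit_rounds = rounds,
              fit_window_start = window_start,
              n_points_used = nrow(df) - window_start + 1L,
              converged = !is.na(last$correlation) &&
                last$correlation >= r_target)
  class(out) <- "saturation_fit"
  out
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("saturation_fit (%s): asymptote a = %.1f genes, b = %.1f reads\n",
              x$model, x$a, x$b))
  cat(sprintf("  r = %.4f over %d points (window start %d, %d refit rounds)%s\n",
              x$correlation, x$n_points_used, x$fit_window_start,
              x$refit_rounds, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Asymptotic number of detectable genes
#'
#' The limit of the fitted saturating model as the read count grows without
#' bound; for both supported model families this is the parameter `a`.
#'
#' @param fit A `saturation_fit`.
#' @return Numeric estimate of the maximum number of detectable genes.
#' @export
estimate_max_genes <- function(fit) {
  stopifnot(inherits(fit, "saturation_fit"))
  fit$a
}
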