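#' Rarefaction of coverage over taxa
#'
#' Adds taxa one at a time in random orders and records the cumulative union
#' coverage fraction after each addition. The final point is the all-taxa
#' union for every order; the curve is non-decreasing within every order by
#' construction.
#'
#' @param presence A `presence_matrix` with >= 2 taxa.
#' @param n_orders Number of random taxon orders (default 100).
#' @param seed Optional RNG seed.
#' @return A `rarefaction_curve` data.frame with columns `x` (taxa added),
#'   `y_mean`, `y_sd`, `n` and attribute `axis = "taxa"`.
#' @export
rarefy_taxa <- function(presence, n_orders = 100L, seed = NULL) {
  t_n <- ncol(presence)
  if (t_n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (n_orders < 1) stop("`n_orders` must be >= 1", call. = FALSE)
  n <- nrow(presence)
  any_p <- rowSums(presence) > 0
  ys <- with_local_seed(seed, {
    vapply(seq_len(n_orders), function(o) {
      ord <- sample.int(t_n)
      m <- presence[, ord, drop = FALSE] == 1
      first <- integer(n)
      first[any_p] <- max.col(m[any_p, , drop = FALSE], ties.method = "first")
      cumsum(tabulate(first[any_p], nbins = t_n)) / n
    }, numeric(t_n))
  })
  ys <- matrix(ys, nrow = t_n)
  curve <- data.frame(x = seq_len(t_n), y_mean = rowMeans(ys),
                      y_sd = apply(ys, 1, stats::sd), n = n_orders)
  structure(curve, axis = "taxa",
            class = c("rarefaction_curve", "data.frame"))
}

#' Rarefaction of coverage over sequencing depth
#'
#' Subsamples each taxon's fragments without replacement to a series of
#' depth fractions and recomputes the union coverage fraction at each depth
#' (each taxon's samples are pooled first, mirroring per-taxon read
#' subsampling). Fraction 1.0 reproduces the full-data coverage exactly
#' (no resampling).
#'
#' @param counts A `count_matrix`.
#' @param mask Optional `common_genome_mask` (coverage denominator).
#' @param fractions Depth fractions in (0, 1]; default 10% steps.
#' @param n_draws Random subsample draws per fraction (default 10).
#' @param tau Presence threshold applied after subsampling (default 1).
#' @param seed Optional RNG seed.
#' @return A `rarefaction_curve` data.frame with attribute `axis = "depth"`;
#'   `x` is the depth fraction.
#' @export
rarefy_depth <- function(counts, mask = NULL, fractions = seq(0.1, 1, by = 0.1),
                         n_draws = 10L, tau = 1L, seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (any(fractions <= 0 | fractions > 1))
    stop("`fractions` must lie in (0, 1]", call. = FALSE)
  fractions <- sort(fractions)
  tc <- taxon_counts(counts)
  if (!is.null(mask)) tc <- tc[as.logical(mask), , drop = FALSE]
  cs <- colSums(tc)
  if (sum(cs) == 0) stop("count matrix holds no fragments", call. = FALSE)
  if (nrow(tc) == 0L) stop("empty mask", call. = FALSE)
  full <- mean(rowSums(tc >= tau) > 0)
  nw <- nrow(tc)
  sub1 <- fractions < 1
  ymat <- with_local_seed(seed, {
    # one random fragment permutation per taxon per draw yields the whole
    # nested fraction series: the first floor(f * N) permuted fragments are
    # a uniform without-replacement subset at every f (subsets at higher
    # fractions contain the lower ones, as in nested read subsampling)
    vapply(seq_len(n_draws), function(d) {
      pres <- matrix(FALSE, nw, sum(sub1))
      for (j in seq_len(ncol(tc))) {
        cnt <- as.integer(round(tc[, j]))
        fw <- rep.int(seq_len(nw), cnt)
        pos <- sample.int(length(fw))
        for (i in seq_len(sum(sub1))) {
          k <- floor(fractions[sub1][i] * cs[j])
          pres[, i] <- pres[, i] | tabulate(fw[pos <= k], nbins = nw) >= tau
        }
      }
      colMeans(pres)
    }, numeric(sum(sub1)))
  })
  ymat <- matrix(ymat, nrow = sum(sub1))
  res <- vector("list", length(fractions))
  res[sub1] <- lapply(seq_len(sum(sub1)), function(i)
    c(mean = mean(ymat[i, ]), sd = stats::sd(ymat[i, ])))
  res[!sub1] <- list(c(mean = full, sd = 0))
  curve <- data.frame(x = fractions,
                      y_mean = vapply(res, `[[`, numeric(1), "mean"),
                      y_sd = vapply(res, `[[`, numeric(1), "sd"),
                      n = ifelse(fractions == 1, 1L, as.integer(n_draws)))
  structure(curve, axis = "depth",
            class = c("rarefaction_curve", "data.frame"))
}

#' Fit and compare saturation models on a rarefaction curve
#'
#' Fits two competing models to curve means by least squares (Gaussian
#' likelihood): a logarithmic, ever-increasing model `y = a + b * log(x)`
#' and a saturating asymptotic regression `y = A + (R0 - A) *
#' exp(-exp(lrc) * x)` (the `SSasymp` parameterization). The winner is the
#' model with minimum BIC; evidence strength is summarized by the BIC-based
#' Bayes factor `exp(|dBIC| / 2)` with the conventional qualitative bands
#' (1-3 weak, 3-20 positive, 20-150 strong, > 150 very strong). The winning
#' model's prediction at twice the current sampling is reported, and the
#' estimated asymptote when the asymptotic model wins.
#'
#' The asymptotic fit tries the self-starting routine first, then explicit
#' starting values (`A = max(y) + 0.05 * range(y)`, `R0 = min(y)`,
#' `lrc = log(1 / median(x))`), then up to 20 jittered Levenberg-Marquardt
#' restarts. If none converge the logarithmic model wins by default and the
#' fit is flagged, never silently.
#'
#' @param curve A `rarefaction_curve`, or any data.frame with columns `x`
#'   and `y_mean` (or `y`); needs >= 4 points.
#' @return A `saturation_fit` object; see [print.saturation_fit()].
#' @export
fit_saturation <- function(curve) {
  x <- curve$x
  y <- curve$y_mean %||% curve$y
  if (is.null(y)) stop("curve needs a `y_mean` or `y` column", call. = FALSE)
  if (length(x) < 4L)
    stop("need >= 4 curve points (the asymptotic model has 3 parameters)",
         call. = FALSE)
  dat <- data.frame(x = x, y = y)
  fit_log <- stats::lm(y ~ log(x), data = dat)

  fit_asym <- NULL
  try(fit_asym <- stats::nls(y ~ SSasymp(x, Asym, R0, lrc), data = dat),
      silent = TRUE)
  if (is.null(fit_asym)) {
    start0 <- list(Asym = max(y) + 0.05 * diff(range(y)), R0 = min(y),
                   lrc = log(1 / stats::median(x)))
    try(fit_asym <- stats::nls(y ~ Asym + (R0 - Asym) * exp(-exp(lrc) * x),
                               data = dat, start = start0), silent = TRUE)
    tries <- 0L
    while (is.null(fit_asym) && tries < 20L) {
      tries <- tries + 1L
      st <- lapply(start0, function(v) v * stats::runif(1, 0.5, 1.5) +
                     stats::rnorm(1, 0, 0.01))
      try(fit_asym <- minpack.lm::nlsLM(
        y ~ Asym + (R0 - Asym) * exp(-exp(lrc) * x),
        data = dat, start = st), silent = TRUE)
    }
  }

  bic_log <- stats::BIC(fit_log)
  converged <- !is.null(fit_asym)
  bic_asym <- if (converged) stats::BIC(fit_asym) else NA_real_
  if (converged) {
    delta <- bic_log - bic_asym  # > 0: asymptotic wins
    winner <- if (bic_asym < bic_log) "asymptotic" else "logarithmic"
  } else {
    delta <- NA_real_
    winner <- "logarithmic"
  }
  bf <- if (is.na(delta)) NA_real_ else exp(abs(delta) / 2)
  support <- if (is.na(bf)) "not assessed (asymptotic fit failed)"
    else if (bf <= 3) "weak" else if (bf <= 20) "positive"
    else if (bf <= 150) "strong" else "very strong"

  x2 <- 2 * max(x)
  pred2 <- if (winner == "asymptotic")
    as.numeric(stats::predict(fit_asym, newdata = data.frame(x = x2)))
  else as.numeric(stats::predict(fit_log, newdata = data.frame(x = x2)))
  asym <- if (converged) unname(stats::coef(fit_asym)["Asym"]) else NA_real_

  structure(list(
    models = list(logarithmic = fit_log, asymptotic = fit_asym),
    bic = c(logarithmic = bic_log, asymptotic = bic_asym),
    delta_bic = delta, bayes_factor = bf, support = support,
    winner = winner, converged = converged,
    asymptote = asym,
    asymptote_plausible = if (is.na(asym)) NA else asym > 0 && asym <= 1,
    predicted_at_2x = pred2, x2 = x2,
    data = dat, axis = attr(curve, "axis") %||% "unknown",
    note = paste("curve points above 50% of the sampling range are not",
                 "statistically independent under the subsampling scheme")),
    class = "saturation_fit")
}

#' @rdname fit_saturation
#' @param x,object A `saturation_fit`.
#' @param ... Unused.
#' @export
print.saturation_fit <- function(x, ...) {
  cat("Saturation model comparison (axis:", x$axis, ",",
      nrow(x$data), "points)\n")
  if (x$converged) {
    cat(sprintf("  BIC logarithmic %.2f | asymptotic %.2f\n",
                x$bic["logarithmic"], x$bic["asymptotic"]))
    cat(sprintf("  winner: %s (Bayes factor %.3g, %s support)\n",
                x$winner, x$bayes_factor, x$support))
  } else {
    cat("  asymptotic fit did not converge; logarithmic wins by default [FLAGGED]\n")
  }
  if (x$winner == "asymptotic")
    cat(sprintf("  estimated asymptote: %.4f%s\n", x$asymptote,
                if (isTRUE(x$asymptote_plausible)) "" else "  [outside (0,1]]"))
  cat(sprintf("  predicted coverage at 2x sampling (x = %g): %.4f\n",
              x$x2, x$predicted_at_2x))
  invisible(x)
}

#' @rdname fit_saturation
#' @export
coef.saturation_fit <- function(object, ...) {
  list(logarithmic = stats::coef(object$models$logarithmic),
       asymptotic = if (object$converged)
         stats::coef(object$models$asymptotic) else NULL)
}

#' @rdname fit_saturation
#' @param newdata Optional data.frame with column `x`.
#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  mod <- object$models[[object$winner]]
  as.numeric(stats::predict(mod, newdata = newdata))
}

#' @rdname fit_saturation
#' @export
plot.saturation_fit <- function(x, ...) {
  dat <- x$data
  plot(dat$x, dat$y, xlab = "sampling units", ylab = "coverage fraction",
       pch = 19, ...)
  xx <- seq(min(dat$x), x$x2, length.out = 200)
  graphics::lines(xx, as.numeric(stats::predict(
    x$models$logarithmic, newdata = data.frame(x = xx))), lty = 2)
  if (x$converged)
    graphics::lines(xx, as.numeric(stats::predict(
      x$models$asymptotic, newdata = data.frame(x = xx))), lty = 1)
  graphics::legend("bottomright", legend = c("logarithmic", "asymptotic"),
                   lty = c(2, 1), bty = "n")
  invisible(x)
}
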