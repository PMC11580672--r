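#' Count particles in a grayscale image by auto-threshold and watershed
#'
#' Reproduces the classic particle-counting recipe: an automatic global
#' threshold (Otsu by default) gives a foreground mask, a distance-transform
#' watershed splits touching objects, and connected components of at least
#' `min_size` pixels are counted with centroids, areas and mean intensities.
#' Intensities are min-max normalized before thresholding, so counting is
#' invariant to linear intensity rescaling.
#'
#' @param image 2D numeric matrix (single channel).
#' @param min_size minimum particle area in pixels (default 30).
#' @param threshold_method "otsu" (default) or a numeric threshold on the
#'   normalized \[0,1\] intensities.
#' @param watershed_tolerance tolerance of the watershed split (default 1).
#' @param intensity_channels optional named list of same-shape matrices whose
#'   per-particle mean intensities are reported.
#' @return list of class `quant_result`: `particle_count` and `particles`
#'   (data.frame: label, x (column), y (row), area, mean_intensity, plus one
#'   `mean_<name>` column per extra channel).
#' @export
count_particles <- function(image, min_size = 30L,
                            threshold_method = "otsu",
                            watershed_tolerance = 1,
                            intensity_channels = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2D numeric matrix")
  }
  rng <- range(image)
  empty <- structure(list(
    particle_count = 0L,
    particles = data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                           area = integer(0), mean_intensity = numeric(0))),
    class = "quant_result")
  if (diff(rng) == 0) return(empty)
  norm <- (image - rng[1]) / diff(rng)
  thr <- if (identical(threshold_method, "otsu")) {
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else if (is.numeric(threshold_method)) {
    threshold_method
  } else stop("unknown threshold_method: ", threshold_method)
  mask <- norm > thr
  if (!any(mask)) return(empty)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance,
                                               ext = 1))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_size)
  if (!length(keep)) return(empty)
  rows <- row(lab); cols <- col(lab)
  parts <- do.call(rbind, lapply(seq_along(keep), function(i) {
    sel <- lab == keep[i]
    data.frame(label = i,
               x = mean(cols[sel]), y = mean(rows[sel]),
               area = sum(sel), mean_intensity = mean(image[sel]))
  }))
  if (!is.null(intensity_channels)) {
    for (nm in names(intensity_channels)) {
      ch <- intensity_channels[[nm]]
      parts[[paste0("mean_", nm)]] <- vapply(seq_along(keep), function(i) {
        mean(ch[lab == keep[i]])
      }, numeric(1))
    }
  }
  structure(list(particle_count = nrow(parts), particles = parts),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %d particles\n", x$particle_count))
  invisible(x)
}

# two-sided p-value and Fisher-z 95% CI for a Pearson r at sample size n
pearson_inference <- function(r, n, conf = 0.95) {
  if (abs(r) >= 1) {
    return(list(p_value = 0, ci = c(r, r)))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * zc / sqrt(n - 3))
  list(p_value = p, ci = ci)
}

#' Two-channel colocalization by Pearson correlation
#'
#' Pearson correlation of the two channels over the in-mask pixels of one
#' cell crop, with the standard inference used for correlation coefficients:
#' a t-test p-value `t = r sqrt((n-2)/(1-r^2))` and a 95% confidence interval
#' by the Fisher z transform `tanh(atanh(r) +/- 1.96 / sqrt(n-3))`.
#'
#' @param ch1,ch2 same-shape numeric matrices (the two channels).
#' @param mask logical matrix selecting the analyzed pixels (default: all);
#'   at least 10 pixels are required.
#' @param cell_id identifier carried into the record.
#' @return one-row data.frame (a colocalization record): `cell_id`, `r`, `n`,
#'   `p_value`, `ci_lo`, `ci_hi`, `flag` ("ok" or "zero_variance").
#' @export
colocalize <- function(ch1, ch2, mask = NULL, cell_id = "cell") {
  stopifnot(is.matrix(ch1), is.matrix(ch2), all(dim(ch1) == dim(ch2)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  stopifnot(all(dim(mask) == dim(ch1)))
  x <- ch1[mask]; y <- ch2[mask]
  n <- length(x)
  if (n < 10) stop("mask must contain at least 10 pixels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(cell_id = cell_id, r = NA_real_, n = n,
                      p_value = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      flag = "zero_variance"))
  }
  r <- stats::cor(x, y)
  inf <- pearson_inference(r, n)
  data.frame(cell_id = cell_id, r = r, n = n, p_value = inf$p_value,
             ci_lo = inf$ci[1], ci_hi = inf$ci[2], flag = "ok")
}

#' Group-level correlation of two markers across cells
#'
#' Pearson correlation of per-cell mean intensities of two markers (e.g. a
#' disease-associated marker vs. a signalling marker), with the same t-test
#' p-value and Fisher z confidence interval as [colocalize()].
#'
#' @param marker1,marker2 per-cell mean intensities (equal length >= 4; the
#'   Fisher interval is undefined at n = 3).
#' @return list: `r`, `n`, `p_value`, `ci` (length 2), and `table` (the
#'   per-cell scatter data).
#' @export
correlate_expression <- function(marker1, marker2) {
  stopifnot(length(marker1) == length(marker2))
  n <- length(marker1)
  if (n < 4) stop("need >= 4 cells for a correlation with a Fisher z CI")
  if (stats::sd(marker1) == 0 || stats::sd(marker2) == 0) {
    stop("zero-variance marker values")
  }
  r <- stats::cor(marker1, marker2)
  inf <- pearson_inference(r, n)
  list(r = r, n = n, p_value = inf$p_value, ci = inf$ci,
       table = data.frame(marker1 = marker1, marker2 = marker2))
}

#' Compare a measurement across experimental groups
#'
#' Two groups: two-sided t-test (Welch by default, pooled-variance
#' optionally). Three or more groups: one-way ANOVA followed by Tukey HSD
#' post-hoc tests on all pairs. Group summaries are reported as
#' mean +/- SEM.
#'
#' @param values numeric measurements.
#' @param group group labels (coerced to factor), >= 2 groups with >= 2
#'   values each.
#' @param var_equal use the pooled-variance t-test for two groups
#'   (default FALSE = Welch).
#' @return object of class `group_comparison`: `summary` (per-group mean,
#'   sem, n), `test` ("t" or "anova"), `statistic` (t or F), `df`, `p_value`,
#'   and for >= 3 groups `posthoc` (data.frame: pair, diff, p_adj).
#' @export
compare_groups <- function(values, group, var_equal = FALSE) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  sizes <- table(group)
  if (length(sizes) < 2L) stop("need >= 2 groups")
  if (any(sizes < 2L)) stop("every group needs >= 2 values")
  summ <- data.frame(
    group = levels(group),
    mean = as.numeric(tapply(values, group, mean)),
    sem = as.numeric(tapply(values, group,
                            function(v) stats::sd(v) / sqrt(length(v)))),
    n = as.integer(sizes)
  )
  if (length(sizes) == 2L) {
    tt <- stats::t.test(values ~ group, var.equal = var_equal)
    out <- list(summary = summ, test = "t",
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, posthoc = NULL)
  } else {
    fit <- stats::aov(values ~ group)
    an <- stats::anova(fit)
    tk <- stats::TukeyHSD(fit)$group
    out <- list(summary = summ, test = "anova",
                statistic = an[["F value"]][1],
                df = c(an$Df[1], an$Df[2]), p_value = an[["Pr(>F)"]][1],
                posthoc = data.frame(pair = rownames(tk),
                                     diff = tk[, "diff"],
                                     lwr = tk[, "lwr"], upr = tk[, "upr"],
                                     p_adj = tk[, "p adj"],
                                     row.names = NULL))
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- if (x$test == "t") {
    sprintf("t = %.3f, df = %.1f", x$statistic, x$df)
  } else {
    sprintf("F = %.3f, df = (%d, %d)", x$statistic, x$df[1], x$df[2])
  }
  cat(sprintf("<group_comparison> %s, p = %.4g\n", lab, x$p_value))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n", x$summary$group[i],
                x$summary$mean[i], x$summary$sem[i], x$summary$n[i]))
  }
  if (!is.null(x$posthoc)) {
    cat("  Tukey HSD adjusted p-values:\n")
    for (i in seq_len(nrow(x$posthoc))) {
      cat(sprintf("    %s: %.4g\n", x$posthoc$pair[i], x$posthoc$p_adj[i]))
    }
  }
  invisible(x)
}
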