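#' Fraction of RNA bound from filter counts
#'
#' Nitrocellulose retains the protein-bound RNA, nylon the free RNA;
#' the fraction bound is `Fb = N / (N + Y)`.
#'
#' @param counts_nitrocellulose,counts_nylon non-negative counts; both
#'   zero is an undefined point (error).
#' @return fraction in `[0, 1]`.
#' @export
fraction_bound <- function(counts_nitrocellulose, counts_nylon) {
  if (any(counts_nitrocellulose < 0) || any(counts_nylon < 0)) {
    stop("counts must be non-negative")
  }
  tot <- counts_nitrocellulose + counts_nylon
  if (any(tot == 0)) stop("undefined point: both filter counts are zero")
  counts_nitrocellulose / tot
}

#' One-site hyperbolic binding model
#'
#' `Fb = Max% * c / (c + K_D)`: at `c = K_D` the model gives
#' `Max% / 2`.
#'
#' @param conc protein concentration(s), nM.
#' @param kd dissociation constant, nM.
#' @param max_pct plateau fraction bound.
#' @return model fraction bound.
#' @export
binding_model <- function(conc, kd, max_pct) {
  max_pct * conc / (conc + kd)
}

#' Fit the one-site binding isotherm
#'
#' Least-squares fit of `(K_D, Max%)` to titration data.  The plateau
#' `Max%` has a closed-form conditional optimum at fixed `K_D`
#' (clamped to `(0, 1]`), so the fit profiles the residual sum of
#' squares over a coarse logarithmic `K_D` grid
#' (`1e-2` to `1e4` nM) and refines the grid optimum by a bounded
#' one-dimensional continuous minimisation -- deterministic and exact
#' for noiseless data.  A fit is censored when the fitted `K_D`
#' exceeds the maximum assayed concentration; the reported bound is
#' that concentration (the ">max" convention used when a titration
#' never approaches saturation).
#'
#' @param dataset data frame with columns `conc` (nM) and either `fb`
#'   or `counts_nc` + `counts_nylon`; at least 4 distinct
#'   concentrations.  `fb` values outside `[0, 1]` (possible with
#'   noisy counts) are clipped for fitting, with a warning.
#' @param max_conc censoring threshold; defaults to the maximum
#'   assayed concentration in `dataset`.
#' @return Object of class `binding_fit`: list with `kd`, `max_pct`,
#'   `rss`, `censored`, `kd_bound`, `n`.
#' @export
fit_binding <- function(dataset, max_conc = NULL) {
  conc <- dataset$conc
  fb <- if (!is.null(dataset$fb)) dataset$fb else
    fraction_bound(dataset$counts_nc, dataset$counts_nylon)
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations")
  }
  if (any(fb < 0 | fb > 1)) {
    warning("fraction-bound values outside [0,1] clipped for fitting")
    fb <- pmin(pmax(fb, 0), 1)
  }
  if (is.null(max_conc)) max_conc <- max(conc)

  # profile RSS over K_D: conditional Max% is closed-form
  prss <- function(log10_kd) {
    kd <- 10^log10_kd
    g <- conc / (conc + kd)
    a <- sum(g * g)
    if (a == 0) return(sum(fb^2))
    m <- min(max(sum(fb * g) / a, 1e-6), 1)
    sum((fb - m * g)^2)
  }
  grid <- seq(-3, 6, by = 0.05)
  rss_grid <- vapply(grid, prss, numeric(1L))
  k0 <- grid[which.min(rss_grid)]
  opt <- optimize(prss, lower = k0 - 0.2, upper = k0 + 0.2, tol = 1e-10)
  kd <- 10^opt$minimum
  g <- conc / (conc + kd)
  max_pct <- min(max(sum(fb * g) / sum(g * g), 1e-6), 1)
  rss <- sum((fb - max_pct * g)^2)
  censored <- kd > max_conc
  structure(list(kd = kd, max_pct = max_pct, rss = rss,
                 censored = censored,
                 kd_bound = if (censored) max_conc else NA_real_,
                 n = length(conc)),
            class = "binding_fit")
}

#' Aggregate replicate binding fits
#'
#' Reports the mean and sample standard deviation of `K_D` over
#' uncensored replicate fits.  If any replicate is censored the
#' aggregate is reported censored at the bound (the conservative
#' convention for weak binders).  Fewer than `min_n` replicates
#' triggers a warning.
#'
#' @param fits list of `binding_fit` objects.
#' @param min_n replicate count below which a warning is issued
#'   (default 3).
#' @return list with `kd_mean`, `kd_sd` (`NA` when fewer than 2
#'   uncensored fits), `n`, `censored`, `kd_bound`, `label` (e.g.
#'   `"22 +/- 2 nM"` or `">500 nM"`).
#' @export
aggregate_fits <- function(fits, min_n = 3L) {
  stopifnot(length(fits) >= 1L)
  if (length(fits) < min_n) {
    warning("only ", length(fits), " replicate fit(s); fewer than ", min_n)
  }
  cens <- vapply(fits, function(f) f$censored, logical(1L))
  kds <- vapply(fits, function(f) f$kd, numeric(1L))
  bound <- if (any(cens)) {
    max(vapply(fits[cens], function(f) f$kd_bound, numeric(1L)))
  } else NA_real_
  ok <- kds[!cens]
  kd_mean <- if (length(ok)) mean(ok) else NA_real_
  kd_sd <- if (length(ok) >= 2L) sd(ok) else NA_real_
  label <- if (any(cens)) {
    paste0(">", format(bound), " nM")
  } else if (!is.na(kd_sd)) {
    paste0(format(signif(kd_mean, 3)), " +/- ", format(signif(kd_sd, 2)),
           " nM")
  } else {
    paste0(format(signif(kd_mean, 3)), " nM (n=1, SD --)")
  }
  list(kd_mean = kd_mean, kd_sd = kd_sd, n = length(fits),
       censored = any(cens), kd_bound = bound, label = label)
}

#' Reporter fluorescence statistics
#'
#' Normalises GFP fluorescence to cell density (GFP/OD600) per
#' replicate, reports per-condition means, the fold change
#' `mean(uninduced) / mean(induced)` (repression by the induced
#' protein gives a fold change above 1), a two-sided Welch t-test on
#' the normalised values, and significance stars (`*` for p < 0.01,
#' `**` for p < 0.001).  With fewer than 3 replicates per condition
#' the test is suppressed and only the means are reported.
#'
#' @param data data frame with columns `condition` (values `induced`
#'   and `uninduced`), `gfp`, `od600` (> 0).
#' @return list with `relative_fluorescence` (named means),
#'   `fold_change`, `p_value`, `stars`, `n`.
#' @export
reporter_stats <- function(data) {
  stopifnot(all(c("condition", "gfp", "od600") %in% names(data)))
  if (any(data$od600 <= 0)) stop("od600 must be positive")
  data$condition <- as.character(data$condition)
  bad <- setdiff(unique(data$condition), c("induced", "uninduced"))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  norm <- data$gfp / data$od600
  ind <- norm[data$condition == "induced"]
  uni <- norm[data$condition == "uninduced"]
  if (!length(ind) || !length(uni)) {
    stop("need replicates for both induced and uninduced conditions")
  }
  means <- c(induced = mean(ind), uninduced = mean(uni))
  fold <- means[["uninduced"]] / means[["induced"]]
  n <- c(induced = length(ind), uninduced = length(uni))
  if (all(n >= 3L)) {
    # degenerate zero-variance data (possible in exact toy examples)
    # cannot support a t statistic; report NA rather than certainty
    p <- tryCatch(t.test(uni, ind, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
    stars <- if (is.na(p)) NA_character_ else
      if (p < 0.001) "**" else if (p < 0.01) "*" else ""
  } else {
    p <- NA_real_
    stars <- NA_character_
  }
  list(relative_fluorescence = means, fold_change = unname(fold),
       p_value = p, stars = stars, n = n)
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$censored) {
    cat("<binding_fit> K_D > ", format(x$kd_bound), " nM (censored), Max% ",
        round(100 * x$max_pct, 1), "\n", sep = "")
  } else {
    cat("<binding_fit> K_D = ", format(signif(x$kd, 4)), " nM, Max% ",
        round(100 * x$max_pct, 1), ", RSS ", signif(x$rss, 3), "\n",
        sep = "")
  }
  invisible(x)
}
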