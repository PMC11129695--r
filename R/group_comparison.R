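#' Compare a display metric among lure groups
#'
#' Omnibus Kruskal-Wallis test across all groups, followed by all pairwise
#' two-sample Wilcoxon rank-sum (Mann-Whitney) comparisons with a Bonferroni
#' adjustment over the number of pairs. The rank-sum statistic `W` is reported
#' for the first group of each pair (groups are compared in the order they
#' first appear), so complete separation with the first group shifted low
#' gives `W = 0`. Exact p-values are used for small samples without ties, the
#' normal approximation otherwise (the `stats::wilcox.test` rule).
#'
#' @param summaries a data.frame of per-recording summaries (one row per
#'   recording, as from [summarize_displays()]).
#' @param metric name of the summary column to compare, e.g.
#'   `"mean_interval_left"`, `"sd_interval_left"`, `"mean_duration_left"`,
#'   `"proportion_sync"`.
#' @param group_col name of the grouping column (default `"morph"`); or pass
#'   `group` as an explicit vector.
#' @param group optional explicit group label per row, overriding `group_col`.
#' @return object of class `group_comparison`: list with `metric`, `groups`,
#'   `kruskal` (list `H`, `df`, `p`), and `pairwise` (data.frame `group_a`,
#'   `group_b`, `n_a`, `n_b`, `W`, `p_raw`, `p_bonferroni`).
#' @export
compare_groups <- function(summaries, metric, group_col = "morph",
                           group = NULL) {
  if (!metric %in% names(summaries)) {
    stop("metric '", metric, "' is not a column of `summaries`")
  }
  g <- group %||% summaries[[group_col]]
  g <- as.character(g)
  x <- summaries[[metric]]
  keep <- !is.na(x) & !is.na(g)
  for (lev in unique(g)) {
    if (!any(keep & g == lev)) {
      stop("metric '", metric, "' is missing for every member of group '",
           lev, "'")
    }
  }
  x <- x[keep]
  g <- g[keep]
  levs <- unique(g)
  if (length(levs) < 2L) stop("need at least 2 groups, got ", length(levs))

  if (length(unique(x)) == 1L) {
    kr <- list(H = 0, df = length(levs) - 1L, p = 1) # all values tied: no signal
  } else {
    kt <- stats::kruskal.test(x, factor(g, levels = levs))
    kr <- list(H = unname(kt$statistic), df = unname(kt$parameter),
               p = kt$p.value)
  }

  pairs <- utils::combn(levs, 2L)
  n_tests <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_tests), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    xa <- x[g == a]; xb <- x[g == b]
    if (length(unique(c(xa, xb))) == 1L) {
      W <- length(xa) * length(xb) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(xa, xb))
      W <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(group_a = a, group_b = b, n_a = length(xa), n_b = length(xb),
               W = W, p_raw = p, p_bonferroni = min(1, p * n_tests),
               stringsAsFactors = FALSE)
  }))
  structure(list(metric = metric, groups = levs, kruskal = kr, pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> metric:", x$metric, "\n")
  cat(sprintf("  Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Spearman correlation of mean movement interval with water temperature
#'
#' @param summaries per-recording summary table with `water_temp_c` and the
#'   interval column.
#' @param metric interval column to correlate (default left-side mean).
#' @return list with `rho`, `p`, and `n` (recordings used).
#' @export
temperature_correlation <- function(summaries,
                                    metric = "mean_interval_left") {
  x <- summaries$water_temp_c
  y <- summaries[[metric]]
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3L) {
    stop("need at least 3 recordings with both water temperature and '",
         metric, "'; have ", sum(keep))
  }
  ct <- suppressWarnings(
    stats::cor.test(x[keep], y[keep], method = "spearman")
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Bootstrap-resample a set of movement intervals
#'
#' Draws exactly `n_boot` values with replacement from `values`,
#' reproducibly under `seed`. Used to give every individual an equal-sized
#' interval dataset before mixed-model fitting, since individuals differ in
#' how many movements fall in the analysis window.
#'
#' @param values non-empty numeric vector (interval values in seconds).
#' @param n_boot number of resampled values (default 1000).
#' @param seed integer seed.
#' @return numeric vector of length `n_boot`.
#' @export
bootstrap_movements <- function(values, n_boot = 1000, seed) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  if (n_boot <= 0) stop("n_boot must be > 0")
  with_seed(seed,
            values[sample.int(length(values), size = n_boot, replace = TRUE)])
}

#' Build per-recording bootstrap interval datasets
#'
#' For each recording, extracts the start-to-start intervals of the chosen
#' side(s) and resamples them to a common size with [bootstrap_movements()].
#' Recordings with no interval on the chosen side are dropped with a message.
#'
#' @param recordings list of `display_recording` objects.
#' @param side `"left"` (default, matching the side used for the group
#'   summaries), `"right"`, or `"pooled"` (both sides' intervals pooled).
#' @param n_boot resamples per recording.
#' @param seed master seed; each recording gets a seed derived from it.
#' @return data.frame with columns `recording_id`, `group` (the morph, with
#'   the congener's `"none"` relabelled by species), `value` (seconds).
#' @export
bootstrap_study <- function(recordings, side = c("left", "right", "pooled"),
                            n_boot = 1000, seed = 1L) {
  side <- match.arg(side)
  out <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    iv <- switch(side,
      left = movement_intervals(rec$left, rec$fps),
      right = movement_intervals(rec$right, rec$fps),
      pooled = c(movement_intervals(rec$left, rec$fps),
                 movement_intervals(rec$right, rec$fps))
    )
    if (!length(iv)) {
      message("recording ", rec$recording_id,
              ": no intervals on side '", side, "'; dropped from bootstrap")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      recording_id = rec$recording_id,
      group = display_group(rec),
      value = bootstrap_movements(iv, n_boot, derive_seed(seed, i)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) stop("no recording contributed intervals")
  do.call(rbind, out)
}

# Group label for comparisons: morph for the polymorphic species, species
# name for the monomorphic congener.
display_group <- function(rec) {
  if (rec$morph == "none") rec$species else rec$morph
}

#' Random-intercept mixed model of movement interval on lure group
#'
#' Fits `value ~ group + (1 | recording_id)` by REML with `lmerTest`, so
#' fixed-effect tests use Satterthwaite denominator degrees of freedom. The
#' random intercept per recording keeps the group comparison driven by
#' between-individual variation even though bootstrapping inflates the number
#' of rows per individual.
#'
#' @param bootstrapped data.frame from [bootstrap_study()] (columns
#'   `recording_id`, `group`, `value`).
#' @return object of class `mixed_model_result`: list with `coefficients`
#'   (the Satterthwaite coefficient table), `group_means` (named vector of
#'   fitted group means, seconds), `ranef_variance` (between-recording
#'   intercept variance, s^2), `resid_variance`, `singular` flag, `n_boot`,
#'   and the fitted `model`.
#' @export
fit_interval_mixed_model <- function(bootstrapped) {
  need <- c("recording_id", "group", "value")
  miss <- setdiff(need, names(bootstrapped))
  if (length(miss)) stop("bootstrapped data is missing: ",
                         paste(miss, collapse = ", "))
  levs <- unique(bootstrapped$group)
  if (length(levs) < 2L) stop("need at least 2 groups, got ", length(levs))
  dat <- bootstrapped
  dat$group <- factor(dat$group, levels = levs)
  fit <- suppressMessages(lmerTest::lmer(
    value ~ group + (1 | recording_id), data = dat, REML = TRUE
  ))
  singular <- lme4::isSingular(fit)
  ctab <- stats::coef(summary(fit)) # Satterthwaite df via lmerTest
  fe <- lme4::fixef(fit)
  gm <- c(fe[1L], fe[1L] + fe[-1L])
  names(gm) <- levs
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(coefficients = ctab, group_means = gm,
         ranef_variance = vc$vcov[vc$grp == "recording_id"],
         resid_variance = vc$vcov[vc$grp == "Residual"],
         singular = singular,
         n_boot = max(table(dat$recording_id)),
         model = fit),
    class = "mixed_model_result"
  )
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("<mixed_model_result> interval ~ group + (1 | recording)\n")
  cat("  group means (s):",
      paste(sprintf("%s = %.3g", names(x$group_means), x$group_means),
            collapse = ", "), "\n")
  cat(sprintf("  random-intercept variance: %.4g s^2; residual: %.4g s^2%s\n",
              x$ranef_variance, x$resid_variance,
              if (x$singular) " [singular fit]" else ""))
  printCoefmat(x$coefficients, digits = 3)
  invisible(x)
}
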