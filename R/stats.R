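# Two-level hierarchical bootstrap for nested mouse/ROI data, two-group
# comparison with a tie-aware exceedance probability p_boot, and pairwise
# ROI activity correlations.

#' Two-level hierarchical bootstrap of a nested sample
#'
#' Each iteration resamples mice with replacement (as many as observed),
#' then within every drawn mouse resamples its per-ROI values with
#' replacement (that mouse's observed count), and records the mean over
#' all resampled values. This propagates both between-mouse and
#' within-mouse variability into the distribution of the group mean.
#'
#' @param values Numeric statistic per ROI (e.g. LocMI, onset lag).
#' @param mouse Mouse identifier per value (same length).
#' @param n_boot Iterations, default 10000.
#' @param seed Optional seed; identical inputs and seed give identical
#'   output.
#' @return Numeric vector of `n_boot` bootstrap means.
#' @export
hierarchical_bootstrap <- function(values, mouse, n_boot = 10000,
                                   seed = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty sample")
  if (length(mouse) != length(values)) {
    stop("`mouse` must have one entry per value")
  }
  keep <- is.finite(values)
  values <- values[keep]
  mouse <- as.character(mouse)[keep]
  if (length(values) == 0L) stop("no finite values in sample")
  by_mouse <- split(values, mouse)
  m <- length(by_mouse)
  sizes <- lengths(by_mouse)
  with_seed(seed, {
    # mouse drawn for every (iteration, slot); for each mouse, all of its
    # slot occurrences are resampled at once and aggregated per iteration
    slots <- matrix(sample.int(m, n_boot * m, replace = TRUE),
                    nrow = n_boot, ncol = m)
    sum_mat <- matrix(0, n_boot, m)
    cnt_mat <- matrix(0, n_boot, m)
    for (j in seq_len(m)) {
      occ <- which(slots == j)
      if (!length(occ)) next
      nj <- sizes[j]
      draws <- matrix(
        by_mouse[[j]][sample.int(nj, length(occ) * nj, replace = TRUE)],
        nrow = length(occ)
      )
      sum_mat[occ] <- rowSums(draws)
      cnt_mat[occ] <- nj
    }
    rowSums(sum_mat) / rowSums(cnt_mat)
  })
}

#' Compare two groups by hierarchical bootstrap
#'
#' Runs [hierarchical_bootstrap()] in both groups, pairs the iterations,
#' and estimates the exceedance probability
#' `p_one = (#\{mA > mB\} + 0.5 #\{mA = mB\}) / n_boot` - the probability
#' that group A's bootstrap mean exceeds group B's, with ties counted as
#' one half. The reported `p_boot` is the two-sided
#' `2 * min(p_one, 1 - p_one)` by default, or `min(p_one, 1 - p_one)` for
#' a one-sided test.
#'
#' @param values_a,mouse_a Group A statistic per ROI and mouse labels.
#' @param values_b,mouse_b Group B likewise.
#' @param n_boot Iterations, default 10000; fewer than 100 triggers a
#'   warning (unstable tail estimate).
#' @param seed Optional seed covering both groups.
#' @param sided `"two"` (default) or `"one"`.
#' @param alpha Significance level, default 0.05.
#' @param labels Length-2 character vector naming the groups.
#' @return Object of class `bootstrap_comparison`: `p_boot`, `p_one`,
#'   `significant`, per-group observed means, bootstrap means and 2.5/97.5
#'   percentile intervals, plus the bootstrap draws.
#' @export
compare_groups <- function(values_a, mouse_a, values_b, mouse_b,
                           n_boot = 10000, seed = NULL,
                           sided = c("two", "one"), alpha = 0.05,
                           labels = c("A", "B")) {
  sided <- match.arg(sided)
  if (n_boot < 100) {
    warning("n_boot < 100 gives an unstable tail estimate", call. = FALSE)
  }
  res <- with_seed(seed, {
    boot_a <- hierarchical_bootstrap(values_a, mouse_a, n_boot, seed = NULL)
    boot_b <- hierarchical_bootstrap(values_b, mouse_b, n_boot, seed = NULL)
    list(a = boot_a, b = boot_b)
  })
  p_one <- (sum(res$a > res$b) + 0.5 * sum(res$a == res$b)) / n_boot
  p_boot <- if (sided == "two") {
    min(2 * min(p_one, 1 - p_one), 1)
  } else {
    min(p_one, 1 - p_one)
  }
  structure(
    list(
      labels = labels, n_boot = n_boot, seed = seed, sided = sided,
      alpha = alpha, p_one = p_one, p_boot = p_boot,
      significant = p_boot < alpha,
      mean_a = mean(as.numeric(values_a), na.rm = TRUE),
      mean_b = mean(as.numeric(values_b), na.rm = TRUE),
      boot_mean_a = mean(res$a), boot_mean_b = mean(res$b),
      ci_a = stats::quantile(res$a, c(0.025, 0.975), names = FALSE),
      ci_b = stats::quantile(res$b, c(0.025, 0.975), names = FALSE),
      boot_a = res$a, boot_b = res$b
    ),
    class = "bootstrap_comparison"
  )
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("Hierarchical bootstrap comparison (%s-sided, %d iterations)\n",
              x$sided, x$n_boot))
  cat(sprintf("  %s: mean %.4f, boot 95%% CI [%.4f, %.4f]\n",
              x$labels[1], x$boot_mean_a, x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  %s: mean %.4f, boot 95%% CI [%.4f, %.4f]\n",
              x$labels[2], x$boot_mean_b, x$ci_b[1], x$ci_b[2]))
  cat(sprintf("  p_boot = %.4g (P[%s > %s] = %.4g)%s\n",
              x$p_boot, x$labels[1], x$labels[2], x$p_one,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pairwise activity correlations between astrocytic ROIs
#'
#' Pearson correlation between the dF/F traces of every unordered pair of
#' astrocytic ROIs within one session. Pairs involving a zero-variance
#' trace are emitted with a missing r.
#'
#' @param dff_list List of `dff_trace` objects from one session.
#' @param compartments Compartments included (default: the four astrocytic
#'   classes).
#' @return Data.frame: `roi_a`, `roi_b`, `r`.
#' @export
pairwise_roi_correlation <- function(dff_list,
                                     compartments = ASTRO_COMPARTMENTS) {
  comp <- vapply(dff_list, function(d) d$compartment, character(1))
  astro <- dff_list[comp %in% compartments]
  if (length(astro) < 2L) {
    stop("need at least 2 astrocytic ROIs for pairwise correlations")
  }
  mat <- vapply(astro, function(d) d$dff, numeric(length(astro[[1]]$dff)))
  ids <- vapply(astro, function(d) d$roi_id, character(1))
  sds <- apply(mat, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(mat))
  pairs <- utils::combn(length(astro), 2)
  data.frame(
    roi_a = ids[pairs[1, ]],
    roi_b = ids[pairs[2, ]],
    r = ifelse(sds[pairs[1, ]] == 0 | sds[pairs[2, ]] == 0, NA_real_,
               cm[t(pairs)])
  )
}
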