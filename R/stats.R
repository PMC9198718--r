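#' Significance star label
#' @param p P-value.
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.05) or
#'   `"ns"`.
#' @export
star_label <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Assumption-gated group comparison
#'
#' The study's testing scheme: Shapiro-Wilk normality per group and Levene's
#' test (classic, mean-centered) of equal variances across groups; if every
#' assumption test passes at `alpha_gate`, a one-way ANOVA with Tukey HSD
#' pairwise comparisons against the reference group is run; otherwise
#' pairwise Mann-Whitney (Wilcoxon rank-sum) tests against the reference.
#' Star labels use the 0.05 / 0.01 / 0.001 thresholds. Undefined (`NA`)
#' values are excluded from testing but counted; groups with fewer than 3
#' usable values are dropped with a warning.
#'
#' No multiplicity correction is applied beyond Tukey's procedure (the
#' rank-sum branch is uncorrected).
#'
#' @param values Numeric vector of per-cell metric values.
#' @param groups Group (variant) labels, same length.
#' @param reference Reference group for pairwise comparisons (default
#'   `"WT"`, or the first group if absent).
#' @param alpha_gate Significance level of the assumption gate.
#' @return An object of class `group_comparison`: `method`
#'   (`"anova_tukey"` or `"mann_whitney"`), `gate` (Shapiro p per group,
#'   Levene p, decision), `omnibus` (ANOVA F and p, if run), `pairwise`
#'   (data frame: group, estimate, p, stars), `n_excluded`.
#' @export
compare_groups <- function(values, groups, reference = "WT",
                           alpha_gate = 0.05) {
  groups <- as.character(groups)
  ok <- is.finite(values)
  n_excluded <- sum(!ok)
  values <- values[ok]; groups <- groups[ok]

  counts <- table(groups)
  small <- names(counts)[counts < 3]
  if (length(small) > 0) {
    warning("dropping groups with n < 3: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  glev <- unique(groups)
  if (length(glev) < 2) stop("need at least 2 groups with n >= 3")
  if (!reference %in% glev) reference <- glev[1]
  gf <- factor(groups, levels = c(reference, setdiff(glev, reference)))

  shapiro_p <- vapply(split(values, gf), function(x) {
    if (length(unique(x)) < 3) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }, 0)
  levene_p <- car::leveneTest(values ~ gf, center = "mean")[1, "Pr(>F)"]
  parametric <- all(shapiro_p > alpha_gate) && levene_p > alpha_gate

  others <- setdiff(levels(gf), reference)
  if (parametric) {
    fit <- stats::aov(values ~ gf)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$gf
    wanted <- c(paste0(others, "-", reference), paste0(reference, "-", others))
    rows <- rownames(tk) %in% wanted
    tkv <- tk[rows, , drop = FALSE]
    # orient estimates as other - reference
    flip <- startsWith(rownames(tkv), paste0(reference, "-"))
    est <- ifelse(flip, -tkv[, "diff"], tkv[, "diff"])
    grp <- sub(paste0("-", reference, "$"), "", rownames(tkv))
    grp[flip] <- sub(paste0("^", reference, "-"), "", rownames(tkv)[flip])
    pairwise <- data.frame(group = grp, estimate = est,
                           p = tkv[, "p adj"], stringsAsFactors = FALSE)
    omnibus <- list(statistic = an[1, "F value"], p = an[1, "Pr(>F)"],
                    df = an[, "Df"])
    method <- "anova_tukey"
  } else {
    ref_vals <- values[gf == reference]
    pairwise <- do.call(rbind, lapply(others, function(g) {
      x <- values[gf == g]
      wt <- suppressWarnings(stats::wilcox.test(x, ref_vals))
      data.frame(group = g, estimate = stats::median(x) - stats::median(ref_vals),
                 p = wt$p.value, stringsAsFactors = FALSE)
    }))
    omnibus <- NULL
    method <- "mann_whitney"
  }
  pairwise$stars <- star_label(pairwise$p)
  rownames(pairwise) <- NULL
  structure(list(method = method,
                 gate = list(shapiro_p = shapiro_p, levene_p = levene_p,
                             parametric = parametric,
                             alpha = alpha_gate),
                 omnibus = omnibus, pairwise = pairwise,
                 reference = reference, n_excluded = n_excluded),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison vs %s: %s (gate: %s)\n", x$reference,
              if (x$method == "anova_tukey")
                "one-way ANOVA + Tukey HSD" else "pairwise Mann-Whitney",
              if (x$gate$parametric) "assumptions passed" else "assumptions failed"))
  if (!is.null(x$omnibus))
    cat(sprintf("  ANOVA F = %.3f, p = %.3g\n", x$omnibus$statistic,
                x$omnibus$p))
  print(x$pairwise, row.names = FALSE)
  if (x$n_excluded > 0)
    cat(sprintf("  (%d undefined values excluded)\n", x$n_excluded))
  invisible(x)
}
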