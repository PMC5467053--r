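#' Extract one measure of a long cohort table in analysis (wide) form
#'
#' @param cohort Long-format cohort table (see [simulate_cohort()]).
#' @param measure Measure name.
#' @return Data frame with `animal`, `genotype`, `drug`, `group`,
#'   `within_level`, `value` rows for that measure.
#' @export
measure_table <- function(cohort, measure) {
  stopifnot(is.data.frame(cohort), "measure" %in% names(cohort))
  out <- cohort[cohort$measure == measure, , drop = FALSE]
  if (!nrow(out)) stop("no rows for measure '", measure, "'")
  rownames(out) <- NULL
  out
}

new_stat_results <- function(df) {
  structure(df, class = c("stat_results", "data.frame"))
}

#' @export
print.stat_results <- function(x, ...) {
  cat("<stat_results>\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Between-subjects factorial ANOVA (type III)
#'
#' Fits `value ~ f1 * f2 * ...` by least squares with sum-to-zero contrasts
#' and reports type III F tests for every main effect and interaction, the
#' convention of mixed-model ANOVA software on unbalanced designs. On
#' balanced designs this coincides with the classical two-way
#' decomposition.
#'
#' @param data Data frame in analysis form (one row per animal).
#' @param response Response column name.
#' @param factors Character vector of between-subject factor columns
#'   (default `c("genotype", "drug")`).
#' @return A `stat_results` data frame: `effect`, `statistic` (F), `df1`,
#'   `df2`, `p_raw`, `p_adj` (`NA`; see [fdr_adjust()]), `tails`.
#' @examples
#' d <- expand.grid(genotype = c("WT", "KO"), drug = c("SAL", "Acamp"),
#'                  rep = 1:5)
#' d$value <- rnorm(nrow(d)) + (d$genotype == "KO")
#' factorial_anova(d, "value")
#' @export
factorial_anova <- function(data, response = "value",
                            factors = c("genotype", "drug")) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)), length(factors) >= 1)
  df <- data
  df$.y <- df[[response]]
  if (!is.numeric(df$.y)) stop("response must be numeric")
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2L) {
      stop("factor '", f, "' needs at least 2 levels")
    }
  }
  cells <- table(df[factors])
  if (any(cells == 0L)) stop("empty design cell; factorial ANOVA requires ",
                             "every factor combination observed")
  fml <- stats::as.formula(paste(".y ~", paste(factors, collapse = " * ")))
  ctr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(fml, data = df, contrasts = ctr)
  if (fit$df.residual <= 0) stop("rank-deficient design: no residual df")
  if (stats::sigma(fit) == 0 || !is.finite(stats::sigma(fit)) ||
      stats::sigma(fit) < sqrt(.Machine$double.eps) * max(1, abs(mean(df$.y)))) {
    stop("zero residual variance: F ratios are undefined for a constant ",
         "or exactly-fitted response")
  }
  a3 <- car::Anova(fit, type = 3)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  res <- data.frame(
    effect = rownames(a3)[keep],
    statistic = a3[keep, "F value"],
    df1 = a3[keep, "Df"],
    df2 = a3["Residuals", "Df"],
    p_raw = a3[keep, "Pr(>F)"],
    p_adj = NA_real_,
    tails = "two",
    stringsAsFactors = FALSE
  )
  new_stat_results(res)
}

#' Mixed-factor (repeated measures) ANOVA
#'
#' Between-subject factors crossed with one complete within-subject factor,
#' fitted as a linear mixed model with a random intercept per subject
#' (compound-symmetry covariance) and reported as type III (marginal) F
#' tests -- the style of Proc-Mixed-type software. An AR(1) within-subject
#' covariance is deliberately not modelled; the compound-symmetry
#' approximation is noted in the output attribute `covariance`.
#'
#' Missing within-subject levels are an error (no imputation). If the
#' response shows no within-subject variability at all (identical values
#' across levels for every subject), within-factor F ratios are reported as
#' 0 and between-subject effects are computed from the subject means.
#'
#' @param data Analysis-form data frame, one row per subject x within-level.
#' @param response Response column name.
#' @param between Between-subject factor columns.
#' @param within Within-subject factor column.
#' @param subject Subject identifier column (default `"animal"`).
#' @return A `stat_results` data frame with attribute
#'   `covariance = "compound symmetry"`.
#' @export
mixed_anova <- function(data, response = "value",
                        between = c("genotype", "drug"),
                        within = "within_level", subject = "animal") {
  stopifnot(is.data.frame(data),
            all(c(response, between, within, subject) %in% names(data)))
  df <- data
  df$.y <- df[[response]]
  df$.subj <- factor(df[[subject]])
  df$.w <- factor(df[[within]])
  for (f in between) df[[f]] <- factor(df[[f]])
  # completeness: every subject once per within level
  tab <- table(df$.subj, df$.w)
  if (any(tab != 1L)) {
    stop("incomplete within-subject data: every subject must appear ",
         "exactly once per within level (no imputation)")
  }
  within_var <- stats::ave(df$.y, df$.subj,
                           FUN = function(v) stats::var(v))
  if (all(within_var < .Machine$double.eps)) {
    # degenerate: no within-subject variability anywhere
    sub_means <- stats::aggregate(
      df$.y, by = c(list(df$.subj), lapply(between, function(f) df[[f]])),
      FUN = mean
    )
    names(sub_means) <- c(".subj", between, "value")
    bet <- factorial_anova(sub_means, "value", between)
    wrows <- data.frame(
      effect = c(within, paste(between, within, sep = ":")),
      statistic = 0, df1 = nlevels(df$.w) - 1L, df2 = NA_real_,
      p_raw = 1, p_adj = NA_real_, tails = "two",
      stringsAsFactors = FALSE
    )
    out <- new_stat_results(rbind(as.data.frame(bet), wrows))
    attr(out, "covariance") <- "compound symmetry"
    return(out)
  }
  fml <- stats::as.formula(
    paste(".y ~", paste(c(between, ".w"), collapse = " * "))
  )
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- nlme::lme(fml, random = ~ 1 | .subj, data = df, method = "REML")
  a <- stats::anova(fit, type = "marginal")
  keep <- rownames(a) != "(Intercept)"
  res <- data.frame(
    effect = gsub("\\.w", within, rownames(a)[keep]),
    statistic = a[keep, "F-value"],
    df1 = a[keep, "numDF"],
    df2 = a[keep, "denDF"],
    p_raw = a[keep, "p-value"],
    p_adj = NA_real_,
    tails = "two",
    stringsAsFactors = FALSE
  )
  out <- new_stat_results(res)
  attr(out, "covariance") <- "compound symmetry"
  out
}

#' Exact Wilcoxon rank-sum test by full enumeration
#'
#' Rank-sum test with mid-ranks for ties and an exact null distribution
#' obtained by enumerating, via a counting recursion over the observed
#' mid-ranks, all `choose(n_x + n_y, n_x)` assignments of the pooled
#' observations to the first group. The enumeration conditions on the
#' observed values, so it is valid under arbitrary ties -- the use case
#' being heavily tied ordinal outcomes such as 0-4 seizure scores.
#'
#' The two-sided p-value is the null probability of a rank sum at least as
#' far from its null mean `n_x (n + 1) / 2` as the observed one (the
#' convention of exact rank-sum software). One-sided p-values are the
#' corresponding tail probabilities.
#'
#' Above `cap` total observations the test falls back to a seeded
#' permutation Monte-Carlo approximation, flagged by `exact = FALSE`.
#'
#' @param x,y Numeric samples.
#' @param tails `"two"` (default), `"less"` or `"greater"` (`x` relative to
#'   `y`).
#' @param cap Maximum `n_x + n_y` for exact enumeration (default 20).
#' @param n_mc Number of Monte-Carlo permutations past the cap.
#' @param mc_seed Seed for the Monte-Carlo fallback.
#' @return An object of class `wilcoxon_exact`: `statistic` (S, the
#'   mid-rank sum of `x`), `p.value`, `tails`, `exact`, `n_x`, `n_y`,
#'   `support` (number of enumerated assignments when exact).
#' @examples
#' exact_wilcoxon(c(1, 2), c(3, 4))$p.value        # 2/6
#' exact_wilcoxon(c(1, 2, 3), c(4, 5, 6))$p.value  # 2/20
#' @export
exact_wilcoxon <- function(x, y, tails = c("two", "less", "greater"),
                           cap = 20, n_mc = 20000, mc_seed = 1L) {
  tails <- match.arg(tails)
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  rk <- rank(pooled, ties.method = "average")
  s_obs <- sum(rk[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (n <= cap) {
    # Exact null distribution of the rank sum over all nx-subsets, by a
    # counting recursion: mid-ranks doubled to integers, dist[k, s] =
    # number of k-subsets of the first i ranks with doubled sum s.
    r2 <- as.integer(round(2 * rk))
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
    counts <- matrix(0, nrow = nx + 1L, ncol = smax + 1L)
    counts[1L, 1L] <- 1
    for (r in r2) {
      kmax <- nx
      for (k in kmax:1) {
        nzero <- which(counts[k, ] > 0)
        nzero <- nzero[nzero + r <= smax + 1L]
        if (length(nzero)) {
          counts[k + 1L, nzero + r] <-
            counts[k + 1L, nzero + r] + counts[k, nzero]
        }
      }
    }
    cnt <- counts[nx + 1L, ]
    support_s <- (which(cnt > 0) - 1L) / 2
    w <- cnt[cnt > 0]
    total <- sum(w)
    p <- switch(tails,
      two = sum(w[abs(support_s - mu) >= abs(s_obs - mu) - 1e-9]) / total,
      less = sum(w[support_s <= s_obs + 1e-9]) / total,
      greater = sum(w[support_s >= s_obs - 1e-9]) / total
    )
    res <- list(statistic = s_obs, p.value = p, tails = tails, exact = TRUE,
                n_x = nx, n_y = n - nx, support = total,
                method = "exact enumeration (mid-ranks)")
  } else {
    set.seed(as.integer(mc_seed))
    s_mc <- replicate(n_mc, sum(rk[sample.int(n, nx)]))
    p <- switch(tails,
      two = mean(abs(s_mc - mu) >= abs(s_obs - mu) - 1e-9),
      less = mean(s_mc <= s_obs + 1e-9),
      greater = mean(s_mc >= s_obs - 1e-9)
    )
    res <- list(statistic = s_obs, p.value = p, tails = tails,
                exact = FALSE, n_x = nx, n_y = n - nx, support = n_mc,
                method = "permutation Monte-Carlo (above enumeration cap)")
  }
  structure(res, class = "wilcoxon_exact")
}

#' @export
print.wilcoxon_exact <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank sum, S = %g (n = %d vs %d), %s-tailed p = %.6g [%s]\n",
    x$statistic, x$n_x, x$n_y, x$tails, x$p.value, x$method
  ))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment for a pairwise family
#'
#' Step-up adjusted p-values for one family of pairwise comparisons (one
#' family per dependent measure), with the rejection set at level `q`.
#' Adjusted values are monotone in the raw ordering, never below the raw
#' p-value, and capped at 1.
#'
#' @param p_raw Numeric vector of raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `p_adj` and logical `reject`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))$p_adj  # 0.03 0.03 0.03
#' @export
fdr_adjust <- function(p_raw, q = 0.05) {
  if (!length(p_raw)) return(list(p_adj = numeric(), reject = logical()))
  stopifnot(all(p_raw >= 0 & p_raw <= 1), q > 0, q < 1)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= q)
}

#' FDR-corrected pairwise group comparisons (LS means)
#'
#' Follow-up family for a significant ANOVA: least-squares (model-adjusted)
#' group means are compared pairwise via [emmeans::emmeans()] on the
#' underlying linear model, and the family of raw p-values is corrected
#' with [fdr_adjust()].
#'
#' @param data Analysis-form data frame.
#' @param response Response column.
#' @param group Grouping column defining the compared cells (default
#'   `"group"`).
#' @param q FDR level.
#' @return A `stat_results` data frame, one row per pairwise comparison,
#'   with `p_adj` filled in and attribute `family` naming the response.
#' @export
pairwise_family <- function(data, response = "value", group = "group",
                            q = 0.05) {
  stopifnot(is.data.frame(data), response %in% names(data),
            group %in% names(data))
  df <- data
  df$.y <- df[[response]]
  df$.g <- factor(df[[group]])
  fit <- stats::lm(.y ~ .g, data = df)
  em <- emmeans::emmeans(fit, ".g")
  cmp <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "none"))
  adj <- fdr_adjust(cmp$p.value, q = q)
  res <- data.frame(
    effect = gsub("\\.g", "", cmp$contrast),
    statistic = cmp$t.ratio,
    df1 = 1,
    df2 = cmp$df,
    p_raw = cmp$p.value,
    p_adj = adj$p_adj,
    tails = "two",
    stringsAsFactors = FALSE
  )
  out <- new_stat_results(res)
  attr(out, "family") <- response
  out
}

#' Least-squares group means with standard errors
#'
#' The descriptive statistic reported alongside the ANOVAs: model-adjusted
#' (LS) means and SEMs per group.
#'
#' @inheritParams pairwise_family
#' @return Data frame with `group`, `lsmean`, `sem`.
#' @export
ls_means <- function(data, response = "value", group = "group") {
  df <- data
  df$.y <- df[[response]]
  df$.g <- factor(df[[group]])
  em <- as.data.frame(emmeans::emmeans(stats::lm(.y ~ .g, data = df), ".g"))
  data.frame(group = as.character(em$.g), lsmean = em$emmean, sem = em$SE,
             stringsAsFactors = FALSE)
}

#' One-tailed preplanned contrast
#'
#' A directional a-priori pairwise comparison: the two-tailed p-value of
#' the pooled-variance two-sample t test is halved when the observed
#' difference lies in the predicted direction, and reported as
#' `1 - p_two/2` otherwise (so a zero observed difference gives 0.5). The
#' direction must be stated explicitly; the function refuses to run
#' one-tailed without it. Include the result in its FDR family alongside
#' the other comparisons of the same measure.
#'
#' @param x,y Numeric samples for the two compared groups.
#' @param direction `"greater"` or `"less"`: the predicted sign of
#'   `mean(x) - mean(y)`, fixed in advance.
#' @return A `stat_results` row (statistic = t, `tails = "one"`).
#' @examples
#' preplanned_contrast(rnorm(8, 1), rnorm(8), direction = "greater")
#' @export
preplanned_contrast <- function(x, y, direction = NULL) {
  if (is.null(direction) || !direction %in% c("greater", "less")) {
    stop("a one-tailed preplanned contrast requires direction 'greater' ",
         "or 'less' stated in advance")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  p_two <- tt$p.value
  diff <- mean(x) - mean(y)
  matches <- (direction == "greater" && diff > 0) ||
             (direction == "less" && diff < 0)
  p_one <- if (diff == 0) 0.5 else if (matches) p_two / 2 else 1 - p_two / 2
  new_stat_results(data.frame(
    effect = paste0("preplanned(", direction, ")"),
    statistic = unname(tt$statistic),
    df1 = 1, df2 = unname(tt$parameter),
    p_raw = p_one, p_adj = NA_real_, tails = "one",
    stringsAsFactors = FALSE
  ))
}

#' Control-group pooling rule (saline vs calcium-vehicle)
#'
#' For each measure, compares the two control arms (default SAL vs CaCl2)
#' with a genotype x drug factorial ANOVA restricted to control animals.
#' If neither the drug main effect nor the genotype:drug interaction is
#' significant at `alpha`, both arms are relabelled as a single
#' `"Controls"` level for that measure; otherwise pooling is withheld for
#' that measure. Every decision is logged.
#'
#' @param cohort Long-format cohort table.
#' @param measures Measures to examine (default: all in the table).
#' @param control_drugs The two control drug labels.
#' @param alpha Significance level for the pooling decision (default 0.05).
#' @param pooled_label Label replacing the control drug levels when pooled.
#' @return List with `cohort` (relabelled copy) and `log`, a data frame
#'   (`measure`, `p_drug`, `p_interaction`, `pooled`, `note`).
#' @export
pool_controls <- function(cohort, measures = unique(cohort$measure),
                          control_drugs = c("SAL", "CaCl2"), alpha = 0.05,
                          pooled_label = "Controls") {
  stopifnot(is.data.frame(cohort),
            all(c("measure", "drug", "genotype", "value") %in% names(cohort)),
            length(control_drugs) == 2L)
  log <- data.frame(measure = character(), p_drug = numeric(),
                    p_interaction = numeric(), pooled = logical(),
                    note = character(), stringsAsFactors = FALSE)
  out <- cohort
  for (m in measures) {
    sub <- cohort[cohort$measure == m & cohort$drug %in% control_drugs, ,
                  drop = FALSE]
    have <- intersect(control_drugs, unique(sub$drug))
    if (length(have) < 2L) {
      warning("measure '", m, "': control group(s) ",
              paste(setdiff(control_drugs, have), collapse = ", "),
              " absent; pooling skipped")
      log <- rbind(log, data.frame(
        measure = m, p_drug = NA_real_, p_interaction = NA_real_,
        pooled = FALSE, note = "control arm missing",
        stringsAsFactors = FALSE))
      next
    }
    an <- factorial_anova(sub, "value", c("genotype", "drug"))
    p_drug <- an$p_raw[an$effect == "drug"]
    p_int <- an$p_raw[an$effect == "genotype:drug"]
    pooled <- p_drug >= alpha && p_int >= alpha
    if (pooled) {
      sel <- out$measure == m & out$drug %in% control_drugs
      out$drug[sel] <- pooled_label
      if ("group" %in% names(out)) {
        out$group[sel] <- paste(out$genotype[sel], pooled_label, sep = ":")
      }
    }
    log <- rbind(log, data.frame(
      measure = m, p_drug = p_drug, p_interaction = p_int, pooled = pooled,
      note = if (pooled) "controls combined" else
        "difference between control arms; pooling withheld",
      stringsAsFactors = FALSE))
  }
  list(cohort = out, log = log)
}
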