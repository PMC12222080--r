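#' Welch's unequal-variance t-test with Cohen's d
#'
#' Two-sided Welch test (Satterthwaite degrees of freedom) plus the
#' pooled-SD standardized mean difference `d = (mean(a) - mean(b)) / s_p`.
#' By convention the first sample is the experienced group, so higher
#' novice values give negative `t` and `d`.
#'
#' @param a,b Numeric samples, each with at least 2 values and nonzero
#'   variance.
#' @param label Optional cell label used in error messages.
#' @return One-row `data.frame`: `statistic`, `df`, `p`, `d`.
#' @export
welch_t <- function(a, b, label = NULL) {
  tag <- if (is.null(label)) "" else paste0(" [", label, "]")
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", tag)
  }
  if (identical(stats::var(a), 0) && identical(stats::var(b), 0) &&
      mean(a) == mean(b)) {
    # identical constant samples: define t = d = 0, p = 1
    return(data.frame(statistic = 0, df = length(a) + length(b) - 2,
                      p = 1, d = 0))
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both samples are degenerate (zero variance)", tag)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = cohens_d(a, b))
}

#' Cohen's d with pooled standard deviation
#'
#' @param a,b Numeric samples.
#' @return `(mean(a) - mean(b)) / s_pooled`.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Mixed-design ANOVA: between-subjects group, within-subjects region
#'
#' Classical repeated-measures sums-of-squares decomposition
#' `Y_ijk = mu + alpha_i + beta_j + (alpha beta)_ij + e_ijk` for one value
#' per subject and region, with group (driving experience) as the
#' between-subjects factor and brain region as the within-subjects
#' factor. The group main effect is tested against the between-subject
#' stratum, region and the interaction against the subject-by-region
#' stratum. Requires complete data: every subject must have a value for
#' every region.
#'
#' @param data `data.frame` with columns `subject`, `group`, `region`,
#'   `value`.
#' @return `data.frame` with one row per effect (`group`, `region`,
#'   `group:region`): `effect`, `df1`, `df2`, `statistic` (F), `p`,
#'   `effect_size` (partial eta squared).
#' @export
mixed_anova <- function(data) {
  stopifnot(all(c("subject", "group", "region", "value") %in% names(data)))
  d <- data.frame(subject = factor(data$subject), group = factor(data$group),
                  region = factor(data$region), value = data$value)
  tab <- table(d$subject, d$region)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    miss <- paste(rownames(tab)[bad[, 1]], colnames(tab)[bad[, 2]],
                  sep = ":", collapse = ", ")
    stop("incomplete repeated measures; offending subject:region cells: ", miss)
  }
  if (min(table(unique(d[c("subject", "group")])$group)) < 2) {
    stop("need at least 2 subjects per group")
  }
  m <- stats::aov(value ~ group * region + Error(subject / region), data = d)
  s <- summary(m)
  pull <- function(stratum, effects) {
    tb <- as.data.frame(s[[stratum]][[1]])
    tb$effect <- trimws(rownames(tb))
    err <- tb[tb$effect == "Residuals", ]
    do.call(rbind, lapply(effects, function(e) {
      r <- tb[tb$effect == e, ]
      data.frame(effect = e, df1 = r$Df, df2 = err$Df,
                 statistic = r$`F value`, p = r$`Pr(>F)`,
                 effect_size = r$`Sum Sq` / (r$`Sum Sq` + err$`Sum Sq`))
    }))
  }
  rbind(pull("Error: subject", "group"),
        pull("Error: subject:region", c("region", "group:region")))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure: p-values are ranked ascending, adjusted as
#' `min_{k >= rank} (m * p_(k) / k)` capped at 1, and rejected when the
#' adjusted value is at most `alpha`.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return List with `adjusted` (BH-adjusted p-values, same order as the
#'   input) and `reject` (logical mask).
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Significance stars from FDR-adjusted p-values
#'
#' `*`, `**`, `***` for adjusted p below 0.05, 0.01 and 0.001.
#'
#' @param p_fdr Numeric adjusted p-values.
#' @return Character vector of star annotations (empty when not
#'   significant).
#' @export
p_stars <- function(p_fdr) {
  ifelse(p_fdr < 0.001, "***",
         ifelse(p_fdr < 0.01, "**",
                ifelse(p_fdr < 0.05, "*", "")))
}

#' Three-tier group comparison of connectivity metrics
#'
#' Runs the full statistical battery on a long metric table from
#' [metrics_table()]:
#' \describe{
#'   \item{Tier 1}{Welch t-tests comparing the groups on whole-graph
#'     metrics (global efficiency, characteristic path length), per band,
#'     condition and sliding window.}
#'   \item{Tier 2}{Mixed-design ANOVA on node-level metrics (in-strength,
#'     out-strength, total strength, clustering) averaged within the
#'     seven intrinsic networks per subject, with group as the
#'     between-subjects factor and network as the within-subjects
#'     "region" factor; the experience main effect is the primary test.}
#'   \item{Tier 3}{Node-level Welch follow-up tests, run only in cells
#'     whose tier-2 experience effect survives FDR, reported with their
#'     network affiliation.}
#' }
#' Within each tier, p-values are pooled into one BH-FDR family per
#' (metric, band, condition) across windows (and nodes, for tier 3); the
#' family definitions actually used are returned alongside the tests.
#'
#' @param table Long metric table from [metrics_table()].
#' @param alpha FDR level (default 0.05).
#' @param groups Character vector of the two group labels, first =
#'   experienced (reference for the sign of t and d).
#' @return List with `tests` (`data.frame`: tier, metric, band,
#'   condition, window, unit, unit_id, network, effect, statistic, df,
#'   df2, p, p_fdr, d, stars) and `families` (FDR family definition per
#'   tier).
#' @export
group_statistics <- function(table, alpha = 0.05,
                             groups = c("experienced", "novice")) {
  stopifnot(all(groups %in% table$group))
  res <- list()

  # ---- tier 1: Welch tests on whole-graph metrics -------------------
  gl <- table[table$unit == "graph", ]
  for (met in unique(gl$metric)) {
    for (bnd in unique(gl$band)) {
      for (cnd in unique(gl$condition)) {
        fam <- list()
        for (w in sort(unique(gl$window))) {
          cell <- gl[gl$metric == met & gl$band == bnd &
                       gl$condition == cnd & gl$window == w, ]
          a <- cell$value[cell$group == groups[1]]
          b <- cell$value[cell$group == groups[2]]
          wt <- welch_t(a, b, label = paste(met, bnd, cnd, w))
          fam[[w]] <- data.frame(
            tier = 1L, metric = met, band = bnd, condition = cnd,
            window = w, unit = "graph", unit_id = "graph",
            network = NA_character_, effect = "group",
            statistic = wt$statistic, df = wt$df, df2 = NA_real_,
            p = wt$p, d = wt$d, stringsAsFactors = FALSE)
        }
        fam <- do.call(rbind, fam)
        fam$p_fdr <- fdr_bh(fam$p, alpha)$adjusted
        res[[length(res) + 1]] <- fam
      }
    }
  }

  # ---- tier 2: mixed ANOVA on node metrics at network granularity ---
  nd <- table[table$unit == "node", ]
  anova_sig <- list()  # gate for tier 3
  for (met in unique(nd$metric)) {
    for (bnd in unique(nd$band)) {
      for (cnd in unique(nd$condition)) {
        fam <- list()
        for (w in sort(unique(nd$window))) {
          cell <- nd[nd$metric == met & nd$band == bnd &
                       nd$condition == cnd & nd$window == w, ]
          agg <- stats::aggregate(value ~ subject + group + network,
                                  data = cell, FUN = mean)
          names(agg)[names(agg) == "network"] <- "region"
          an <- mixed_anova(agg)
          grp <- an[an$effect == "group", ]
          fam[[w]] <- data.frame(
            tier = 2L, metric = met, band = bnd, condition = cnd,
            window = w, unit = "network", unit_id = "all",
            network = NA_character_, effect = "group",
            statistic = grp$statistic, df = grp$df1, df2 = grp$df2,
            p = grp$p, d = NA_real_, stringsAsFactors = FALSE)
        }
        fam <- do.call(rbind, fam)
        fam$p_fdr <- fdr_bh(fam$p, alpha)$adjusted
        res[[length(res) + 1]] <- fam
        for (i in seq_len(nrow(fam))) {
          anova_sig[[paste(met, bnd, cnd, fam$window[i])]] <-
            fam$p_fdr[i] <= alpha
        }
      }
    }
  }

  # ---- tier 3: node-level follow-ups in FDR-significant cells -------
  for (met in unique(nd$metric)) {
    for (bnd in unique(nd$band)) {
      for (cnd in unique(nd$condition)) {
        fam <- list()
        for (w in sort(unique(nd$window))) {
          if (!isTRUE(anova_sig[[paste(met, bnd, cnd, w)]])) next
          cell <- nd[nd$metric == met & nd$band == bnd &
                       nd$condition == cnd & nd$window == w, ]
          for (node in unique(cell$unit_id)) {
            nc <- cell[cell$unit_id == node, ]
            wt <- welch_t(nc$value[nc$group == groups[1]],
                          nc$value[nc$group == groups[2]],
                          label = paste(met, bnd, cnd, w, node))
            fam[[paste(w, node)]] <- data.frame(
              tier = 3L, metric = met, band = bnd, condition = cnd,
              window = w, unit = "node", unit_id = node,
              network = nc$network[1], effect = "group",
              statistic = wt$statistic, df = wt$df, df2 = NA_real_,
              p = wt$p, d = wt$d, stringsAsFactors = FALSE)
          }
        }
        if (length(fam)) {
          fam <- do.call(rbind, fam)
          fam$p_fdr <- fdr_bh(fam$p, alpha)$adjusted
          res[[length(res) + 1]] <- fam
        }
      }
    }
  }

  tests <- do.call(rbind, c(res, make.row.names = FALSE))
  tests$stars <- p_stars(tests$p_fdr)
  list(tests = tests,
       families = data.frame(
         tier = 1:3,
         family = c(
           "tier 1: one BH family per (metric, band, condition) across windows",
           "tier 2: one BH family per (metric, band, condition) across windows",
           "tier 3: one BH family per (metric, band, condition) across windows x nodes, gated on tier-2 FDR significance"),
         stringsAsFactors = FALSE))
}

#' Aggregate significant node-level follow-ups by intrinsic network
#'
#' Summarizes tier-3 results: how many member nodes of each network reach
#' FDR significance in each window, with the mean effect size.
#'
#' @param stats_result Output of [group_statistics()].
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return `data.frame` with metric, band, condition, window, network,
#'   `n_significant`, `n_nodes`, `mean_d`.
#' @export
followup_by_network <- function(stats_result, alpha = 0.05) {
  t3 <- stats_result$tests[stats_result$tests$tier == 3L, ]
  if (nrow(t3) == 0) {
    return(data.frame(metric = character(), band = character(),
                      condition = character(), window = character(),
                      network = character(), n_significant = integer(),
                      n_nodes = integer(), mean_d = numeric()))
  }
  key <- interaction(t3$metric, t3$band, t3$condition, t3$window, t3$network,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(t3, key), function(g) {
    data.frame(metric = g$metric[1], band = g$band[1],
               condition = g$condition[1], window = g$window[1],
               network = g$network[1],
               n_significant = sum(g$p_fdr <= alpha),
               n_nodes = nrow(g), mean_d = mean(g$d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
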