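test_that("welch test matches the closed-form computation", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  r <- welch_t(a, b)
  va <- var(a) / 4; vb <- var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 3 + vb^2 / 3)
  expect_equal(r$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r$df, df_hand, tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  expect_equal(r$d, (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2),
               tolerance = 1e-10)
})

test_that("welch equals the pooled t when variances and sizes match", {
  set.seed(1)
  a <- rnorm(10); b <- rnorm(10)
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b)  # force equal variance
  r <- welch_t(a, b)
  pooled <- t.test(a, b, var.equal = TRUE)
  expect_equal(r$statistic, unname(pooled$statistic), tolerance = 1e-10)
  expect_equal(r$df, unname(pooled$parameter), tolerance = 1e-10)
})

test_that("welch is antisymmetric and handles degenerate input", {
  set.seed(2)
  a <- rnorm(8); b <- rnorm(8, 1)
  r1 <- welch_t(a, b); r2 <- welch_t(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$d, -r2$d)
  expect_equal(r1$p, r2$p)

  same <- c(2, 2, 2)
  expect_equal(welch_t(same, same)$statistic, 0)
  expect_equal(welch_t(same, same)$d, 0)
  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "degenerate")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

# manual classical sums-of-squares decomposition for a balanced
# two-group / r-region repeated-measures design
manual_mixed_anova <- function(d) {
  grand <- mean(d$value)
  r <- length(unique(d$region))
  gsize <- table(unique(d[c("subject", "group")])$group)
  subj_means <- tapply(d$value, d$subject, mean)
  grp_of <- tapply(as.character(d$group), d$subject, function(x) x[1])
  grp_means <- tapply(d$value, d$group, mean)
  reg_means <- tapply(d$value, d$region, mean)
  cell_means <- tapply(d$value, list(d$group, d$region), mean)
  n_subj <- length(subj_means)
  ss_between_subj <- r * sum((subj_means - grand)^2)
  ss_group <- r * sum(gsize * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_region <- n_subj * sum((reg_means - grand)^2)
  ss_cells <- sum(rep(gsize, r) * (cell_means - grand)^2)
  ss_inter <- ss_cells - ss_group - ss_region
  ss_total <- sum((d$value - grand)^2)
  ss_err <- ss_total - ss_between_subj - ss_region - ss_inter
  df_g <- length(gsize) - 1; df_sw <- n_subj - length(gsize)
  df_r <- r - 1; df_err <- df_sw * df_r
  list(
    F_group = (ss_group / df_g) / (ss_subj_within / df_sw),
    F_region = (ss_region / df_r) / (ss_err / df_err),
    F_inter = (ss_inter / (df_g * df_r)) / (ss_err / df_err))
}

test_that("mixed ANOVA matches a hand-worked decomposition", {
  d <- data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("experienced", "experienced", "novice", "novice"), each = 2),
    region = rep(c("Visual", "DMN"), 4),
    value = c(3.1, 2.0, 2.8, 2.4, 4.6, 3.1, 4.1, 3.9))
  got <- mixed_anova(d)
  man <- manual_mixed_anova(d)
  expect_equal(got$statistic[got$effect == "group"], man$F_group,
               tolerance = 1e-10)
  expect_equal(got$statistic[got$effect == "region"], man$F_region,
               tolerance = 1e-10)
  expect_equal(got$statistic[got$effect == "group:region"], man$F_inter,
               tolerance = 1e-10)
  expect_equal(got$df1, c(1, 1, 1))
  expect_equal(got$df2, c(2, 2, 2))
})

test_that("mixed ANOVA group p-values are uniform under a permuted null", {
  set.seed(3)
  pvals <- replicate(400, {
    d <- expand.grid(subject = paste0("s", 1:8),
                     region = c("A", "B", "C", "D"))
    grp <- sample(rep(c("experienced", "novice"), each = 4))
    d$group <- grp[as.integer(factor(d$subject))]
    d$value <- rnorm(nrow(d))
    mixed_anova(d)$p[1]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("group F grows monotonically with an injected offset", {
  set.seed(4)
  base <- expand.grid(subject = paste0("s", 1:10),
                      region = c("A", "B", "C"))
  base$group <- rep(c("experienced", "novice"),
                    each = 5)[as.integer(factor(base$subject))]
  noise <- rnorm(nrow(base))
  f_at <- vapply(c(0, 0.5, 1, 2), function(delta) {
    d <- base
    d$value <- noise + delta * (d$group == "novice")
    mixed_anova(d)$statistic[1]
  }, numeric(1))
  expect_true(all(diff(f_at) > 0))
})

test_that("mixed ANOVA validates completeness and group sizes", {
  d <- data.frame(subject = c("s1", "s1", "s2"), group = "experienced",
                  region = c("A", "B", "A"), value = 1:3)
  expect_error(mixed_anova(d), "incomplete.*s2:B")
})

test_that("BH step-up matches the hand-applied rule", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$reject))  # thresholds 0.0125, 0.025, 0.0375, 0.05
  expect_equal(r$adjusted, c(0.04, 0.04, 0.04, 0.04))

  single <- fdr_bh(0.04)
  expect_equal(single$adjusted, 0.04)
  expect_true(single$reject)

  all_one <- fdr_bh(rep(1, 6))
  expect_false(any(all_one$reject))
  expect_equal(all_one$adjusted, rep(1, 6))

  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")
})

test_that("BH rejections nest between Bonferroni and uncorrected", {
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(15)^2
    bh <- fdr_bh(p, 0.05)$reject
    bonf <- p <= 0.05 / length(p)
    raw <- p <= 0.05
    expect_true(all(bh[bonf]))   # Bonferroni subset of BH
    expect_true(all(raw[bh]))    # BH subset of uncorrected
  }
})

test_that("stars follow the FDR-adjusted thresholds", {
  expect_equal(p_stars(c(0.2, 0.049, 0.009, 0.0009)),
               c("", "*", "**", "***"))
})

# build a small node-level metric table for tier-2/3 behaviour tests
toy_table <- function(delta_visual = 0, n_per_group = 8, seed = 1) {
  set.seed(seed)
  networks <- c("Visual", "DMN", "VAN", "FCN")
  nodes <- paste0(rep(networks, each = 2), "_", 1:2)
  subj <- paste0("s", 1:(2 * n_per_group))
  grp <- rep(c("experienced", "novice"), each = n_per_group)
  rows <- expand.grid(subject = subj, unit_id = nodes,
                      stringsAsFactors = FALSE)
  rows$group <- grp[match(rows$subject, subj)]
  rows$network <- sub("_.*", "", rows$unit_id)
  rows$band <- "beta"; rows$condition <- "collision"; rows$window <- "SW1"
  rows$unit <- "node"; rows$metric <- "s_in"
  rows$value <- rnorm(nrow(rows)) +
    delta_visual * (rows$network == "Visual") * (rows$group == "novice")
  rows
}

test_that("follow-up tests are gated on the ANOVA and localize a planted effect", {
  null_tab <- toy_table(0, seed = 6)
  st0 <- group_statistics(null_tab)
  expect_equal(sum(st0$tests$tier == 3), 0)  # nothing significant, no follow-ups

  eff_tab <- toy_table(3, seed = 7)
  st1 <- group_statistics(eff_tab)
  t2 <- st1$tests[st1$tests$tier == 2, ]
  expect_true(any(t2$p_fdr < 0.05))
  t3 <- st1$tests[st1$tests$tier == 3, ]
  expect_gt(nrow(t3), 0)
  sig <- t3[t3$p_fdr < 0.05, ]
  expect_true(all(sig$network == "Visual"))
  expect_true(all(sig$d < 0))  # experienced minus novice is negative
  byn <- followup_by_network(st1)
  expect_equal(byn$n_significant[byn$network == "Visual"], 2)
})

test_that("the gated pipeline controls false positives on exchangeable nulls", {
  set.seed(8)
  n_sim <- 150
  any_fp <- logical(n_sim)
  for (s in 1:n_sim) {
    st <- group_statistics(toy_table(0, n_per_group = 6, seed = 1000 + s))
    t3 <- st$tests[st$tests$tier == 3, ]
    any_fp[s] <- nrow(t3) > 0 && any(t3$p_fdr <= 0.05)
  }
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(mean(any_fp), 0.05 + 3 * se)
})
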