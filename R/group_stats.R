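#' @include AllClasses.R
NULL

#' Unpaired two-sample t-test
#'
#' Classical two-sided unpaired t-test on normalized spike rates (or any two
#' samples), with the Welch (default) or pooled-variance statistic and a
#' confidence interval for the mean difference. When both groups have zero
#' variance and equal means the test is degenerate and returns `t = 0`,
#' `p = 1`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param varEqual use the pooled-variance statistic instead of Welch.
#' @param conf confidence level for the CI (default 0.95).
#' @return list with `t`, `df`, `p`, `mean_diff` (`mean(a) - mean(b)`), `ci`,
#'   `method`.
#' @export
unpairedT <- function(a, b, varEqual = FALSE, conf = 0.95) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2")
  md <- mean(a) - mean(b)
  va <- var(a); vb <- var(b)
  if (varEqual) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    method <- "pooled"
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- if (se > 0)
      (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    else na + nb - 2
    method <- "welch"
  }
  if (se == 0) {
    if (md == 0)
      return(list(t = 0, df = df, p = 1, mean_diff = 0, ci = c(0, 0),
                  method = method))
    return(list(t = sign(md) * Inf, df = df, p = 0, mean_diff = md,
                ci = c(md, md), method = method))
  }
  t <- md / se
  p <- 2 * pt(-abs(t), df)
  q <- qt(1 - (1 - conf) / 2, df)
  list(t = t, df = df, p = p, mean_diff = md, ci = c(md - q * se, md + q * se),
       method = method)
}

.rateTableCheck <- function(samples) {
  need <- c("value", "neuron", "culture", "condition")
  if (!all(need %in% names(samples)))
    stop("need columns ", paste(need, collapse = ", "))
  if (anyNA(samples$culture)) stop("every neuron needs a culture id")
  conds <- unique(samples$condition)
  if (length(conds) != 2L) stop("need exactly two conditions, got ",
                                length(conds))
  conds
}

#' Cluster bootstrap for a between-condition rate difference
#'
#' Neurons from one culture are not independent; the grouping-aware check
#' resamples cultures (the clustering unit) with replacement within each
#' condition and recomputes the neuron-weighted mean difference
#' `mean(treatment) - mean(baseline)`. Reported are the observed difference,
#' the percentile bootstrap CI and a sign-flip bootstrap p-value. The result
#' is deterministic under `seed`.
#'
#' @param samples data.frame with columns `value`, `neuron`, `culture`,
#'   `condition` (two levels; `conditions[1]` is the baseline).
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @param conditions optional length-2 character giving (baseline, treatment)
#'   order; defaults to sorted unique conditions.
#' @return list with `mean_diff`, `ci`, `p_boot`, `n_cultures`, `nBoot`.
#' @export
clusterBootstrapDiff <- function(samples, nBoot = 2000, seed = 1, conf = 0.95,
                                 conditions = NULL) {
  .rateTableCheck(samples)
  if (is.null(conditions)) conditions <- sort(unique(samples$condition))
  stopifnot(length(conditions) == 2L)
  byCond <- lapply(conditions, function(cc) {
    sub <- samples[samples$condition == cc, , drop = FALSE]
    split(sub$value, sub$culture)
  })
  nCult <- vapply(byCond, length, integer(1))
  if (any(nCult < 2L))
    stop("cluster bootstrap needs >= 2 cultures per condition")
  obs <- mean(unlist(byCond[[2]])) - mean(unlist(byCond[[1]]))

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  boot <- vapply(seq_len(nBoot), function(r) {
    ms <- vapply(byCond, function(cultures) {
      pick <- sample.int(length(cultures), replace = TRUE)
      mean(unlist(cultures[pick], use.names = FALSE))
    }, numeric(1))
    ms[2] - ms[1]
  }, numeric(1))
  alpha <- 1 - conf
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 7))
  pb <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  list(mean_diff = obs, ci = ci, p_boot = min(1, pb),
       n_cultures = setNames(nCult, conditions), nBoot = nBoot)
}

#' Mixed-model check of a condition effect (optional lme4 adapter)
#'
#' Fits `value ~ condition + (1 | culture)` and reports the condition fixed
#' effect with a Wald CI, as an independent grouping-aware confirmation of
#' [clusterBootstrapDiff()]. Requires the suggested package lme4.
#'
#' @param samples as in [clusterBootstrapDiff()].
#' @param conf confidence level.
#' @return list with `estimate`, `ci`, or an error if lme4 is unavailable.
#' @export
mixedModelCheck <- function(samples, conf = 0.95) {
  .rateTableCheck(samples)
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("mixedModelCheck needs the suggested package 'lme4'")
  samples$condition <- factor(samples$condition)
  fit <- lme4::lmer(value ~ condition + (1 | culture), data = samples,
                    REML = TRUE)
  est <- lme4::fixef(fit)[[2]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
  z <- qnorm(1 - (1 - conf) / 2)
  list(estimate = est, ci = c(est - z * se, est + z * se))
}

#' Compare normalized rates between two conditions
#'
#' Runs the neuron-level unpaired t-test and the culture-level cluster
#' bootstrap on a long-format rate table.
#'
#' @param samples data.frame with `value`, `neuron`, `culture`, `condition`.
#' @param conditions length-2 (baseline, treatment) ordering.
#' @param nBoot,seed,conf passed to [clusterBootstrapDiff()].
#' @return list with `ttest` and `bootstrap` components.
#' @export
compareConditions <- function(samples, conditions = NULL, nBoot = 2000,
                              seed = 1, conf = 0.95) {
  cc <- .rateTableCheck(samples)
  if (is.null(conditions)) conditions <- sort(cc)
  a <- samples$value[samples$condition == conditions[2]]
  b <- samples$value[samples$condition == conditions[1]]
  list(ttest = unpairedT(a, b, conf = conf),
       bootstrap = clusterBootstrapDiff(samples, nBoot = nBoot, seed = seed,
                                        conf = conf, conditions = conditions))
}
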