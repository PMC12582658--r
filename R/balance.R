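#' Standardized mean difference for a binary covariate
#'
#' Pooled-variance definition from group counts:
#' `|p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)` with
#' `p = positives / n`. When both group variances are zero the SMD is 0 if
#' the proportions agree and infinite (with a warning) otherwise.
#'
#' @param x1,x2 Length-2 vectors `c(positives, n)` for each group.
#' @return Absolute standardized mean difference.
#' @export
smd_binary <- function(x1, x2) {
  stopifnot(length(x1) == 2, length(x2) == 2, x1[2] >= 1, x2[2] >= 1,
            x1[1] >= 0, x1[1] <= x1[2], x2[1] >= 0, x2[1] <= x2[2])
  p1 <- x1[1] / x1[2]
  p2 <- x2[1] / x2[2]
  smd_from_moments(p1, sqrt(p1 * (1 - p1)), p2, sqrt(p2 * (1 - p2)))
}

#' Standardized mean difference for a continuous covariate
#'
#' `|mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)`; the weighted variant is
#' obtained by supplying weighted moments.
#'
#' @param mean1,sd1,mean2,sd2 Group means and standard deviations
#'   (`sd >= 0`).
#' @return Absolute standardized mean difference.
#' @export
smd_continuous <- function(mean1, sd1, mean2, sd2) {
  stopifnot(sd1 >= 0, sd2 >= 0)
  smd_from_moments(mean1, sd1, mean2, sd2)
}

smd_from_moments <- function(m1, s1, m2, s2) {
  pooled <- sqrt((s1^2 + s2^2) / 2)
  if (pooled == 0) {
    if (isTRUE(all.equal(m1, m2))) return(0)
    warning("zero pooled variance with unequal means: infinite SMD ",
            "(degenerate covariate, positivity-style problem)")
    return(Inf)
  }
  abs(m1 - m2) / pooled
}

weighted_mean_sd <- function(x, w) {
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w)
  c(mean = m, sd = sqrt(v))
}

#' Covariate balance table with SMDs before and after weighting
#'
#' One row per covariate, with the standardized mean difference between
#' arms computed unweighted and with the supplied inverse probability
#' weights (same formulas on weighted means/proportions). Multi-level
#' categorical covariates are summarized by the maximum over level-wise
#' binary SMDs (a declared convention). Missing values are dropped
#' covariate-wise; factor levels named `"missing"` participate as ordinary
#' levels.
#'
#' @param cohort Cohort data frame with `arm`.
#' @param weights Per-person weights (default 1: the weighted column then
#'   equals the unweighted one).
#' @param covariates Covariate column names.
#' @return Data frame `covariate`, `type`, `smd_unweighted`,
#'   `smd_weighted`.
#' @export
balance_table <- function(cohort, weights = NULL, covariates) {
  absent <- setdiff(covariates, names(cohort))
  if (length(absent)) {
    stop("covariate(s) not in cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(cohort))
  g1 <- cohort$arm == "acei_arb"
  out <- lapply(covariates, function(nm) {
    x <- cohort[[nm]]
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2) {
      type <- "continuous"
      smd_u <- {
        a <- weighted_mean_sd(x[g1], rep(1, sum(g1)))
        b <- weighted_mean_sd(x[!g1], rep(1, sum(!g1)))
        smd_continuous(a["mean"], a["sd"], b["mean"], b["sd"])
      }
      smd_w <- {
        a <- weighted_mean_sd(x[g1], weights[g1])
        b <- weighted_mean_sd(x[!g1], weights[!g1])
        smd_continuous(a["mean"], a["sd"], b["mean"], b["sd"])
      }
    } else {
      type <- if (is.numeric(x)) "binary" else "categorical"
      f <- factor(x)
      lv <- levels(f)
      level_smd <- function(w) {
        vapply(lv, function(l) {
          z <- as.numeric(f == l)
          a <- weighted_mean_sd(z[g1], w[g1])
          b <- weighted_mean_sd(z[!g1], w[!g1])
          smd_from_moments(a["mean"], a["sd"], b["mean"], b["sd"])
        }, numeric(1))
      }
      u <- level_smd(rep(1, nrow(cohort)))
      wv <- level_smd(weights)
      if (length(lv) <= 2) {
        smd_u <- u[length(u)]; smd_w <- wv[length(wv)]
      } else {
        smd_u <- max(u); smd_w <- max(wv)
      }
    }
    data.frame(covariate = nm, type = type,
               smd_unweighted = unname(smd_u), smd_weighted = unname(smd_w))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
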