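#' Nonparametric bootstrap confidence intervals for effect estimates
#'
#' Resamples individuals with replacement, re-runs the full estimation
#' pipeline (including re-estimation of any weights) in each replicate, and
#' forms percentile confidence intervals from the replicate distribution.
#' Replicates that fail (for example a non-converged fit) are excluded and
#' counted; more than `max_failure_rate` failures aborts, since the
#' estimate would be unstable.
#'
#' @param pipeline_fn Function taking a data object and returning a named
#'   numeric vector of estimates (e.g. `c(R1 = , R0 = , RD = , RR = )`).
#' @param data A list of data frames that each carry `person_id` (for
#'   example `list(cohort = , dispensations = , ...)`); the individual is
#'   the resampling unit and duplicated individuals receive fresh ids so
#'   downstream grouping treats them as distinct.
#' @param n_reps Number of bootstrap replicates (the protocol default is
#'   500).
#' @param seed Integer seed; fixed seeds give identical intervals.
#' @param conf Confidence level (default 0.95).
#' @param max_failure_rate Abort above this replicate failure share.
#' @return A list of class `effect_estimate`: `point`, `lower`, `upper`
#'   (named vectors), `n_reps`, `n_failed`, `seed`, `replicates` (matrix).
#' @export
bootstrap_effects <- function(pipeline_fn, data, n_reps = 500L, seed = 1L,
                              conf = 0.95, max_failure_rate = 0.10) {
  point <- pipeline_fn(data)
  ids <- data[[1]]$person_id
  n <- length(ids)
  set.seed(seed)
  reps <- matrix(NA_real_, n_reps, length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    take <- sample.int(n, n, replace = TRUE)
    boot_data <- resample_individuals(data, ids[take])
    est <- tryCatch(pipeline_fn(boot_data), error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L else reps[r, ] <- est
  }
  if (n_failed > max_failure_rate * n_reps) {
    stop("bootstrap unstable: ", n_failed, "/", n_reps,
         " replicates failed", call. = FALSE)
  }
  alpha <- (1 - conf) / 2
  lower <- apply(reps, 2, stats::quantile, probs = alpha, na.rm = TRUE,
                 type = 7)
  upper <- apply(reps, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE,
                 type = 7)
  structure(list(point = point, lower = lower, upper = upper,
                 n_reps = n_reps, n_failed = n_failed, seed = seed,
                 conf = conf, replicates = reps),
            class = "effect_estimate")
}

# Rebuild a data object for a resampled id multiset: each drawn copy gets a
# unique suffixed id, and child-table rows are duplicated to follow it.
resample_individuals <- function(data, drawn_ids) {
  new_ids <- make.unique(drawn_ids, sep = "#")
  out <- lapply(data, function(tab) {
    by_person <- split(seq_len(nrow(tab)), tab$person_id)
    idx_list <- by_person[drawn_ids]
    lens <- lengths(idx_list)
    lens[is.na(names(idx_list))] <- 0L
    idx <- unlist(idx_list, use.names = FALSE)
    res <- tab[idx, , drop = FALSE]
    res$person_id <- rep(new_ids, lens)
    rownames(res) <- NULL
    res
  })
  out
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("<effect_estimate>  ", x$n_reps, "bootstrap replicates (",
      x$n_failed, "failed ), seed", x$seed, "\n")
  tab <- data.frame(point = x$point, lower = x$lower, upper = x$upper)
  print(round(tab, 4))
  invisible(x)
}
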