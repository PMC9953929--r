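#' Split configuration
#'
#' @param fractions train/validation/test fractions, summing to 1. Default
#'   0.7 / 0.1 / 0.2.
#' @param seed integer seed for the random assignment.
#' @param stratified keep per-split class proportions equal to the cohort's
#'   (default) or split the pooled cohort.
#' @return A `split_config`.
#' @export
split_config <- function(fractions = c(train = 0.7, val = 0.1, test = 0.2),
                         seed = 1L, stratified = TRUE) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0) || any(fractions > 1)) {
    stop("`fractions` must be three values in [0, 1]", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1", call. = FALSE)
  }
  structure(list(fractions = stats::setNames(fractions,
                                             c("train", "val", "test")),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_config")
}

# largest-remainder apportionment of n into parts proportional to fractions;
# ties go to the earlier part
largest_remainder <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  deficit <- n - sum(base)
  if (deficit > 0) {
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(deficit)]] <- base[ord[seq_len(deficit)]] + 1
  }
  as.integer(base)
}

#' Assign train / validation / test splits, stratified by class
#'
#' Within each diagnostic class the split sizes are the largest-remainder
#' apportionment of the fractions, so the class distribution of every split
#' matches the cohort's as closely as integer counts allow (e.g. 187 AD
#' and 229 CN at 0.7/0.1/0.2 give AD 131/19/37 and CN 160/23/46). Assignment
#' of subjects to splits is random but deterministic given the seed.
#'
#' @param records cohort tibble with `subject_id` and `label` columns.
#' @param config a [split_config()].
#' @return `records` with the `split` column set to
#'   `"train"`/`"val"`/`"test"`; row order preserved.
#' @export
stratified_split <- function(records, config = split_config()) {
  stopifnot(inherits(config, "split_config"))
  if (!all(c("subject_id", "label") %in% names(records))) {
    stop("`records` needs subject_id and label columns", call. = FALSE)
  }
  f <- config$fractions
  split <- rep(NA_character_, nrow(records))
  groups <- if (config$stratified) unique(records$label) else "all"
  with_local_seed(config$seed, {
    for (cl in groups) {
      idx <- if (config$stratified) which(records$label == cl)
             else seq_len(nrow(records))
      counts <- largest_remainder(length(idx), f)
      if (any(f > 0 & counts == 0L)) {
        stop(sprintf(
          "class '%s' (n=%d) is too small to populate all requested splits",
          cl, length(idx)
        ), call. = FALSE)
      }
      idx <- sample(idx)
      split[idx] <- rep(c("train", "val", "test"), counts)
    }
  })
  records$split <- split
  records
}

#' Balance the test set by matched undersampling of the majority class
#'
#' For each AD subject, taken in ascending subject-id order, selects the
#' not-yet-used CN subject with the smallest mean voxel-wise absolute
#' intensity difference from it, until both classes have equal counts. All
#' AD subjects are retained; selection is greedy and without replacement.
#' This deliberately keeps the CN controls that are *hardest* to distinguish
#' from the patients, making the balanced test set conservative.
#'
#' @param test_records cohort tibble rows for the test split.
#' @param volumes optional named list of in-memory volumes keyed by
#'   subject_id; otherwise volumes are read from `volume_path`.
#' @return The balanced subset of `test_records` (original row order), with
#'   the matched pairs in `attr(, "pairs")`. If CN are not in the majority
#'   the input is returned unchanged with a warning.
#' @export
undersample_match <- function(test_records, volumes = NULL) {
  ad_ids <- sort(test_records$subject_id[test_records$label == "AD"])
  cn_ids <- sort(test_records$subject_id[test_records$label == "CN"])
  if (length(cn_ids) < length(ad_ids)) {
    warning("CN class is not in the majority; returning records unchanged")
    return(test_records)
  }
  if (length(cn_ids) == length(ad_ids)) return(test_records)
  vol_of <- function(id) get_subject_volume(test_records, volumes, id)$data
  cn_vols <- lapply(cn_ids, vol_of)
  names(cn_vols) <- cn_ids
  used <- character(0)
  pairs <- vector("list", length(ad_ids))
  for (i in seq_along(ad_ids)) {
    a <- vol_of(ad_ids[i])
    candidates <- setdiff(cn_ids, used)
    dists <- vapply(candidates, function(cid) {
      mean(abs(a - cn_vols[[cid]]))
    }, numeric(1))
    pick <- candidates[which.min(dists)]  # ties: smallest CN id (sorted)
    used <- c(used, pick)
    pairs[[i]] <- tibble::tibble(ad_id = ad_ids[i], cn_id = pick,
                                 distance = min(dists))
  }
  keep <- test_records$label == "AD" | test_records$subject_id %in% used
  out <- test_records[keep, ]
  attr(out, "pairs") <- dplyr::bind_rows(pairs)
  out
}

#' Confusion counts and the five evaluation indices
#'
#' AD is the positive class. At the given threshold on the AD probability:
#' ACC = (TP+TN)/(TP+TN+FP+FN), SEN = TP/(TP+FN), SPE = TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN). AUC is the rank (Mann-Whitney) statistic — the
#' probability that a random AD score exceeds a random CN score, ties
#' counted one half — which equals the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param truth labels, `"AD"` / `"CN"`.
#' @param scores predicted probability of AD, same length.
#' @param threshold decision threshold on the AD score (default 0.5;
#'   `score >= threshold` predicts AD).
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `acc`, `sen`, `spe`,
#'   `f1`, `auc`. With a single-class truth AUC is `NA`.
#' @export
#' @examples
#' compute_metrics(c("AD", "AD", "CN"), c(0.9, 0.4, 0.2))
compute_metrics <- function(truth, scores, threshold = 0.5) {
  truth <- as.character(truth)
  if (!all(truth %in% c("AD", "CN"))) {
    stop("labels must be 'AD' or 'CN'", call. = FALSE)
  }
  stopifnot(length(truth) == length(scores))
  pred_ad <- scores >= threshold
  is_ad <- truth == "AD"
  tp <- sum(pred_ad & is_ad); fn <- sum(!pred_ad & is_ad)
  tn <- sum(!pred_ad & !is_ad); fp <- sum(pred_ad & !is_ad)
  n_ad <- sum(is_ad); n_cn <- sum(!is_ad)
  auc <- if (n_ad == 0L || n_cn == 0L) NA_real_ else {
    r <- rank(scores)  # midranks handle ties as 1/2
    (sum(r[is_ad]) - n_ad * (n_ad + 1) / 2) / (n_ad * n_cn)
  }
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    acc = (tp + tn) / length(truth),
    sen = if (n_ad > 0) tp / (tp + fn) else NA_real_,
    spe = if (n_cn > 0) tn / (tn + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    auc = auc
  )
}

#' Balanced class weights
#'
#' `w_c = N_total / (2 * N_c)`: classes are weighted inversely proportional
#' to their training-set frequency, and the weights average to one over the
#' training set.
#'
#' @param train_labels character labels, both classes present.
#' @return Named numeric vector of weights (AD, CN).
#' @export
class_weights <- function(train_labels) {
  train_labels <- as.character(train_labels)
  classes <- c("AD", "CN")
  n_c <- vapply(classes, function(cl) sum(train_labels == cl), numeric(1))
  if (any(n_c == 0)) stop("both classes must be present", call. = FALSE)
  stats::setNames(length(train_labels) / (2 * n_c), classes)
}

#' One-way repeated-measures ANOVA with sphericity diagnostics
#'
#' Standard within-subject decomposition of a complete repetition-by-
#' condition accuracy table: condition and subject (repetition) effects are
#' removed, F = MS_condition / MS_error with (k-1) and (n-1)(k-1) degrees of
#' freedom. Mauchly's test of sphericity is computed on the orthonormalized
#' contrast covariance; when it indicates a violation at the 0.05 level the
#' reported p-value is the Greenhouse-Geisser corrected one (epsilon
#' multiplying both degrees of freedom), otherwise the uncorrected p-value
#' is reported. Both are always returned.
#'
#' @param data a long tibble of the repeated-run table, or a wide
#'   numeric matrix/data frame (rows = repetitions, columns = conditions).
#' @param value,condition,repetition column names when `data` is long.
#' @return An `rm_anova_fit` with fields `F`, `df1`, `df2`, `p_uncorrected`,
#'   `epsilon_gg`, `p_gg`, `mauchly_W`, `mauchly_p`, `sphericity_violated`,
#'   `p_reported`, plus the wide table and per-condition means. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
rm_anova <- function(data, value = "acc", condition = "condition",
                     repetition = "repetition") {
  Y <- as_rm_table(data, value, condition, repetition)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L || k < 2L) {
    stop("need >= 2 repetitions and >= 2 conditions", call. = FALSE)
  }
  grand <- mean(Y)
  cond_means <- colMeans(Y)
  subj_means <- rowMeans(Y)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- Y - outer(subj_means, rep(1, k)) -
    outer(rep(1, n), cond_means) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  Fv <- if (ms_err > 0) ms_cond / ms_err else if (ss_cond == 0) 0 else Inf
  p_unc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)

  # orthonormal contrasts of the condition covariance
  M <- qr.Q(qr(stats::contr.helmert(k)))
  S <- stats::cov(Y)
  T_ <- t(M) %*% S %*% M
  ev <- eigen(T_, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  eps_gg <- if (sum(ev^2) > 0) sum(ev)^2 / (df1 * sum(ev^2)) else 1
  if (k == 2L) {
    mauchly_W <- 1; mauchly_p <- 1  # sphericity is vacuous with 2 conditions
  } else {
    detT <- prod(ev)
    trT <- sum(ev)
    mauchly_W <- if (trT > 0) detT / (trT / df1)^df1 else NA_real_
    # Box's two-term chi-square expansion for -n rho log W
    p <- df1; nrepl <- n - 1
    rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nrepl)
    w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * k + 2) /
      (288 * (nrepl * p * rho)^2)
    z <- -nrepl * rho * log(max(mauchly_W, .Machine$double.xmin))
    f_m <- p * (p + 1) / 2 - 1
    pr1 <- stats::pchisq(z, f_m, lower.tail = FALSE)
    pr2 <- stats::pchisq(z, f_m + 4, lower.tail = FALSE)
    mauchly_p <- pr1 + w2 * (pr2 - pr1)
  }
  p_gg <- stats::pf(Fv, df1 * eps_gg, df2 * eps_gg, lower.tail = FALSE)
  violated <- is.finite(mauchly_p) && mauchly_p < 0.05
  structure(
    list(F = Fv, df1 = df1, df2 = df2,
         ss_condition = ss_cond, ss_error = ss_err, ms_error = ms_err,
         p_uncorrected = p_unc, epsilon_gg = eps_gg, p_gg = p_gg,
         mauchly_W = mauchly_W, mauchly_p = mauchly_p,
         sphericity_violated = violated,
         p_reported = if (violated) p_gg else p_unc,
         n_repetitions = n, condition_means = cond_means, table = Y),
    class = "rm_anova_fit"
  )
}

# accept long tibble or wide matrix/data.frame; returns n x k numeric matrix
as_rm_table <- function(data, value, condition, repetition) {
  if (is.matrix(data)) {
    Y <- data
  } else if (is.data.frame(data) &&
             all(c(value, condition, repetition) %in% names(data))) {
    wide <- tidyr::pivot_wider(
      data[, c(repetition, condition, value)],
      names_from = dplyr::all_of(condition),
      values_from = dplyr::all_of(value)
    )
    wide <- wide[order(wide[[repetition]]), ]
    Y <- as.matrix(wide[, -1, drop = FALSE])
    rownames(Y) <- wide[[repetition]]
  } else if (is.data.frame(data)) {
    Y <- as.matrix(data)
  } else {
    stop("`data` must be a long tibble or a wide matrix", call. = FALSE)
  }
  if (!is.numeric(Y)) stop("table values must be numeric", call. = FALSE)
  if (anyNA(Y)) {
    stop("repeated-measures table is incomplete (missing cells)",
         call. = FALSE)
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("cond", seq_len(ncol(Y)))
  Y
}

#' @export
print.rm_anova_fit <- function(x, ...) {
  cat(sprintf(
    "One-way repeated-measures ANOVA: F(%.4g, %.4g) = %.3f, p = %.4g\n",
    x$df1, x$df2, x$F, x$p_uncorrected
  ))
  cat(sprintf("Mauchly W = %.4f (p = %.4g); GG epsilon = %.4f, p_GG = %.4g\n",
              x$mauchly_W, x$mauchly_p, x$epsilon_gg, x$p_gg))
  cat(sprintf("reported p (%s): %.4g\n",
              if (x$sphericity_violated) "GG-corrected" else "uncorrected",
              x$p_reported))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rm_anova_fit <- function(x, ...) {
  tibble::tibble(
    term = c("condition", "error"),
    df = c(x$df1, x$df2),
    sumsq = c(x$ss_condition, x$ss_error),
    meansq = c(x$ss_condition / x$df1, x$ms_error),
    statistic = c(x$F, NA_real_),
    p.value = c(x$p_uncorrected, NA_real_)
  )
}

#' @export
glance.rm_anova_fit <- function(x, ...) {
  tibble::tibble(
    statistic = x$F, df1 = x$df1, df2 = x$df2,
    p.value = x$p_uncorrected, epsilon_gg = x$epsilon_gg, p.gg = x$p_gg,
    mauchly_w = x$mauchly_W, mauchly_p = x$mauchly_p,
    sphericity_violated = x$sphericity_violated, p.reported = x$p_reported,
    n_repetitions = x$n_repetitions, n_conditions = x$df1 + 1L
  )
}

#' Tukey post hoc comparisons for the repeated-measures design
#'
#' All pairwise condition contrasts with studentized-range adjustment, using
#' the within-subject error mean square and its degrees of freedom. With two
#' conditions the adjusted p-value coincides with the paired t-test's.
#'
#' @param x an `rm_anova_fit` or anything [rm_anova()] accepts.
#' @param ... passed to [rm_anova()] when `x` is raw data.
#' @return Tibble of pairs: `condition1`, `condition2`, `diff`, `se`,
#'   `q`, `p_adj` (symmetric in pair order).
#' @export
tukey_posthoc <- function(x, ...) {
  fit <- if (inherits(x, "rm_anova_fit")) x else rm_anova(x, ...)
  means <- fit$condition_means
  k <- length(means)
  n <- fit$n_repetitions
  se_pair <- sqrt(2 * fit$ms_error / n)
  pairs <- utils::combn(names(means), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    d <- means[pr[1]] - means[pr[2]]
    q <- abs(d) / sqrt(fit$ms_error / n)
    p <- if (fit$ms_error == 0) as.numeric(abs(d) > 0) * 0 + (abs(d) == 0)
         else stats::ptukey(q, k, fit$df2, lower.tail = FALSE)
    tibble::tibble(condition1 = pr[1], condition2 = pr[2],
                   diff = unname(d), se = se_pair, q = unname(q),
                   p_adj = unname(p))
  })
  dplyr::bind_rows(rows)
}

#' Write an ANOVA + post hoc report as JSON
#'
#' @param fit an `rm_anova_fit`.
#' @param path output path.
#' @param tukey optional tibble from [tukey_posthoc()] (computed if omitted).
#' @return `path`, invisibly.
#' @export
write_anova_report <- function(fit, path, tukey = NULL) {
  stopifnot(inherits(fit, "rm_anova_fit"))
  if (is.null(tukey)) tukey <- tukey_posthoc(fit)
  jsonlite::write_json(
    list(
      F = fit$F, df1 = fit$df1, df2 = fit$df2,
      p_uncorrected = fit$p_uncorrected, epsilon_gg = fit$epsilon_gg,
      p_gg = fit$p_gg, mauchly_W = fit$mauchly_W, mauchly_p = fit$mauchly_p,
      sphericity_violated = fit$sphericity_violated,
      p_reported = fit$p_reported,
      condition_means = as.list(fit$condition_means),
      tukey = tukey
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
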