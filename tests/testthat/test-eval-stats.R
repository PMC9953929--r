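test_that("stratified split apportions by largest remainder within class", {
  rec <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:416),
    label = c(rep("AD", 187), rep("CN", 229))
  )
  out <- stratified_split(rec, split_config(seed = 1))
  tab <- table(out$label, out$split)
  expect_equal(unname(tab["AD", c("train", "val", "test")]), c(131, 19, 37))
  expect_equal(unname(tab["CN", c("train", "val", "test")]), c(160, 23, 46))
  # no subject in two splits, all assigned
  expect_false(anyNA(out$split))
  expect_equal(nrow(out), 416L)
})

test_that("splitting is deterministic and degenerate fractions work", {
  rec <- tibble::tibble(subject_id = sprintf("s%02d", 1:30),
                        label = rep(c("AD", "CN"), 15))
  a <- stratified_split(rec, split_config(seed = 9))
  b <- stratified_split(rec, split_config(seed = 9))
  expect_identical(a, b)
  c2 <- stratified_split(rec, split_config(seed = 10))
  expect_false(identical(a$split, c2$split))

  all_train <- stratified_split(rec, split_config(c(1, 0, 0), seed = 1))
  expect_true(all(all_train$split == "train"))

  tiny <- tibble::tibble(subject_id = c("a", "b"), label = c("AD", "CN"))
  expect_error(stratified_split(tiny, split_config(seed = 1)), "too small")
})

test_that("matched undersampling picks the nearest unused CN control", {
  mkvol <- function(val) vol3d(array(val, c(2, 2, 2)))
  rec <- tibble::tibble(
    subject_id = c("a1", "c1", "c2"),
    label = c("AD", "CN", "CN"),
    volume_path = NA_character_, split = "test"
  )
  vols <- list(a1 = mkvol(0.5), c1 = mkvol(0.7), c2 = mkvol(0.6))
  out <- undersample_match(rec, vols)
  expect_setequal(out$subject_id, c("a1", "c2"))
  expect_equal(attr(out, "pairs")$cn_id, "c2")
  expect_equal(attr(out, "pairs")$distance, 0.1, tolerance = 1e-12)

  balanced <- rec[1:2, ]
  expect_identical(undersample_match(balanced, vols), balanced)

  minority <- tibble::tibble(subject_id = c("a1", "a2", "c1"),
                             label = c("AD", "AD", "CN"),
                             volume_path = NA_character_, split = "test")
  expect_warning(out2 <- undersample_match(minority, vols), "majority")
  expect_identical(out2, minority)
})

test_that("greedy matching agrees with an independent brute-force check", {
  # 2 AD, 3 CN with a constructed distance table; the oracle replays the
  # stated greedy rule (ascending AD id, argmin over unused CN) explicitly
  set.seed(31)
  for (trial in 1:10) {
    vals_ad <- runif(2); vals_cn <- runif(3)
    rec <- tibble::tibble(
      subject_id = c("ad1", "ad2", "cn1", "cn2", "cn3"),
      label = c("AD", "AD", "CN", "CN", "CN"),
      volume_path = NA_character_, split = "test"
    )
    vols <- c(
      stats::setNames(lapply(vals_ad, function(v) vol3d(array(v, c(3, 3, 3)))),
                      c("ad1", "ad2")),
      stats::setNames(lapply(vals_cn, function(v) vol3d(array(v, c(3, 3, 3)))),
                      c("cn1", "cn2", "cn3"))
    )
    dist_tab <- outer(vals_ad, vals_cn, function(a, b) abs(a - b))
    used <- integer(0); expect_pick <- character(0)
    for (i in 1:2) {
      cand <- setdiff(1:3, used)
      pick <- cand[which.min(dist_tab[i, cand])]
      used <- c(used, pick)
      expect_pick <- c(expect_pick, paste0("cn", pick))
    }
    out <- undersample_match(rec, vols)
    expect_equal(attr(out, "pairs")$cn_id, expect_pick)
    expect_equal(sum(out$label == "AD"), sum(out$label == "CN"))
  }
})

test_that("the five indices follow their defining formulas", {
  # TP=9 TN=9 FP=1 FN=1 by construction
  truth <- c(rep("AD", 10), rep("CN", 10))
  scores <- c(rep(0.9, 9), 0.1, rep(0.1, 9), 0.9)
  m <- compute_metrics(truth, scores)
  expect_equal(unlist(m[c("tp", "tn", "fp", "fn")], use.names = FALSE),
               c(9L, 9L, 1L, 1L))
  expect_equal(unlist(m[c("acc", "sen", "spe", "f1")], use.names = FALSE),
               rep(0.9, 4))

  perfect <- compute_metrics(truth, c(rep(0.8, 10), rep(0.2, 10)))
  expect_equal(perfect$auc, 1)

  m3 <- compute_metrics(c("AD", "CN", "AD"), c(0.9, 0.8, 0.4))
  expect_equal(m3$auc, 0.5)
  m3sq <- compute_metrics(c("AD", "CN", "AD"), c(0.9, 0.8, 0.4)^2)
  expect_equal(m3sq$auc, m3$auc)  # rank statistic: monotone invariant

  single <- compute_metrics(c("AD", "AD"), c(0.9, 0.2))
  expect_true(is.na(single$auc))
  expect_equal(single$acc, 0.5)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(17)
  for (i in 1:100) {
    tp <- sample(0:30, 1); fn <- sample(0:30, 1)
    tn <- sample(0:30, 1); fp <- sample(0:30, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    truth <- c(rep("AD", tp + fn), rep("CN", tn + fp))
    scores <- c(rep(0.9, tp), rep(0.1, fn), rep(0.1, tn), rep(0.9, fp))
    m <- compute_metrics(truth, scores)
    expect_equal(unlist(m[c("tp", "tn", "fp", "fn")], use.names = FALSE),
                 c(tp, tn, fp, fn))
    expect_equal(m$acc, (tp + tn) / (tp + tn + fp + fn))
    expect_equal(m$sen * (tp + fn), tp)
    expect_equal(m$spe * (tn + fp), tn)
    if (2 * tp + fp + fn > 0) {
      expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
    }
    # balanced identity: ACC = (SEN + SPE) / 2 when classes have equal size
    if (tp + fn == tn + fp) {
      expect_equal(m$acc, (m$sen + m$spe) / 2)
    }
  }
})

test_that("rank AUC equals the trapezoidal ROC area", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    truth <- sample(c("AD", "CN"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), 2)  # rounding forces ties
    m <- compute_metrics(truth, scores)
    ref <- pROC::auc(pROC::roc(response = truth, predictor = scores,
                               levels = c("CN", "AD"), direction = "<",
                               quiet = TRUE))
    expect_equal(m$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("class weights are inverse-frequency and average to one", {
  expect_equal(class_weights(rep(c("AD", "CN"), 25)),
               c(AD = 1, CN = 1))
  w <- class_weights(c(rep("AD", 40), rep("CN", 60)))
  expect_equal(w, c(AD = 1.25, CN = 100 / 120))
  labels <- c(rep("AD", 13), rep("CN", 29))
  w2 <- class_weights(labels)
  expect_equal(mean(w2[labels]), 1)
  expect_error(class_weights(rep("AD", 5)), "both classes")
})

test_that("repeated-measures ANOVA has the textbook properties", {
  # identical cells: no condition effect at all
  flat <- matrix(0.8, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- rm_anova(flat)
  expect_equal(fit$F, 0)
  expect_equal(fit$ss_condition, 0)

  # two conditions: F is the squared paired t statistic
  set.seed(5)
  for (i in 1:50) {
    Y <- matrix(runif(2 * 12), 12, 2, dimnames = list(NULL, c("a", "b")))
    fit2 <- rm_anova(Y)
    tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
    expect_equal(fit2$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(fit2$p_uncorrected, tt$p.value, tolerance = 1e-10)
  }

  # compound-symmetric data: epsilon near 1
  set.seed(6)
  subj <- rnorm(200, sd = 0.5)
  Y <- sapply(1:4, function(j) subj + rnorm(200, sd = 0.3))
  fit3 <- rm_anova(Y)
  expect_gt(fit3$epsilon_gg, 0.95)

  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2, 2)), "incomplete")
})

test_that("our RM-ANOVA matches the car univariate oracle", {
  skip_if_not_installed("car")
  set.seed(77)
  n <- 15; k <- 4
  Y <- matrix(rnorm(n * k), n, k) + outer(rnorm(n), rep(1, k)) +
    outer(rep(1, n), c(0, 0.2, 0.1, 0.4))
  Y <- Y + matrix(rnorm(n * k, sd = rep(c(0.2, 1), length.out = k)), n, k,
                  byrow = TRUE)  # heteroscedastic: sphericity stressed
  colnames(Y) <- paste0("c", 1:k)
  fit <- rm_anova(Y)
  mod <- stats::lm(Y ~ 1)
  aov_car <- car::Anova(mod, idata = data.frame(cond = factor(1:k)),
                        idesign = ~cond, type = 3)
  s <- summary(aov_car, multivariate = FALSE)
  uni <- s$univariate.tests
  expect_equal(fit$F, uni["cond", "F value"], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$p_uncorrected, uni["cond", "Pr(>F)"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$epsilon_gg, s$pval.adjustments["cond", "GG eps"],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$p_gg, s$pval.adjustments["cond", "Pr(>F[GG])"],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$mauchly_W, s$sphericity.tests["cond", "Test statistic"],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$mauchly_p, s$sphericity.tests["cond", "p-value"],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("tidy and glance summarize the fit", {
  Y <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- rm_anova(Y)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("condition", "error"))
  expect_equal(td$statistic[1], fit$F)
  gl <- generics::glance(fit)
  expect_equal(gl$epsilon_gg, fit$epsilon_gg)
  expect_equal(gl$n_conditions, 3L)
})

test_that("Tukey post hoc reduces to the paired t with two conditions", {
  set.seed(8)
  Y <- matrix(runif(24), 12, 2, dimnames = list(NULL, c("a", "b")))
  tk <- tukey_posthoc(rm_anova(Y))
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)

  # identical conditions: adjusted p of 1
  flat <- matrix(rep(runif(12), 3), 12, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  tk2 <- tukey_posthoc(rm_anova(flat))
  expect_true(all(tk2$p_adj == 1))

  # a strongly shifted condition yields the smallest adjusted p-values
  set.seed(9)
  Y3 <- matrix(rnorm(36, sd = 0.1), 12, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  Y3[, "c"] <- Y3[, "c"] + 5
  tk3 <- tukey_posthoc(rm_anova(Y3))
  with_c <- grepl("c", paste(tk3$condition1, tk3$condition2))
  expect_lt(max(tk3$p_adj[with_c]), min(tk3$p_adj[!with_c]))
  expect_true(all(tk3$p_adj[with_c] < 1e-6))
})

test_that("the ANOVA report serializes to JSON", {
  Y <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- rm_anova(Y)
  path <- withr::local_tempfile(fileext = ".json")
  write_anova_report(fit, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$F, fit$F, tolerance = 1e-10)
  expect_named(j$condition_means, c("a", "b", "c"))
  expect_equal(length(j$tukey), 3L)
})
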