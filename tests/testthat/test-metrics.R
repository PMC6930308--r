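test_that("confusion counts match a naive double loop", {
  co <- c("a", "b", "c")
  cm <- confusion(c("a", "a", "b"), c("a", "a", "b"), co)
  expect_equal(unname(diag(cm)), c(2, 1, 0))
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  with_seed_local(13, {
    truth <- sample(co, 60, replace = TRUE)
    guess <- sample(co, 60, replace = TRUE)
  })
  got <- confusion(truth, guess, co)
  naive <- matrix(0L, 3, 3, dimnames = list(true = co, assigned = co))
  for (i in seq_along(truth)) {
    r <- match(truth[i], co); c <- match(guess[i], co)
    naive[r, c] <- naive[r, c] + 1L
  }
  expect_identical(got, naive)
  expect_equal(unname(rowSums(got)), unname(as.integer(table(factor(truth, co)))))

  expect_error(confusion(c("a"), c("a", "b"), co), "equal length")
  expect_error(confusion("z", "a", co), "z")
})

test_that("one-vs-rest metrics follow the TP/TN decomposition", {
  # 15 in-class / 75 out-of-class test design: TP=12, FN=3, FP=0, TN=75
  cm <- matrix(0L, 2, 2, dimnames = list(true = c("g", "rest"),
                                         assigned = c("g", "rest")))
  cm["g", "g"] <- 12L; cm["g", "rest"] <- 3L; cm["rest", "rest"] <- 75L
  m <- per_class_metrics(cm)
  g <- m[m$class == "g", ]
  expect_equal(g$sensitivity, 0.800)
  expect_equal(g$specificity, 1.000)
  expect_equal(round(100 * g$accuracy, 1), 96.7)

  perfect <- diag(c(5L, 7L, 9L))
  dimnames(perfect) <- list(true = letters[1:3], assigned = letters[1:3])
  mp <- per_class_metrics(perfect)
  expect_true(all(mp$sensitivity == 1 & mp$specificity == 1 & mp$accuracy == 1))

  cm2 <- matrix(c(3L, 2L, 1L, 4L), 2, 2,
                dimnames = list(true = c("p", "q"), assigned = c("p", "q")))
  m2 <- per_class_metrics(cm2)
  expect_equal(m2$sensitivity[1], 0.75)
  expect_equal(m2$specificity[1], 4 / 6)
  expect_equal(m2$accuracy[1], 0.7)

  empty <- matrix(c(0L, 5L, 0L, 3L), 2, 2,
                  dimnames = list(true = c("none", "all"),
                                  assigned = c("none", "all")))
  me <- per_class_metrics(empty)
  expect_true(is.na(me$sensitivity[me$class == "none"]))
})

# published per-class results for the six-variety study: sensitivity,
# specificity and accuracy (%) for cross-validation (35 in-class / 175
# out-of-class calibration leaves) and test-set validation (15 / 75),
# full-spectrum and truncated models, dried and fresh leaves
published_rows <- function() {
  txt <- "
model,type,class,evaluation,sens,spec,acc
full,dried,Avijor,cv,0.971,0.994,99.0
full,dried,Avijor,test,1.000,0.973,97.8
full,dried,Guara,cv,0.829,0.983,95.7
full,dried,Guara,test,0.800,1.000,96.7
full,dried,Isabelona,cv,0.971,0.960,96.2
full,dried,Isabelona,test,1.000,0.973,97.8
full,dried,Marta,cv,0.971,0.983,98.1
full,dried,Marta,test,1.000,1.000,100
full,dried,Pentacebas,cv,0.886,0.989,97.1
full,dried,Pentacebas,test,0.933,0.987,97.8
full,dried,Soleta,cv,0.886,0.994,97.6
full,dried,Soleta,test,0.933,1.000,98.9
full,fresh,Avijor,cv,0.857,0.977,95.7
full,fresh,Avijor,test,1.000,1.000,100
full,fresh,Guara,cv,0.857,0.943,92.9
full,fresh,Guara,test,0.600,0.987,92.2
full,fresh,Isabelona,cv,0.657,0.943,89.5
full,fresh,Isabelona,test,0.867,0.933,92.2
full,fresh,Marta,cv,0.943,0.994,98.6
full,fresh,Marta,test,1.000,1.000,100
full,fresh,Pentacebas,cv,0.914,0.983,97.1
full,fresh,Pentacebas,test,1.000,1.000,100
full,fresh,Soleta,cv,0.743,0.954,91.9
full,fresh,Soleta,test,0.933,0.960,95.6
trunc,dried,Avijor,cv,0.971,0.994,99.0
trunc,dried,Avijor,test,1.000,0.973,97.8
trunc,dried,Guara,cv,0.829,0.977,95.2
trunc,dried,Guara,test,0.867,0.987,96.7
trunc,dried,Isabelona,cv,0.914,0.943,93.8
trunc,dried,Isabelona,test,0.933,0.987,97.8
trunc,dried,Marta,cv,1.000,0.989,99.0
trunc,dried,Marta,test,1.000,1.000,100
trunc,dried,Pentacebas,cv,0.886,0.983,96.7
trunc,dried,Pentacebas,test,0.933,1.000,98.9
trunc,dried,Soleta,cv,0.800,0.994,96.2
trunc,dried,Soleta,test,1.000,1.000,100
trunc,fresh,Avijor,cv,0.857,0.977,95.7
trunc,fresh,Avijor,test,1.000,1.000,100
trunc,fresh,Guara,cv,0.829,0.943,92.4
trunc,fresh,Guara,test,0.600,0.987,92.2
trunc,fresh,Isabelona,cv,0.686,0.949,90.5
trunc,fresh,Isabelona,test,0.867,0.907,90.0
trunc,fresh,Marta,cv,0.914,0.983,97.1
trunc,fresh,Marta,test,1.000,1.000,100
trunc,fresh,Pentacebas,cv,0.886,0.971,95.7
trunc,fresh,Soleta,cv,0.743,0.960,92.4
trunc,fresh,Soleta,test,0.933,0.960,95.6
"
  read.csv(text = txt, stringsAsFactors = FALSE)
}

test_that("published table cells reconstruct from the metric identity", {
  # accuracy = (sens * n_pos + spec * n_neg) / (n_pos + n_neg), with
  # 35/175 leaves in cross-validation and 15/75 in the test set.
  # The truncated fresh Pentacebas test row is excluded: its printed
  # specificity (0.133) contradicts its own printed accuracy and is a
  # typographical error in the source table.
  rows <- published_rows()
  n_pos <- ifelse(rows$evaluation == "cv", 35, 15)
  n_neg <- ifelse(rows$evaluation == "cv", 175, 75)
  acc <- 100 * (rows$sens * n_pos + rows$spec * n_neg) / (n_pos + n_neg)
  # inputs are printed to 3 decimals (up to 0.05% slack after weighting),
  # accuracies to 1 decimal (0.05% slack): combined bound 0.1
  expect_true(all(abs(acc - rows$acc) <= 0.1),
              info = paste("worst cell off by",
                           round(max(abs(acc - rows$acc)), 3)))
  expect_equal(nrow(rows), 47)
})

test_that("reports render with one-decimal percentages and re-parse", {
  cm_cv <- confusion(rep(letters[1:3], each = 10),
                     rep(letters[1:3], each = 10), letters[1:3])
  cm_te <- cm_cv
  rep1 <- class_report(cm_cv, cm_te, "full_spectrum", n_lv = 5,
                       n_variables = 100)
  expect_equal(nrow(rep1), 6)  # 3 classes x 2 evaluations
  expect_named(rep1, c("model", "class", "evaluation", "sensitivity",
                       "specificity", "accuracy_percent", "n_lv",
                       "n_variables"))

  rep1$accuracy_percent[1] <- 96.66667
  lines <- render_report(rep1)
  expect_match(lines[2], "96.7%")

  path <- withr::local_tempfile(fileext = ".csv")
  render_report(rep1, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 6)
  expect_equal(back$accuracy_percent[1], 96.7)

  # micro-accuracy: trace over total is one minus the misassignment rate
  cm <- confusion(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
                  c("a", "b"))
  expect_equal(sum(diag(cm)) / sum(cm), 1 - 1 / 4)
})
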