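test_that("a spiked column separates two classes in the first predictive score", {
  set.seed(21)
  x <- matrix(rnorm(40 * 25), 40, 25)
  cls <- rep(c("a", "b"), each = 20)
  x[cls == "b", 7] <- x[cls == "b", 7] + 6
  x <- sweep(x, 2, colMeans(x))
  fit <- fit_oplsda(x, cls, n_pred = 1)
  expect_equal(fit$N, 40)
  sa <- fit$scores[cls == "a", 1]
  sb <- fit$scores[cls == "b", 1]
  expect_true(max(sa) < min(sb) || min(sa) > max(sb))
  expect_equal(sort(unique(predict(fit, x))), c("a", "b"))
  expect_equal(mean(predict(fit, x) == cls), 1)
})

test_that("the indicator matrix has one column per condition class", {
  set.seed(4)
  x <- matrix(rnorm(100 * 30), 100, 30)
  cls <- rep(paste0(rep(c("F", "M"), each = 10), rep(1:10, 2)), each = 5)
  fit <- fit_oplsda(x, cls, n_pred = 3)
  expect_equal(length(fit$class_levels), 20)
  expect_equal(fit$N, 100)
  expect_error(fit_oplsda(x[1:3, ], c("a", "a", "b")), "at least 2 samples")
})

test_that("shuffled class labels drive cross-validated accuracy to chance", {
  set.seed(77)
  x <- matrix(rnorm(40 * 20), 40, 20)
  cls <- rep(c("a", "b"), each = 20)
  x[cls == "b", 3] <- x[cls == "b", 3] + 5
  acc_true <- oplsda_cv_accuracy(x, cls, n_pred = 1, folds = 5,
                                 scaling = "none")
  expect_gte(acc_true, 0.9)
  accs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    oplsda_cv_accuracy(x, sample(cls), n_pred = 1, folds = 5, seed = s,
                       scaling = "none")
  }, numeric(1))
  # chance level for two balanced classes; cross-validation under
  # permuted labels is biased slightly below 0.5
  expect_lt(mean(accs), 0.65)
  expect_gt(mean(accs), 0.2)
})

test_that("identical points merge at height zero and small cases match brute force", {
  pts <- rbind(a = c(1, 1), b = c(1, 1), c = c(4, 5))
  dend <- hca_ward(pts)
  expect_equal(dend$height[1], 0)
  one_d <- matrix(c(0, 1, 10), ncol = 1,
                  dimnames = list(c("p0", "p1", "p10"), NULL))
  dend2 <- hca_ward(one_d)
  sets <- hclust_merge_sets(dend2$hclust)
  expect_equal(sets[[1]], c("p0", "p1"))
  expect_equal(sets[[2]], c("p0", "p1", "p10"))
  oracle <- oracle_ward(one_d)
  expect_equal(dend2$height, oracle$heights, tolerance = 1e-10)
  expect_error(hca_ward(pts, labels = c("x", "x", "y")), "duplicate")
})

test_that("Ward merge heights are monotone and the tree exports as valid Newick", {
  set.seed(13)
  pts <- matrix(rnorm(20 * 3), 20, 3,
                dimnames = list(sprintf("c%02d", 1:20), NULL))
  dend <- hca_ward(pts)
  expect_true(all(diff(dend$height) >= -1e-10))
  nwk <- as_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_equal(sort(phy$tip.label), sort(rownames(pts)))
})

test_that("a strong sex split at warm temperatures reproduces the expected topology", {
  temps <- c(12, 15.5, 18, 20, 22, 25, 27, 29.5, 31, 32)
  # low temperatures: temperature differences dwarf the sex offset;
  # warm temperatures: the male offset dominates
  sex_gap <- ifelse(temps >= 22, 8, 0.2)
  temp_axis <- 0.2 * (temps - 22)
  pts <- rbind(cbind(temp_axis, sex_gap / 2),
               cbind(temp_axis, -sex_gap / 2))
  labels <- c(paste0("F", temps), paste0("M", temps))
  dend <- hca_ward(pts, labels = labels)
  top <- top_partition(dend)
  male_warm <- paste0("M", c(22, 25, 27, 29.5, 31, 32))
  side <- vapply(top, function(g) all(male_warm %in% g), logical(1))
  expect_true(any(side))
  warm_side <- top[[which(side)[1]]]
  expect_false(any(paste0("F", temps) %in% warm_side))
  # at cold temperatures the sexes stay together
  coph <- stats::cophenetic(dend$hclust)
  m <- as.matrix(coph)
  expect_lt(m["F12", "M12"], m["F12", "F18"])
})
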