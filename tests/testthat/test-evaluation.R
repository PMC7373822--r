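# Group mean, NCC-to-mean, majority vote, Dice, surface points, HD95

test_that("group mean and ncc_to_mean behave on degenerate cohorts", {
  set.seed(6)
  a <- volume(array(rnorm(5^3)^2 + 0.1, dim = c(5, 5, 5)))
  expect_equal(group_mean(list(a, a, a))$data, a$data)
  b <- volume(-a$data)
  expect_equal(max(abs(group_mean(list(a, b))$data)), 0)
  same <- ncc_to_mean(list(x = a, y = a, z = a))
  expect_true(all(same$scores == 1))
  expect_equal(same$sd, 0)
  # two images of equal variance score identically against their mean
  c2 <- volume(array(sample(a$data), dim = c(5, 5, 5)))
  two <- ncc_to_mean(list(p = a, q = c2))
  expect_equal(two$scores[["p"]], two$scores[["q"]], tolerance = 1e-10)
  # elementwise oracle for the mean
  d3 <- lapply(1:3, function(i) volume(array(rnorm(4^3), dim = c(4, 4, 4))))
  gm <- group_mean(d3)
  expect_equal(gm$data, (d3[[1]]$data + d3[[2]]$data + d3[[3]]$data) / 3)
})

test_that("majority vote takes the modal label with low ties", {
  mk <- function(v) label_volume(array(v, dim = c(1, 1, 1)))
  expect_equal(as.vector(majority_vote(list(mk(1), mk(1), mk(2)))$labels), 1L)
  expect_equal(as.vector(majority_vote(list(mk(1), mk(2)))$labels), 1L)
  expect_equal(as.vector(majority_vote(list(mk(5), mk(2), mk(2)))$labels), 2L)
  l <- random_label_volume(1)
  expect_identical(majority_vote(list(l, l, l))$labels, l$labels)
})

test_that("dice matches closed forms and the brute-force oracle", {
  l1 <- array(0L, dim = c(4, 4, 4)); l1[1:2, 1, 1] <- 1L; l1[1:2, 2, 1] <- 1L
  l2 <- array(0L, dim = c(4, 4, 4)); l2[1:2, 2, 1] <- 1L; l2[1:2, 3, 1] <- 1L
  a <- label_volume(l1); b <- label_volume(l2)
  expect_equal(dice(a, a, 1), 100)
  expect_equal(dice(a, b, 1), 50)  # |V1| = |V2| = 4, overlap 2
  disj <- label_volume({ d <- array(0L, dim = c(4, 4, 4)); d[4, 4, 4] <- 1L; d })
  expect_equal(dice(a, disj, 1), 0)
  expect_error(dice(a, b, 9), "absent")
  expect_equal(dice(a, b, 1), dice(b, a, 1))
})

test_that("surface extraction follows 6-connectivity with grid edges as boundary", {
  one <- array(0L, dim = c(5, 5, 5)); one[3, 3, 3] <- 1L
  sp <- surface_points(label_volume(one), 1)
  expect_equal(nrow(sp), 1)
  expect_equal(as.vector(sp), c(2, 2, 2))  # (3,3,3) -> mm with origin 0
  cube <- array(0L, dim = c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1L
  expect_equal(nrow(surface_points(label_volume(cube), 1)), 26)
  full <- array(1L, dim = c(4, 4, 4))
  expect_equal(nrow(surface_points(label_volume(full), 1)), 4^3 - 2^3)
  expect_error(surface_points(label_volume(one), 2), "absent")
})

test_that("hd95 matches distances and the all-pairs oracle", {
  two <- array(0L, dim = c(10, 10, 10))
  two[2, 2, 2] <- 1L
  a <- label_volume(two)
  two2 <- array(0L, dim = c(10, 10, 10))
  two2[5, 6, 2] <- 1L  # offset (3, 4, 0) -> distance 5
  b <- label_volume(two2)
  expect_equal(hd95(a, b, 1), 5)
  expect_equal(hd95(a, a, 1), 0)
  for (seed in c(1:10)) {
    la <- random_label_volume(seed)
    lb <- random_label_volume(seed + 100)
    for (lab in 1:2) {
      if (!any(la$labels == lab) || !any(lb$labels == lab)) next
      expect_equal(hd95(la, lb, lab),
                   ref_hd(la$labels, lb$labels, lab),
                   tolerance = 1e-9, info = paste("seed", seed, "label", lab))
      expect_equal(dice(la, lb, lab),
                   ref_dice(as.vector(la$labels), as.vector(lb$labels), lab),
                   info = paste("dice seed", seed))
    }
  }
})

test_that("evaluate_cohort reports perfect scores for identical cohorts", {
  l <- random_label_volume(3)
  v <- volume(array(rnorm(16^3)^2 + 0.1, dim = c(16, 16, 16)))
  vols <- list(a = v, b = v, c = v)
  labs <- list(a = l, b = l, c = l)
  rep_ <- evaluate_cohort(vols, labs, c(blob1 = 1, blob2 = 2))
  expect_equal(nrow(rep_$per_image), 3 * 2)
  expect_true(all(rep_$per_image$dice == 100))
  expect_true(all(rep_$per_image$hd95 == 0))
  expect_true(all(rep_$ncc$scores == 1))
  expect_identical(rep_$summary$structure, c("blob1", "blob2", "overall"))
})
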