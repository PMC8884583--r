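rand_map <- function(m, tw) {
  channel_prob_map(matrix(runif(m * tw), m, tw,
                          dimnames = list(paste0("ch", seq_len(m)), NULL)))
}

test_that("the global trace is the channel-wise maximum", {
  map <- channel_prob_map(matrix(c(0.2, 0.9, 0.4, 0.1, 0.3, 0.5), 3, 2,
                                 dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(global_max_pool(map), c(0.9, 0.5))
  one <- channel_prob_map(matrix(runif(5), 1, 5,
                                 dimnames = list("a", NULL)))
  expect_equal(global_max_pool(one), unname(unclass(one)[1, ]))
  tie <- channel_prob_map(matrix(0.5, 4, 3,
                                 dimnames = list(letters[1:4], NULL)))
  expect_equal(global_max_pool(tie), rep(0.5, 3))
  empty <- channel_prob_map(matrix(numeric(0), 0, 0,
                                   dimnames = list(NULL, NULL)))
  expect_error(global_max_pool(empty), "zero channels")
})

test_that("onset increments keep only positive transitions", {
  expect_equal(onset_increments(c(0.1, 0.7, 0.7)), c(0.6, 0))
  expect_equal(onset_increments(rep(0.4, 5)), rep(0, 4))
  expect_equal(onset_increments(c(0.9, 0.5, 0.2)), c(0, 0))
  expect_error(onset_increments(0.5), "at least 2")
})

test_that("onset map weights channel activity at entered windows", {
  # single transition: scores equal the entered-window column
  probs <- matrix(c(0.1, 0.1, 0.8, 0.2), 2, 2,
                  dimnames = list(c("a", "b"), NULL))
  om <- compute_onset_map(channel_prob_map(probs))
  expect_equal(unname(om$channel_scores), c(0.8, 0.2), tolerance = 1e-12)
  # constant map across channels -> uniform scores
  const <- channel_prob_map(matrix(c(0.2, 0.2, 0.7, 0.7, 0.7, 0.2), 3, 2,
                                   dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(unname(compute_onset_map(const)$channel_scores), rep(1/3, 3))
  # hand-evaluated two-step example with an explicit trace (0, 0.5, 1):
  # delta = (0.5, 0.5); ch1: 0.5*0.5 + 0.5*0.9 = 0.7; ch2: 0.5*0.5 +
  # 0.5*0.1 = 0.3 (matches the independent brute-force oracle below)
  probs <- matrix(c(0.0, 0.0, 0.5, 0.5, 0.9, 0.1), 2, 3,
                  dimnames = list(c("a", "b"), NULL))
  om <- compute_onset_map(channel_prob_map(probs), trace = c(0, 0.5, 1))
  expect_equal(unname(om$channel_scores), c(0.7, 0.3), tolerance = 1e-12)
  expect_false(om$degenerate)
  # no positive increment anywhere -> uniform, flagged
  flat <- channel_prob_map(matrix(c(0.9, 0.3, 0.1, 0.2), 2, 2,
                                  dimnames = list(c("a", "b"), NULL)))
  om <- compute_onset_map(flat)
  expect_true(om$degenerate)
  expect_equal(unname(om$channel_scores), c(0.5, 0.5))
})

test_that("onset map and max pool match brute force on 200 random maps", {
  set.seed(2024)
  for (i in 1:200) {
    m <- sample(2:6, 1)
    tw <- sample(2:10, 1)
    map <- rand_map(m, tw)
    expect_lt(max(abs(global_max_pool(map) - naive_max_pool(unclass(map)))),
              1e-10)
    om <- compute_onset_map(map)
    expect_lt(max(abs(om$channel_scores - naive_onset_map(unclass(map)))),
              1e-10)
  }
})

test_that("normalization, dominance and scale-covariance invariants hold", {
  set.seed(11)
  for (i in 1:50) {
    map <- rand_map(sample(2:8, 1), sample(3:12, 1))
    trace <- global_max_pool(map)
    expect_true(all(sweep(unclass(map), 2, trace) <= 1e-12))   # dominance
    om <- compute_onset_map(map)
    expect_lt(abs(sum(om$channel_scores) - 1), 1e-6)
    # scaling all probabilities by c in (0, 1] rescales increments but
    # leaves the normalized scores unchanged
    sc <- channel_prob_map(unclass(map) * 0.37)
    if (!om$degenerate)
      expect_equal(compute_onset_map(sc)$channel_scores, om$channel_scores,
                   tolerance = 1e-9)
  }
})

test_that("zone scores aggregate and renormalize over included electrodes", {
  mont <- default_montage()
  hp <- hemisphere_partition(mont)
  # all mass on one left electrode
  sc <- setNames(rep(0, 16), mont); sc["T7"] <- 1
  om <- structure(list(channel_scores = sc, degenerate = FALSE),
                  class = "onset_map")
  expect_equal(as.numeric(zone_scores(om, hp)), c(1, 0))
  # uniform over the lateral montage -> symmetric hemispheres
  omu <- structure(list(channel_scores = setNames(rep(1/16, 16), mont),
                        degenerate = FALSE), class = "onset_map")
  expect_equal(as.numeric(zone_scores(omu, hp)), c(0.5, 0.5))
  # region zones are unbalanced by electrode count (6 anterior, 10 posterior)
  rp <- region_partition(mont)
  expect_equal(as.numeric(zone_scores(omu, rp)), c(6, 10) / 16)
  # midline mass is discarded and the pair renormalized
  mont3 <- default_montage(include_midline = TRUE)
  sc3 <- setNames(rep(0, 19), mont3)
  sc3[c("Cz", "T7", "T8")] <- c(0.5, 0.3, 0.2)
  om3 <- structure(list(channel_scores = sc3, degenerate = FALSE),
                   class = "onset_map")
  zs <- zone_scores(om3, hemisphere_partition(mont3))
  expect_equal(as.numeric(zs), c(0.6, 0.4))
  expect_lt(abs(sum(zs) - 1), 1e-6)
  # zero mass in both zones -> uninformative pair, flagged
  om0 <- structure(list(channel_scores = setNames(c(1, rep(0, 18)),
                                                  c("Cz", mont3[-10])),
                        degenerate = FALSE), class = "onset_map")
  z0 <- zone_scores(om0, hemisphere_partition(mont3))
  expect_equal(as.numeric(z0), c(0.5, 0.5))
  expect_true(attr(z0, "degenerate"))
})

test_that("localize_map reports both partitions", {
  set.seed(3)
  map <- channel_prob_map(matrix(runif(16 * 6), 16, 6,
                                 dimnames = list(default_montage(), NULL)))
  om <- localize_map(map)
  expect_lt(abs(sum(om$hemisphere_scores) - 1), 1e-6)
  expect_lt(abs(sum(om$region_scores) - 1), 1e-6)
})
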