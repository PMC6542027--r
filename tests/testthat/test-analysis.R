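test_that("frame and instance usages follow the run-length encoding", {
  z <- c(1L, 1L, 2L)
  uf <- usages(z, "frames")
  expect_equal(uf$usage, c(2 / 3, 1 / 3))
  ui <- usages(z, "instances")
  expect_equal(ui$usage, c(1 / 2, 1 / 2))
  expect_error(usages(integer(0)), "empty")
})

test_that("frame usages equal run-length-weighted instance usages", {
  set.seed(21)
  z <- sample_sticky_chain(5, 6, 3000, seed = 21)
  runs <- rle(z)
  uf <- usages(z, "frames")
  weighted <- vapply(uf$syllable, function(s)
    sum(runs$lengths[runs$values == s]) / length(z), numeric(1))
  expect_equal(uf$usage, weighted, tolerance = 1e-12)
  expect_equal(sum(uf$usage), 1, tolerance = 1e-10)
  expect_equal(sum(usages(z, "instances")$usage), 1, tolerance = 1e-10)
})

test_that("durations are run lengths over fps", {
  d <- durations(label_sequence(c(1, 1, 1, 2, 2, 1), fps = 30))
  expect_equal(d$duration_s[d$syllable == 1], c(3 / 30, 1 / 30))
  expect_equal(d$duration_s[d$syllable == 2], 2 / 30)
  one <- durations(label_sequence(rep(1L, 300), fps = 30))
  expect_equal(one$duration_s, 10)
})

test_that("geometric dwell of mean 9 frames gives roughly 300 ms mean durations", {
  z <- sample_sticky_chain(6, 9, 1e5, seed = 30)
  d <- durations(label_sequence(z, fps = 30))
  expect_lt(abs(mean(d$duration_s) - 0.3) / 0.3, 0.1)
})

test_that("transition matrix counts run-to-run transitions", {
  P <- transition_matrix(c(1L, 1L, 2L, 2L, 1L, 3L))
  # run sequence 1,2,1,3: counts 1->2, 2->1, 1->3
  expect_equal(unname(P["1", ]), c(0, 0.5, 0.5))
  expect_equal(unname(P["2", "1"]), 1)
  expect_true(attr(P, "terminal")[["3"]])
  expect_error(transition_matrix(c(1L, 2L), exclude_self = FALSE))
})

test_that("single-run sequences have an all-terminal transition set", {
  P <- transition_matrix(rep(2L, 10))
  expect_true(all(attr(P, "terminal")))
  expect_true(all(P == 0))
})

test_that("non-terminal rows are stochastic for any labels", {
  for (s in 1:5) {
    z <- sample_sticky_chain(4, 5, 500, seed = s)
    P <- transition_matrix(z)
    live <- !attr(P, "terminal")
    expect_true(all(abs(rowSums(P[live, , drop = FALSE]) - 1) < 1e-10))
  }
})

test_that("identity thresholds keep the full graph; harsh ones empty it", {
  z <- sample_sticky_chain(4, 5, 400, seed = 2)
  u <- usages(z)
  P <- transition_matrix(z)
  full <- build_state_map(u, P, 0, 0)
  expect_equal(sort(full$nodes$syllable), sort(u$syllable))
  expect_equal(nrow(full$edges), sum(P > 0))
  expect_warning(empty <- build_state_map(u, P, min_usage = 1.1),
                 "empty")
  expect_equal(nrow(empty$nodes), 0)
  # thresholded edges are a subset of the full graph's
  thr <- build_state_map(u, P, 0, 0.2)
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(thr$edges) %in% key(full$edges)))
  expect_equal(sum(full$nodes$usage), 1, tolerance = 1e-10)
})

test_that("identical conditions produce zero effects and no flags", {
  sessions <- lapply(1:3, function(s)
    label_sequence(sample_sticky_chain(5, 6, 500, seed = s), fps = 30))
  cmp <- compare_usages(sessions, sessions, n_permutations = 200, seed = 1)
  expect_true(all(cmp$effect == 0))
  expect_false(any(cmp$significant))
})

test_that("one session per group is rejected with advice", {
  a <- list(label_sequence(rep(1L, 10), 30))
  expect_error(compare_usages(a, a), "2 sessions")
})

test_that("a doubled-usage syllable is detected with high power", {
  make_session <- function(probs, seed) {
    set.seed(seed)
    z <- sample(seq_along(probs), 400, replace = TRUE, prob = probs)
    label_sequence(rep(z, each = 5), fps = 30)  # dwell 5 frames
  }
  p_a <- rep(0.1, 10)
  p_b <- p_a; p_b[3] <- 0.2; p_b <- p_b / sum(p_b)
  hits <- vapply(1:20, function(rep_i) {
    la <- lapply(1:10, function(s) make_session(p_a, 1000 * rep_i + s))
    lb <- lapply(1:10, function(s) make_session(p_b, 2000 * rep_i + s))
    cmp <- compare_usages(la, lb, n_permutations = 400, fdr = 0.05,
                          seed = rep_i)
    cmp$significant[cmp$syllable == 3]
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("null p-values are calibrated (any-rejection rate near BH level)", {
  make_session <- function(seed) {
    set.seed(seed)
    z <- sample(1:8, 300, replace = TRUE)
    label_sequence(rep(z, each = 5), fps = 30)
  }
  any_hit <- vapply(1:100, function(rep_i) {
    la <- lapply(1:6, function(s) make_session(5000 * rep_i + s))
    lb <- lapply(1:6, function(s) make_session(9000 * rep_i + s))
    cmp <- compare_usages(la, lb, n_permutations = 200, fdr = 0.05,
                          seed = rep_i)
    any(cmp$significant)
  }, logical(1))
  # under the global null BH bounds the any-rejection rate by the level;
  # allow 3 binomial standard errors above it
  expect_lte(mean(any_hit), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("difference maps subtract edgewise with the absent-edge convention", {
  z_a <- c(1L, 1L, 2L, 2L, 1L)
  z_b <- c(1L, 3L, 1L, 3L, 1L)
  mk <- function(z) build_state_map(usages(z), transition_matrix(z))
  ma <- mk(z_a); mb <- mk(z_b)
  d <- difference_state_map(ma, mb)
  # edge 1->3 exists only in B with p = 1
  expect_equal(d$delta[d$from == 1 & d$to == 3], 1)
  # antisymmetry
  d_rev <- difference_state_map(mb, ma)
  merged <- merge(d, d_rev, by = c("from", "to"))
  expect_equal(merged$delta.x, -merged$delta.y)
  # identical maps differ nowhere above any positive threshold
  expect_equal(nrow(difference_state_map(ma, ma, min_abs_delta = 1e-9)), 0)
})

test_that("mismatched usage modes are rejected", {
  z <- c(1L, 2L, 1L, 2L)
  u1 <- usages(z); u2 <- usages(z, "instances")
  attr(u2, "usage_mode") <- "instances"
  m1 <- build_state_map(u1, transition_matrix(z))
  m2 <- build_state_map(u2, transition_matrix(z))
  m2$usage_mode <- "instances"
  expect_error(difference_state_map(m1, m2), "usage mode")
})

test_that("summaries are invariant to a CSV round trip of the labels", {
  z <- label_sequence(sample_sticky_chain(4, 6, 800, seed = 31), fps = 30)
  path <- tempfile(fileext = ".csv")
  write_labels_csv(z, path)
  z2 <- read_labels_csv(path)
  expect_identical(z2$labels, z$labels)
  expect_equal(usages(z2), usages(z))
  expect_equal(durations(z2), durations(z))
  expect_equal(transition_matrix(z2), transition_matrix(z))
})
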