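toy_matrix <- function() {
  # 6 genes x 4 cells; hand-designed detection pattern
  m <- matrix(c(1, 0, 2, 0,    # g1: 2 cells
                1, 1, 1, 0,    # g2: 3 cells
                0, 0, 0, 0,    # g3: 0 cells
                3, 1, 1, 1,    # g4: 4 cells
                0, 2, 1, 1,    # g5: 3 cells
                1, 1, 0, 1),   # g6: 3 cells
              nrow = 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:4)))
  m
}

test_that("matrix filtering applies both thresholds in a single pass", {
  m <- toy_matrix()
  # detected genes per cell: c1 = 4, c2 = 4, c3 = 4, c4 = 3
  f <- filter_matrix(m, min_cells = 3, min_features = 4)
  expect_equal(rownames(f), c("g2", "g4", "g5", "g6"))
  expect_equal(colnames(f), c("c1", "c2", "c3"))
  # gene detected in 2 cells removed, in 3 retained
  expect_false("g1" %in% rownames(f))
  expect_true("g2" %in% rownames(f))
  # single pass: cell criterion counts genes of the INPUT matrix, so c1-c3
  # keep 4 detected features even though g1/g3 get dropped
  expect_error(filter_matrix(matrix(0, 2, 2,
                                    dimnames = list(c("a", "b"), NULL))),
               "every gene")
})

test_that("filtering matches exhaustive enumeration and is idempotent", {
  m <- toy_matrix()
  # oracle: brute-force loops over the input matrix
  keep_g <- vapply(rownames(m),
                   function(g) sum(m[g, ] >= 1) >= 3, logical(1))
  keep_c <- vapply(colnames(m),
                   function(cc) sum(m[, cc] >= 1) >= 4, logical(1))
  f <- filter_matrix(m, 3, 4)
  expect_identical(rownames(f), rownames(m)[keep_g])
  expect_identical(colnames(f), colnames(m)[keep_c])

  # single-pass filtering reaches a fixed point when the removed genes and
  # cells only co-occur with each other; such a matrix filters idempotently
  m2 <- matrix(0, 5, 5, dimnames = list(paste0("g", 1:5), paste0("c", 1:5)))
  m2[2:5, 1:4] <- 1          # stable dense block
  m2[1, 5] <- 1              # g1 detected only in c5, c5 has only g1
  f2 <- filter_matrix(m2, 3, 4)
  expect_identical(filter_matrix(f2, 3, 4), f2)
  expect_identical(rownames(f2), paste0("g", 2:5))
})

test_that("filtering works identically on sparse matrices", {
  m <- toy_matrix()
  sp <- Matrix::Matrix(m, sparse = TRUE)
  f <- filter_matrix(sp, 3, 4)
  expect_identical(as.matrix(f), filter_matrix(m, 3, 4))
})

test_that("single-copy positivity calls", {
  m <- toy_matrix()
  expect_identical(positive_cells(m, "g3"), character())
  expect_identical(positive_cells(m, "g4"), paste0("c", 1:4))
  expect_identical(positive_cells(m, "g1"), c("c1", "c3"))
  expect_error(positive_cells(m, "g9"), "not found")
  # near-match listing for typos
  rownames(m)[1] <- "Stard5"
  expect_error(positive_cells(m, "Star5"), "Stard5")
})

test_that("co-expression fractions for degenerate and hand-counted cases", {
  m <- toy_matrix()
  # disjoint: g1+ = {c1, c3}, g5+ = {c2, c3, c4} -> overlap {c3}
  expect_equal(coexpression_fraction(m, "g1", "g5", "a"), 50)
  expect_equal(coexpression_fraction(m, "g1", "g5", "b"), 100 / 3)
  # identical sets
  expect_equal(coexpression_fraction(m, "g2", "g2", "a"), 100)
  # disjoint sets
  m2 <- matrix(c(1, 0, 0, 1), nrow = 2,
               dimnames = list(c("x", "y"), c("c1", "c2")))
  expect_equal(coexpression_fraction(m2, "x", "y", "a"), 0)
  expect_error(coexpression_fraction(m, "g3", "g1", "a"), "no positive")
})

test_that("co-expression on simulated counts converges to joint/marginal", {
  cfg <- count_sim_config(n_genes = 4, n_cells = 50000,
                          marker_names = c("A", "B"),
                          positivity_probs = c(A = 0.3, B = 0.4),
                          joint_probs = data.frame(marker_a = "A",
                                                   marker_b = "B",
                                                   p_joint = 0.12),
                          seed = 31)
  sim <- simulate_count_matrix(cfg)
  # fraction of B+ cells that are A+: 0.12 / 0.4 = 30%
  expect_equal(coexpression_fraction(sim$counts, "A", "B", "b"), 30,
               tolerance = 1 / 30)
})

test_that("fish proportions match hand-tabulated contingency counts", {
  cells <- data.frame(
    animal = rep(c("m1", "m2"), each = 10),
    section = rep(c("s1", "s2"), times = 10),
    roi = "medNAcSh_dorsal",
    axis_position = rep(c("rostral", "caudal"), each = 5, times = 2),
    drd1_pos = rep(c(TRUE, TRUE, FALSE, TRUE, FALSE), 4),
    drd2_pos = rep(c(FALSE, FALSE, TRUE, FALSE, TRUE), 4),
    probe_pos = c(TRUE, FALSE, TRUE, TRUE, FALSE,
                  TRUE, TRUE, TRUE, FALSE, TRUE,
                  FALSE, FALSE, TRUE, TRUE, FALSE,
                  TRUE, TRUE, FALSE, TRUE, TRUE))
  got <- fish_proportions(cells)
  # oracle for one group cell: rostral, animal m1: sections s1 {rows 1,3,5},
  # s2 {rows 2,4} etc, computed by explicit loops
  oracle_group <- function(axis) {
    per_animal <- sapply(c("m1", "m2"), function(a) {
      d <- cells[cells$animal == a & cells$axis_position == axis, ]
      mean(sapply(split(d, d$section), function(s) {
        100 * sum(s$drd1_pos & s$probe_pos) / sum(s$drd1_pos)
      }))
    })
    mean(per_animal)
  }
  expect_equal(got$pct_probe_in_drd1[got$axis_position == "rostral"],
               oracle_group("rostral"))
  expect_equal(got$pct_probe_in_drd1[got$axis_position == "caudal"],
               oracle_group("caudal"))
  expect_true(all(got$pct_probe_in_drd1 >= 0 & got$pct_probe_in_drd1 <= 100))
})

test_that("fish proportions are invariant to row order and animal duplication", {
  withr::with_seed(14, {
    cells <- data.frame(
      animal = sample(c("m1", "m2", "m3"), 60, replace = TRUE),
      section = sample(c("s1", "s2"), 60, replace = TRUE),
      roi = sample(c("medNAcSh_dorsal", "core"), 60, replace = TRUE),
      axis_position = sample(c("rostral", "caudal"), 60, replace = TRUE),
      drd1_pos = sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(.7, .3)),
      drd2_pos = sample(c(TRUE, FALSE), 60, replace = TRUE),
      probe_pos = sample(c(TRUE, FALSE), 60, replace = TRUE))
  })
  base <- fish_proportions(cells)
  shuffled <- fish_proportions(cells[sample(nrow(cells)), ])
  expect_equal(base, shuffled)
  # duplicating an entire animal's rows leaves animal-level means unchanged
  dup <- rbind(cells, transform(cells[cells$animal == "m2", ]))
  expect_equal(fish_proportions(dup)$pct_probe_in_drd1,
               base$pct_probe_in_drd1)
})

test_that("groups without receptor-positive cells are flagged undefined", {
  cells <- data.frame(animal = "m1", section = "s1", roi = "core",
                      axis_position = "rostral",
                      drd1_pos = FALSE, drd2_pos = TRUE, probe_pos = TRUE)
  got <- fish_proportions(cells)
  expect_true(is.nan(got$pct_probe_in_drd1))
  expect_equal(got$pct_probe_in_drd2, 100)
})

test_that("all probe-negative tables give 0% wherever defined", {
  cells <- data.frame(animal = rep("m1", 8), section = "s1",
                      roi = "latNAcSh",
                      axis_position = rep(c("rostral", "caudal"), 4),
                      drd1_pos = TRUE, drd2_pos = TRUE, probe_pos = FALSE)
  got <- fish_proportions(cells)
  expect_equal(got$pct_probe_in_drd1, c(0, 0))
  expect_equal(got$pct_probe_in_drd2, c(0, 0))
})

test_that("optical density subtracts background and averages hemispheres", {
  res <- optical_density(c(10, 20), 5)
  expect_equal(res$corrected, c(5, 15))
  expect_equal(res$value, 10)
  expect_false(res$single_hemisphere)
  # roi equal to background
  expect_equal(optical_density(c(5, 5), 5)$value, 0)
  # background above roi: negative preserved
  expect_equal(optical_density(c(3, 4), 5)$value, -1.5)
  expect_warning(one <- optical_density(7, 5), "single hemisphere")
  expect_equal(one$value, 2)
  expect_true(one$single_hemisphere)
  expect_error(optical_density(numeric(), 5), "roi_means")
})
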