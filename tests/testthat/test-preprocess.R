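mk <- function(vals) {
  m <- matrix(vals, nrow = 1)
  rownames(m) <- "S1"
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

test_that("ratio normalization divides by the per-sample observed total", {
  expect_equal(unname(drop(normalize_to_ratio(mk(c(2, 3, 5))))),
               c(0.2, 0.3, 0.5))
  expect_equal(unname(drop(normalize_to_ratio(mk(7)))), 1)
  # missing cells stay missing and the rest renormalizes over observed cells
  expect_equal(unname(drop(normalize_to_ratio(mk(c(1, NA, 3))))),
               c(0.25, NA, 0.75))
})

test_that("ratio normalization is idempotent and rows sum to one", {
  set.seed(3)
  x <- matrix(rlnorm(60), 6, 10,
              dimnames = list(paste0("S", 1:6), paste0("f", 1:10)))
  x[2, 4] <- NA
  r1 <- normalize_to_ratio(x)
  expect_equal(unname(rowSums(r1, na.rm = TRUE)), rep(1, 6), tolerance = 1e-12)
  expect_equal(as_matrix_plain(normalize_to_ratio(r1)), as_matrix_plain(r1),
               tolerance = 1e-12)
})

test_that("all-zero samples are rejected by name", {
  x <- rbind(S1 = c(f1 = 1, f2 = 2), S2 = c(0, 0))
  expect_error(normalize_to_ratio(x), "S2")
})

test_that("duplicate wells average; a missing member passes the other through", {
  x <- rbind(w1 = c(f1 = 4, f2 = 2), w2 = c(6, 2), w3 = c(4, NA),
             w4 = c(NA, NA))
  map <- data.frame(replicate_id = c("w1", "w2", "w3", "w4"),
                    sample_id = c("A", "A", "B", "B"))
  out <- average_duplicates(x, map)
  expect_equal(unname(out["A", ]), c(5, 2))
  expect_equal(unname(out["B", "f1"]), 4)     # single-observation rule
  expect_true(is.na(out["B", "f2"]))          # both missing stays missing
  expect_error(average_duplicates(x,
    data.frame(replicate_id = "nope", sample_id = "A")), "nope")
})

test_that("outlier exclusion matches the hand-computed single-pass rule", {
  # SD inflated by the outlier itself: (1,1,1,1,10) has mean 2.8, SD 4.02,
  # so |10 - 2.8| = 7.2 < 2 * 4.02 and nothing is excluded at k_sd = 2
  x <- matrix(c(1, 1, 1, 1, 10), 5, 1,
              dimnames = list(paste0("S", 1:5), "f"))
  md <- data.frame(sample_id = paste0("S", 1:5), grp = "A")
  res <- exclude_outliers(x, md, "grp", k_sd = 2)
  expect_equal(nrow(res$qc$excluded_cells), 0)

  # in a group of 5 a lone point can never exceed 2 sample SDs
  # (max |z| = (n - 1) / sqrt(n) < 2), so a larger group is needed:
  x2 <- matrix(c(rep(1, 9), 100), 10, 1,
               dimnames = list(paste0("S", 1:10), "f"))
  md2 <- data.frame(sample_id = paste0("S", 1:10), grp = "A")
  res2 <- exclude_outliers(x2, md2, "grp", k_sd = 2)
  expect_equal(res2$qc$excluded_cells$sample_id, "S10")
  expect_true(is.na(res2$table["S10", "f"]))

  # constant groups exclude nothing
  x3 <- matrix(5, 4, 1, dimnames = list(paste0("S", 1:4), "f"))
  md3 <- data.frame(sample_id = paste0("S", 1:4), grp = "A")
  expect_equal(nrow(exclude_outliers(x3, md3, "grp", 2)$qc$excluded_cells), 0)
})

test_that("a value exactly at mean + k_sd * SD is retained (strict rule)", {
  x <- matrix(c(-1, -1, 1, 1, 6), 5, 1,
              dimnames = list(paste0("S", 1:5), "f"))
  md <- data.frame(sample_id = paste0("S", 1:5), grp = "A")
  # k_sd chosen so the extreme point sits exactly on the threshold
  k_exact <- (x[5, 1] - mean(x)) / sd(x)
  res <- exclude_outliers(x, md, "grp", k_sd = k_exact)
  expect_equal(nrow(res$qc$excluded_cells), 0)
  # and it is excluded as soon as k_sd dips below that exact multiple
  res2 <- exclude_outliers(x, md, "grp", k_sd = k_exact * 0.999)
  expect_equal(nrow(res2$qc$excluded_cells), 1)
})

test_that("k_sd = 3 never removes more cells than k_sd = 2", {
  set.seed(8)
  for (rep in 1:20) {
    x <- matrix(rnorm(40, sd = runif(1, 0.5, 3)), 20, 2,
                dimnames = list(paste0("S", 1:20), c("a", "b")))
    md <- data.frame(sample_id = paste0("S", 1:20),
                     grp = rep(c("A", "B"), each = 10))
    n2 <- nrow(exclude_outliers(x, md, "grp", 2)$qc$excluded_cells)
    n3 <- nrow(exclude_outliers(x, md, "grp", 3)$qc$excluded_cells)
    expect_lte(n3, n2)
  }
})

test_that("control stability ranks by combined inter/intra-group variability", {
  md <- data.frame(sample_id = paste0("S", 1:8),
                   group = rep(c("case", "control"), each = 4))
  # constant candidate: stability 0, ranked first
  cq <- cbind(c1 = rep(25, 8),
              c2 = c(20, 20, 20, 20, 22, 22, 22, 22),   # between-group only
              c3 = rnorm(8, 25, 3))
  rownames(cq) <- md$sample_id
  st <- control_stability(cq, md, c("c1", "c2", "c3"))
  expect_equal(st$control_id[1], "c1")
  expect_equal(st$stability[st$control_id == "c1"], 0)
  # group means 20 and 22 with zero within-group variance: s = sqrt(var({20,22})) = sqrt(2)
  expect_equal(st$stability[st$control_id == "c2"], sqrt(2))
  expect_error(control_stability(cq, md, c("c1", "missing")), "missing")
})

test_that("the tighter of two equal-mean candidates ranks first", {
  set.seed(5)
  md <- data.frame(sample_id = paste0("S", 1:40),
                   group = rep(c("case", "control"), each = 20))
  base <- rnorm(40)
  cq <- cbind(tight = 25 + base, loose = 25 + 2 * base)
  rownames(cq) <- md$sample_id
  st <- control_stability(cq, md, c("tight", "loose"))
  expect_equal(st$control_id[1], "tight")
  expect_equal(attr(st, "chosen"), "tight")
})

test_that("delta Cq subtracts the control and drops its column", {
  cq <- rbind(S1 = c(miR1 = 28, miR2 = 24, ctrl = 25),
              S2 = c(30, 26, 27))
  out <- delta_cq(cq, "ctrl")
  expect_equal(unname(out$table["S1", ]), c(3, -1))
  expect_equal(unname(out$table["S2", ]), c(3, -1))
  expect_false("ctrl" %in% colnames(out$table))
  expect_error(delta_cq(cq, "absent"), "absent")
})

test_that("delta Cq is invariant to per-sample shifts; the control maps to zero", {
  set.seed(6)
  cq <- matrix(rnorm(30, 25, 2), 10, 3,
               dimnames = list(paste0("S", 1:10), c("a", "b", "ctrl")))
  d1 <- delta_cq(cq, "ctrl")$table
  shifted <- cq + rnorm(10)            # recycles per row: adds c_i to sample i
  d2 <- delta_cq(shifted, "ctrl")$table
  expect_equal(as_matrix_plain(d1), as_matrix_plain(d2), tolerance = 1e-12)
})

test_that("samples with a missing control Cq are dropped and logged", {
  cq <- rbind(S1 = c(m = 28, ctrl = 25), S2 = c(29, NA), S3 = c(27, 24))
  out <- delta_cq(cq, "ctrl")
  expect_equal(rownames(out$table), c("S1", "S3"))
  expect_equal(out$qc$dropped_samples, "S2")
})
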