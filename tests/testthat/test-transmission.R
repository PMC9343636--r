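mk_seed_groups <- function(pattern) {
  # pattern: OTU x 3 presence matrix; builds a table with 2 samples per group
  n <- nrow(pattern)
  m <- matrix(0L, n, 6)
  rownames(m) <- paste0("OTU", seq_len(n))
  colnames(m) <- paste0("g", rep(1:3, each = 2), "_", rep(1:2, 3))
  for (g in 1:3) m[pattern[, g] == 1, (2 * g - 1)] <- 5L
  m[1, ] <- m[1, ] + 1L  # keep all sample columns nonzero
  meta <- sample_meta(data.frame(
    sample_id = colnames(m), compartment = "Se",
    age_days = rep(c(120, 0, 141), each = 2),
    year = rep(c(2017, 2018, 2018), each = 2), site = "SW",
    bio_rep = rep(1:2, 3), tech_rep = 1))
  groups <- split(colnames(m), rep(1:3, each = 2))
  list(t = count_table(m), meta = meta, groups = unname(groups))
}

test_that("transmitted calls require detection in all three generations", {
  pat <- rbind(c(1, 1, 1), c(1, 0, 1), c(1, 1, 0), c(0, 1, 1), c(1, 1, 1))
  fx <- mk_seed_groups(pat)
  res <- detect_transmitted(fx$t, fx$meta, fx$groups)
  expect_equal(sum(res$status == "transmitted"), 2)
  expect_equal(sum(res$status == "transient"), 3)
  expect_setequal(names(res$status)[res$status == "transmitted"],
                  c("OTU1", "OTU5"))
  # partition invariant: statuses cover all seed OTUs
  expect_equal(length(res$status), 5)
})

test_that("detection rule boundary: group mean vs minimum count", {
  pat <- rbind(c(1, 1, 1), c(1, 1, 1))
  fx <- mk_seed_groups(pat)
  # OTU2 gets a single read in one replicate of group 2: mean > 0 but < 5
  m <- unclass(fx$t)
  m["OTU2", ] <- c(20L, 0L, 1L, 0L, 20L, 0L)
  t2 <- count_table(m)
  r_mean <- detect_transmitted(t2, fx$meta, fx$groups, "mean_gt_zero")
  r_min <- detect_transmitted(t2, fx$meta, fx$groups, "min_count", k = 5)
  expect_equal(unname(r_mean$status["OTU2"]), "transmitted")
  expect_equal(unname(r_min$status["OTU2"]), "transient")
})

test_that("generation group validation", {
  fx <- mk_seed_groups(rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_error(detect_transmitted(fx$t, fx$meta,
                                  list(fx$groups[[1]], fx$groups[[2]],
                                       character(0))), "empty")
  overlapping <- list(fx$groups[[1]], fx$groups[[2]],
                      c(fx$groups[[3]][1], fx$groups[[1]][1]))
  expect_error(detect_transmitted(fx$t, fx$meta, overlapping), "overlap")
})

test_that("succession classifier applies the slope/significance rule", {
  ages <- rep(c(76, 90, 106, 120, 141), each = 3)
  # exactly linear increase, zero noise -> Late
  up <- matrix(rep(0.001 * ages, 3), nrow = 3, byrow = TRUE)
  rownames(up) <- paste0("o", 1:3)
  colnames(up) <- paste0("s", seq_along(ages))
  res <- classify_succession(up, ages = ages)
  expect_true(all(res$mode == "Late"))
  # constant -> MidNoTrend with slope 0
  flat <- matrix(0.02, 2, length(ages),
                 dimnames = list(c("a", "b"), paste0("s", seq_along(ages))))
  resf <- classify_succession(flat, ages = ages)
  expect_true(all(resf$mode == "MidNoTrend"))
  expect_true(all(resf$slope == 0))
  # all-zero OTU flagged degenerate
  z <- rbind(zero = rep(0, length(ages)), up)
  colnames(z) <- paste0("s", seq_along(ages))
  resz <- classify_succession(z, ages = ages)
  expect_true(resz$degenerate[resz$otu_id == "zero"])
  expect_equal(resz$mode[resz$otu_id == "zero"], "MidNoTrend")
  # every OTU gets exactly one mode
  expect_true(all(resz$mode %in% c("Early", "MidNoTrend", "Late")))
  expect_error(classify_succession(up, ages = rep(c(90, 106), c(8, 7))),
               "three distinct timepoints")
})

test_that("parent seeds are excluded from the regression by default", {
  ages <- c(0, 0, 90, 90, 120, 120, 141, 141)
  # decreasing only because of a huge parent value at age 0
  y <- rbind(o1 = c(0.9, 0.9, 0.01, 0.012, 0.02, 0.022, 0.03, 0.028))
  colnames(y) <- paste0("s", 1:8)
  res <- classify_succession(y, ages = ages)         # progeny only: rising
  expect_equal(res$mode, "Late")
  res_in <- classify_succession(y, ages = ages, include_parent = TRUE)
  expect_equal(res_in$mode, "Early")
})

test_that("convergence trajectory decreases on interpolated compositions", {
  parent <- c(40, 30, 20, 10, 0, 0)
  far <- c(0, 0, 10, 20, 30, 40)
  ages <- c(76, 90, 106, 120, 141)
  cols <- list()
  for (i in seq_along(ages)) {
    w <- (i - 1) / (length(ages) - 1)
    prof <- round((1 - w) * far + w * parent) + 1
    for (r in 1:2) cols[[paste0("p", ages[i], "_", r)]] <- prof
  }
  m <- cbind(par1 = parent + 1, par2 = parent + 1, do.call(cbind, cols))
  rownames(m) <- paste0("o", 1:6)
  meta <- sample_meta(data.frame(
    sample_id = colnames(m), compartment = "Se",
    age_days = c(0, 0, rep(ages, each = 2)), year = 2018, site = "SW",
    bio_rep = rep(1:2, length(ages) + 1),
    tech_rep = rep(seq_len(length(ages) + 1), each = 2)))
  tr <- convergence_trajectory(count_table(m), meta)
  expect_true(all(diff(tr$per_age$median) < 0))
  # identical to parent at final age -> distance ~ 0
  expect_lt(tr$per_age$median[nrow(tr$per_age)], 0.05)
  # restricting to the full OTU set changes nothing
  tr_full <- convergence_trajectory(count_table(m), meta,
                                    restrict_to = paste0("o", 1:6))
  expect_equal(tr$distances$distance, tr_full$distances$distance)
})

test_that("core OTU prevalence boundaries and monotonicity", {
  m <- matrix(0L, 2, 10)
  m[1, 1:8] <- 1L; m[2, 1:7] <- 1L
  m[1, 9:10] <- 0L; m[2, 8] <- 0L
  m <- rbind(m, rep(1L, 10))
  rownames(m) <- c("in8", "in7", "all")
  colnames(m) <- paste0("s", 1:10)
  meta <- sample_meta(data.frame(
    sample_id = colnames(m), compartment = "Se", age_days = 90,
    year = 2018, site = "SW", bio_rep = 1:10, tech_rep = 1))
  cs <- core_otus(count_table(m, allow_zero_samples = FALSE), meta,
                  prevalence = 0.8)
  expect_true("in8" %in% cs$cores$Se)     # 8/10 at 0.8 is inclusive
  expect_false("in7" %in% cs$cores$Se)
  cs1 <- core_otus(count_table(m), meta, prevalence = 1.0)
  expect_equal(cs1$cores$Se, "all")
  # raising the threshold never adds members
  for (pr in c(0.5, 0.7, 0.9)) {
    lo <- core_otus(count_table(m), meta, prevalence = pr)$cores$Se
    hi <- core_otus(count_table(m), meta, prevalence = pr + 0.1)$cores$Se
    expect_true(all(hi %in% lo))
  }
  expect_error(core_otus(count_table(m), meta, prevalence = 0), "\\(0, 1]")
})

test_that("overlap summary matches brute-force set enumeration", {
  sets <- list(transmitted = c("a", "b", "c", "d"),
               Se = c("b", "c", "e"),
               S = c("c", "d", "e", "f"))
  ov <- overlap_summary(sets)
  count_region <- function(inT, inSe, inS) {
    u <- unique(unlist(sets))
    sum(vapply(u, function(x)
      (x %in% sets$transmitted) == inT && (x %in% sets$Se) == inSe &&
        (x %in% sets$S) == inS, logical(1)))
  }
  for (r in seq_len(nrow(ov)))
    expect_equal(ov$count[r],
                 count_region(ov$transmitted[r], ov$Se[r], ov$S[r]))
  # disjoint sets intersect in 0
  ov2 <- overlap_summary(list(A = c("x", "y"), B = c("z")))
  expect_equal(ov2$count[ov2$A & ov2$B], 0)
  # subset: transmitted-only region empty when transmitted is inside core
  ov3 <- overlap_summary(list(tr = c("a"), core = c("a", "b")))
  expect_equal(ov3$count[ov3$tr & !ov3$core], 0)
})
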