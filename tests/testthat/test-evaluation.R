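test_that("mutation tables read with exact fields and token parsing", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("pdb_id,chain,mutation,temperature,ph,exp_ddg",
               "1ABC,A,D89E,25,7.0,-1.2",
               "2XYZ,B,K10AW,24.5,6.9,0.8",
               "1ABC,A,G5V,37,4.0,-3.1"), f)
  rec <- read_mutation_table(f)
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$pdb_id, c("1ABC", "2XYZ", "1ABC"))
  expect_identical(rec$wt_res, c("D", "K", "G"))
  expect_identical(rec$position, c(89L, 10L, 5L))
  expect_identical(rec$insert, c("", "A", ""))
  expect_identical(rec$mut_res, c("E", "W", "V"))
  expect_identical(rec$exp_ddg, c(-1.2, 0.8, -3.1))
  expect_identical(rec$direction, rep("forward", 3))
})

test_that("malformed rows go to the rejects report, not the void", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("pdb_id,chain,mutation,temperature,ph,exp_ddg",
               "1ABC,A,D89E,25,7.0,-1.2",
               "1ABC,A,notamutation,25,7.0,-1.2"), f)
  rec <- read_mutation_table(f)
  expect_identical(nrow(rec), 1L)
  rej <- attr(rec, "rejects")
  expect_identical(nrow(rej), 1L)
  expect_identical(rej$mutation, "notamutation")
  f2 <- tempfile(fileext = ".csv")
  writeLines("pdb_id,chain,mutation", f2)
  expect_error(read_mutation_table(f2), "missing mandatory column")
  expect_error(read_mutation_table(tempfile()), "cannot read")
})

test_that("generated tables round-trip through the reader", {
  f <- tempfile(fileext = ".csv")
  tab <- make_benchmark_table(40, seed = 35, file = f)
  rec <- read_mutation_table(f)
  expect_identical(nrow(rec), 40L)
  expect_identical(rec$mutation, tab$mutation)
  expect_equal(rec$temperature, tab$temperature)
  expect_equal(rec$ph, tab$ph)
  expect_equal(rec$exp_ddg, tab$exp_ddg)
})

test_that("condition filters keep exactly the in-window rows", {
  rec <- data.frame(temperature = c(25, 24, 26, 23.9, 26.1, NA, 25),
                    ph = c(7.0, 6.8, 7.2, 7.0, 7.0, 7.0, NA))
  kept <- filter_conditions(rec)
  expect_identical(rownames(kept), c("1", "2", "3"))  # closed intervals
  # infinite ranges drop only missing values
  all_kept <- filter_conditions(rec, c(-Inf, Inf), c(-Inf, Inf))
  expect_identical(nrow(all_kept), 5L)
  # seeded synthetic table vs both brute force and generator bookkeeping
  tab <- make_benchmark_table(100, seed = 36)
  kept2 <- filter_conditions(tab)
  brute <- which(!is.na(tab$temperature) & !is.na(tab$ph) &
                   tab$temperature >= 24 & tab$temperature <= 26 &
                   tab$ph >= 6.8 & tab$ph <= 7.2)
  expect_identical(as.integer(rownames(kept2)), brute)
  expect_identical(nrow(kept2), sum(attr(tab, "in_range")))
})

test_that("metrics agree with textbook oracles", {
  set.seed(37)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50)
  expect_equal(pearson(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(rmse(x, y), oracle_rmse(x, y), tolerance = 1e-12)
  expect_equal(pearson(x, x), 1, tolerance = 1e-12)
  expect_equal(rmse(x, x), 0, tolerance = 0)
  expect_equal(pearson(x, -x), -1, tolerance = 1e-12)
  f <- rnorm(30); r <- rnorm(30)
  expect_equal(antisymmetry(f, r), oracle_pearson(f, r), tolerance = 1e-12)
  expect_equal(bias(f, r), oracle_bias(f, r), tolerance = 1e-12)
  expect_equal(antisymmetry(f, -f), -1, tolerance = 1e-12)
  expect_equal(antisymmetry(f, f), 1, tolerance = 1e-12)
  expect_identical(bias(f, -f), 0)
  expect_identical(bias(rep(1, 5), rep(1, 5)), 1)
  expect_error(pearson(x, y[-1]), "equal-length")
  expect_error(pearson(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(bias(numeric(0), numeric(0)), "non-empty")
})

test_that("pearson is affine-invariant and rmse translation-covariant", {
  set.seed(38)
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(pearson(3 * x + 2, y), pearson(x, y), tolerance = 1e-12)
  expect_equal(pearson(x, 0.5 * y - 7), pearson(x, y), tolerance = 1e-12)
  expect_equal(rmse(x + 3, y + 3), rmse(x, y), tolerance = 1e-12)
})

test_that("evaluation summaries bundle the metric set", {
  set.seed(39)
  calc <- rnorm(20); exp_v <- calc + rnorm(20, sd = 0.5)
  s <- evaluation_summary(calc, exp_v, fwd = calc, rev = -calc)
  expect_identical(s$n, 20L)
  expect_equal(s$pcc, oracle_pearson(calc, exp_v), tolerance = 1e-12)
  expect_equal(s$rmse, oracle_rmse(calc, exp_v), tolerance = 1e-12)
  expect_equal(s$antisymmetry, -1, tolerance = 1e-12)
  expect_identical(s$bias, 0)
})

test_that("parameter scans report per-point metrics and prediction rates", {
  pairs <- lapply(40:44, function(seed) make_mutant_pair(18, seed = seed))
  structures <- setNames(lapply(pairs, `[[`, "wt"),
                         vapply(pairs, function(p) p$wt$structure_id, ""))
  records <- do.call(rbind, lapply(pairs, function(p)
    data.frame(pdb_id = p$wt$structure_id, chain = "A",
               mutation = paste0(p$spec$wt_res, p$spec$position, p$spec$mut_res),
               temperature = 25, ph = 7, exp_ddg = rnorm(1),
               wt_res = p$spec$wt_res, position = p$spec$position,
               insert = "", mut_res = p$spec$mut_res)))
  one <- parameter_scan(records, structures, MJ, rc_grid = 9, mode_grid = 10)
  expect_identical(nrow(one), 1L)
  direct <- lapply(seq_len(nrow(records)), function(r)
    compute_ddg(structures[[records$pdb_id[r]]],
                mutation_spec("A", records$wt_res[r], records$position[r],
                              records$mut_res[r]), MJ))
  expect_equal(one$pct_predictions,
               100 * mean(vapply(direct, `[[`, "", "status") == "computed"))
  expect_identical(one$n_failed, 0L)
  # a 2x2 grid equals independent per-point runs
  grid <- parameter_scan(records, structures, MJ, rc_grid = c(8, 9),
                         mode_grid = c(5, 10))
  expect_identical(nrow(grid), 4L)
  expect_true(all(diff(grid$pcc) <= 1e-12))  # sorted by pcc descending
  pt <- parameter_scan(records, structures, MJ, rc_grid = 8, mode_grid = 5)
  row <- grid[grid$rc == 8 & grid$n_modes == 5, ]
  expect_equal(row$pcc, pt$pcc)
  expect_equal(row$rmse, pt$rmse)
  # no-contact structures give zero percent predictions
  flat <- make_toy_chain(12, seed = 45, geometry = "extended", spacing = 10)
  rec2 <- data.frame(pdb_id = flat$structure_id, chain = "A",
                     mutation = paste0(flat$resid[5], 5,
                                       setdiff(c("A", "G"), flat$resid[5])[1]),
                     temperature = 25, ph = 7, exp_ddg = -1,
                     wt_res = flat$resid[5], position = 5L, insert = "",
                     mut_res = setdiff(c("A", "G"), flat$resid[5])[1])
  z <- parameter_scan(rec2, setNames(list(flat), flat$structure_id), MJ,
                      rc_grid = 9, mode_grid = 10)
  expect_identical(z$pct_predictions, 0)
})
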