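test_that("build_comparison lays out estimates, SEs and stars", {
  # published age-model row: rape coefficient across the three columns
  nms <- c("(Intercept)", "sv_type=rape")
  res_A <- fake_reg(stats::setNames(c(40.074, -0.405), nms), c(0.456, 0.298),
                    n = 6102)
  res_B <- fake_reg(stats::setNames(c(39.097, -1.949), nms), c(1.059, 0.708),
                    n = 1232)
  res_S <- fake_reg(stats::setNames(c(38.591, -1.761), nms), c(1.368, 0.683),
                    n = 6102)
  comp <- build_comparison(res_A, res_B, res_S)
  txt <- format(comp)
  # non-significant recipient cell carries no stars; donor and synthetic do
  expect_match(txt, "-0\\.405 ")
  expect_match(txt, "-1\\.949\\*\\*")
  expect_match(txt, "-1\\.761\\*\\*")
  # SEs in brackets beneath the estimates
  expect_match(txt, "\\(0\\.298\\)")
  expect_match(txt, "\\(0\\.708\\)")
  # footer carries per-column n
  expect_match(txt, "6102")
  expect_match(txt, "1232")
  # identical inputs give three equal columns
  same <- build_comparison(res_B, res_B, res_B)
  expect_equal(same$table$A_original_estimate, same$table$synthetic_estimate)
  # predictor mismatch is an alignment error
  bad <- fake_reg(c(other = 1), 1)
  expect_error(build_comparison(res_A, bad, res_S), "alignment error")
  # two-column variant for targets absent from the recipient
  two <- build_comparison(NULL, res_B, res_S)
  expect_equal(two$columns, c("B_donor", "synthetic"))
})

test_that("comparison CSV rendering is lossless", {
  set.seed(61)
  nms <- c("(Intercept)", "x", "g=q")
  mk <- function() fake_reg(stats::setNames(rnorm(3), nms),
                            abs(rnorm(3)) + 0.01, n = 77)
  comp <- build_comparison(mk(), mk(), mk())
  path <- tempfile(fileext = ".csv")
  write_comparison(comp, path)
  back <- read_comparison(path)
  for (cl in comp$columns) {
    expect_identical(back$table[[paste0(cl, "_estimate")]],
                     comp$table[[paste0(cl, "_estimate")]])
    expect_identical(back$table[[paste0(cl, "_se")]],
                     comp$table[[paste0(cl, "_se")]])
    expect_equal(back$table[[paste0(cl, "_stars")]],
                 comp$table[[paste0(cl, "_stars")]])
  }
  expect_equal(back$n, comp$n, ignore_attr = TRUE)
})

test_that("concordance counts signs, stars and flips", {
  nms <- paste0("b", 1:10)
  est <- stats::setNames(c(1, -2, 3, -4, 5, -6, 7, -8, 9, -10), nms)
  se <- rep(0.1, 10)
  res_B <- fake_reg(est, se)
  # identical results: full agreement, no flips
  same <- concordance(res_B, res_B)
  expect_equal(same$sign_agreement, 1.0)
  expect_equal(same$significance_agreement, 1.0)
  expect_length(same$flips, 0)
  expect_equal(same$mean_abs_relative_diff, 0)
  # one sign flip out of 10
  est2 <- est
  est2["b3"] <- -est2["b3"]
  flipped <- concordance(res_B, fake_reg(est2, se))
  expect_equal(flipped$sign_agreement, 0.9)
  # star-category change is recorded as a flip
  se3 <- se
  se3[1] <- 10                                   # b1 becomes non-significant
  drop1 <- concordance(res_B, fake_reg(est, se3))
  expect_true("b1" %in% drop1$flips)
  # truth adds bias/rmse
  truth <- outcome_model(list(outcome = "y", family = "gaussian",
                              beta = as.list(est), sigma2 = 1))
  with_truth <- concordance(res_B, fake_reg(est + 0.5, se), truth = truth)
  expect_equal(with_truth$bias, 0.5, tolerance = 1e-12)
  expect_equal(with_truth$rmse, 0.5, tolerance = 1e-12)
})

test_that("run_pipeline executes end-to-end and is manifest-reproducible", {
  out1 <- tempfile("pipe1_")
  cfg <- list(mode = "synthetic", profile_A = "rcew", profile_B = "csew",
              n_A = 250, n_B = 200, outcome = "age", m = 3, maxit = 2,
              seed = 77, out_dir = out1)
  res <- suppressMessages(run_pipeline(cfg))
  expect_true(file.exists(file.path(out1, "comparison.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "concordance.json")))
  expect_true(file.exists(file.path(out1, "fused", "fused_001.csv")))
  expect_equal(res$fused$n, 250)
  expect_equal(length(res$fused$datasets), 3)
  # the three-column table is present with the synthetic column pooled
  expect_equal(res$comparison$columns,
               c("A_original", "B_donor", "synthetic"))
  # manifest reproducibility: re-running from the stored config reproduces
  # the comparison table bit-identically
  man <- jsonlite::read_json(file.path(out1, "manifest.json"),
                             simplifyVector = TRUE)
  out2 <- tempfile("pipe2_")
  cfg2 <- man$config
  cfg2$out_dir <- out2
  suppressMessages(run_pipeline(cfg2))
  expect_identical(readLines(file.path(out2, "comparison.csv")),
                   readLines(file.path(out1, "comparison.csv")))
  # seed change alters imputations but not the observed donor column
  cfg3 <- cfg
  cfg3$out_dir <- tempfile("pipe3_")
  cfg3$seed <- 78
  res3 <- suppressMessages(run_pipeline(cfg3))
  expect_false(identical(res3$pooled$q_bar, res$pooled$q_bar))
})

test_that("direction-swapped pipeline exchanges donor and recipient roles", {
  out <- tempfile("swap_")
  cfg <- list(mode = "synthetic", n_A = 180, n_B = 150, outcome = "age",
              m = 2, maxit = 1, seed = 5, direction_swapped = TRUE,
              out_dir = out)
  res <- suppressMessages(run_pipeline(cfg))
  # recipient is now the survey-like dataset: fused size = n_B
  expect_equal(res$fused$n, 150)
  expect_true(res$manifest$direction_swapped)
})

test_that("csv-mode pipeline fuses harmonized files from disk", {
  r <- make_fusion_scenario(mini_scenario(n_A = 60, n_B = 60, seed = 44))
  dirp <- tempfile("csvmode_")
  dir.create(dirp)
  A_csv <- file.path(dirp, "A.csv"); B_csv <- file.path(dirp, "B.csv")
  write_harmonized(r$A, A_csv)
  write_harmonized(r$B, B_csv)
  out <- file.path(dirp, "out")
  res <- suppressMessages(run_pipeline(list(
    mode = "csv", A_csv = A_csv, B_csv = B_csv, target = "y",
    comparison_vector = c("x", "age", "k"), family = "ols",
    m = 2, maxit = 1, seed = 3, out_dir = out)))
  expect_equal(res$fused$n, 60)
  # no recipient-original column: the target never existed in A
  expect_equal(res$comparison$columns, c("B_donor", "synthetic"))
})

test_that("the CLI dispatches simulate and rejects unknown commands", {
  dirp <- tempfile("cli_")
  dir.create(dirp)
  out_csv <- file.path(dirp, "sim.csv")
  suppressMessages(lookalike_cli(c("simulate", "--profile", "csew",
                                   "--n", "50", "--seed", "4",
                                   "--out", out_csv)))
  expect_true(file.exists(out_csv))
  tab <- read_harmonized(out_csv)
  expect_equal(nrow(tab$data), 50)
  expect_error(lookalike_cli("frobnicate"), "unknown command")
  expect_output(lookalike_cli(character(0)), "usage: lookalike")
})
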