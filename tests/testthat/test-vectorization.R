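test_that("weight normalization divides cortisol by 10 and DHEAS by 100", {
  p <- test_panel()
  w <- weight_normalize(p)
  expect_equal(w[["cortisol"]], p[["cortisol"]] / 10)
  expect_equal(w[["DHEAS"]], p[["DHEAS"]] / 100)
  others <- setdiff(steroid_analytes(), c("cortisol", "DHEAS"))
  expect_equal(w[others], p[others])
  # input panel untouched
  expect_equal(p[["cortisol"]], 100)

  # divisors compound: re-application is refused unless forced
  expect_error(weight_normalize(w), "already")
  ww <- weight_normalize(w, force = TRUE)
  expect_equal(ww[["cortisol"]], p[["cortisol"]] / 100)

  bad <- p; bad["cortisol"] <- NA
  expect_error(weight_normalize(bad), "cortisol")
})

test_that("percent vector normalizes to 100 and carries the total at m/z 1000", {
  p <- test_panel()
  v <- percent_vector(p)
  expect_s3_class(v, "concentration_vector")
  expect_equal(sum(v$cn), 100, tolerance = 1e-9)
  expect_equal(v$cv, sum(p))
  expect_equal(v$virtual_mz, 1000)
  expect_true(all(v$cn >= 0))

  # global scaling: percentages unchanged, total scales proportionally
  v3 <- percent_vector(test_panel(scale = 3))
  expect_equal(v3$cn, v$cn)
  expect_equal(v3$cv, 3 * v$cv)

  # concentrated panels: single analyte takes 100%, a 1:3 split is 25/75
  zeros <- steroid_panel(setNames(rep(0, 10), steroid_analytes()))
  one <- zeros; one["testosterone"] <- 7
  expect_equal(percent_vector(one)$cn[match("testosterone", steroid_analytes())],
               100)
  two <- zeros; two["DHEA"] <- 1; two["testosterone"] <- 3
  cn <- percent_vector(two)$cn
  expect_equal(cn[match("DHEA", steroid_analytes())], 25)
  expect_equal(cn[match("testosterone", steroid_analytes())], 75)

  expect_error(percent_vector(zeros), "all-zero")
})

test_that("ratio vector enumerates all unordered pairs in canonical order", {
  p <- test_panel()
  rv <- ratio_vector(p, apply_weight_normalization = FALSE)
  expect_s3_class(rv, "ratio_vector")
  expect_equal(length(rv$r), 45L)
  # brute-force elementwise oracle: numerator is the earlier-indexed analyte
  idx <- 0
  for (k in 1:9) for (i in (k + 1):10) {
    idx <- idx + 1
    expect_identical(rv$num[idx], steroid_analytes()[k])
    expect_identical(rv$den[idx], steroid_analytes()[i])
    expect_equal(rv$r[idx], p[[k]] / p[[i]])
  }

  # scale invariance: c * panel gives the identical ratio vector
  expect_equal(ratio_vector(test_panel(scale = 17),
                            apply_weight_normalization = FALSE)$r, rv$r)

  bad <- p; bad["progesterone"] <- 0
  expect_error(ratio_vector(bad, apply_weight_normalization = FALSE),
               "progesterone")
})

test_that("weight normalization changes exactly the cortisol/DHEAS ratios", {
  p <- random_panel(11)
  raw <- ratio_vector(p, apply_weight_normalization = FALSE)
  wn <- ratio_vector(weight_normalize(p), apply_weight_normalization = FALSE)
  factor_for <- function(analyte) {
    if (analyte == "cortisol") 10 else if (analyte == "DHEAS") 100 else 1
  }
  for (j in seq_along(raw$r)) {
    expected <- raw$r[j] / factor_for(raw$num[j]) * factor_for(raw$den[j])
    expect_equal(wn$r[j], expected, info = paste(raw$num[j], raw$den[j]))
  }
})

test_that("ratio count matches the pair-enumeration oracle for n = 1..12", {
  oracle <- function(n) {
    total <- 0L
    for (k in seq_len(max(n - 1, 0))) total <- total + (n - k)
    total
  }
  for (n in 1:12) expect_equal(ratio_count(n), oracle(n), info = n)
  expect_equal(ratio_count(10), 45L)
  expect_equal(ratio_count(2), 1L)
  expect_equal(ratio_count(1), 0L)
  expect_error(ratio_count(0), "integer >= 1")

  # generic panels of size n produce exactly ratio_count(n) entries
  for (n in 2:12) {
    set.seed(n)
    panel <- setNames(stats::rlnorm(n), paste0("analyte", seq_len(n)))
    rv <- ratio_vector(panel, apply_weight_normalization = FALSE)
    expect_equal(length(rv$r), ratio_count(n), info = n)
  }
})

test_that("vectors export as key,value delimited text", {
  f <- withr::local_tempfile(fileext = ".csv")
  export_vector(ratio_vector(test_panel()), f)
  df <- read.csv(f)
  expect_equal(nrow(df), 45L)
  expect_identical(df$key[1], "aldosterone/corticosterone")

  export_vector(percent_vector(test_panel()), f)
  df <- read.csv(f)
  expect_equal(nrow(df), 11L)  # 10 analytes + virtual total entry
  expect_equal(df$key[11], 1000)
})
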