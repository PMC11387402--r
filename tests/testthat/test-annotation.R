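make_lpc_catalog <- function() {
  build_catalog(toy_template("LPC", carbon = c(20, 30), db = c(0, 2),
                             adducts = c("[M+H]+", "[M+Na]+")))
}

test_that("features at exact catalog m/z annotate back with ppm error 0", {
  catalog <- make_lpc_catalog()
  sub <- catalog[catalog$adduct == "[M+H]+", ]
  features <- tibble::tibble(feature_id = sub$name, mz = sub$mz,
                             polarity = "positive")
  hits <- annotate_features(features, catalog, tol_ppm = 5)
  acc <- hits[hits$accepted, ]
  expect_identical(acc$name, sub$name)
  expect_true(all(abs(acc$ppm_error) < 1e-9))
})

test_that("single accepted hit: smallest |ppm|, then adduct priority, then name", {
  # two candidate entries straddling the observed m/z
  catalog <- tibble::tibble(
    class_code = "LPC", n = c(26L, 26L), d = c(0L, 1L),
    name = c("A(26:0)", "B(26:1)"), formula = "x",
    neutral_mass = c(635.4890, 635.4917),
    adduct = "[M+H]+", polarity = "positive", charge = 1L,
    mz = c(636.4963, 636.4990)
  )
  attr(catalog, "adduct_priority") <- "[M+H]+"
  class(catalog) <- c("mz_catalog", class(catalog))
  f <- tibble::tibble(feature_id = "f1", mz = 636.4970,
                      polarity = "positive")
  hits <- annotate_features(f, catalog, tol_ppm = 10)
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$name[hits$accepted], "A(26:0)")
  # exact tie in |ppm| (isobaric species) resolved lexicographically
  catalog2 <- catalog
  catalog2$mz <- c(636.4963, 636.4963)
  f2 <- tibble::tibble(feature_id = "f1", mz = 636.4963,
                       polarity = "positive")
  h2 <- annotate_features(f2, catalog2, tol_ppm = 5)
  expect_identical(h2$name[h2$accepted], "A(26:0)")
})

test_that("unmatched and polarity-mismatched features are kept, flagged", {
  catalog <- make_lpc_catalog()
  f <- tibble::tibble(feature_id = c("far", "neg"),
                      mz = c(9000, 636.4963),
                      polarity = c("positive", "negative"))
  expect_warning(hits <- annotate_features(f, catalog, tol_ppm = 5),
                 "polarity")
  expect_identical(nrow(hits), 2L)
  expect_true(all(!hits$accepted))
  expect_true(all(is.na(hits$name)))
})

test_that("annotation acceptance under Gaussian ppm jitter and RT windows", {
  catalog <- make_lpc_catalog()
  sub <- catalog[catalog$adduct == "[M+H]+", ]
  sigma <- 1
  set.seed(3)
  reps <- 30
  idx <- rep(seq_len(nrow(sub)), reps)
  features <- tibble::tibble(
    feature_id = sprintf("f%04d", seq_along(idx)),
    mz = sub$mz[idx] * (1 + rnorm(length(idx), 0, sigma) * 1e-6),
    polarity = "positive"
  )
  hits <- annotate_features(features, catalog, tol_ppm = 3 * sigma)
  acc_rate <- sum(hits$accepted) / nrow(features)
  expect_gte(acc_rate, 0.99)
  # permutation invariance: same hits in permuted order
  perm <- sample(nrow(features))
  hits_perm <- annotate_features(features[perm, ], catalog,
                                 tol_ppm = 3 * sigma)
  expect_identical(
    dplyr::arrange(hits_perm[hits_perm$accepted, ], .data$feature_id),
    dplyr::arrange(hits[hits$accepted, ], .data$feature_id)
  )
  # an RT window excludes out-of-window candidates of the listed class
  f_rt <- tibble::tibble(feature_id = "r1", mz = sub$mz[1],
                         polarity = "positive", rt = 12)
  win <- tibble::tibble(class_code = "LPC", rt_min = 1, rt_max = 3)
  h_rt <- annotate_features(f_rt, catalog, tol_ppm = 5, rt_windows = win)
  expect_false(any(h_rt$accepted))
})

test_that("name-keyed tables become pre-annotated features with rejects", {
  tab <- tibble::tibble(name = c("LPC(26:0)", "PC(44:2)", "not_a_lipid"),
                        s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  out <- features_from_names(tab)
  expect_identical(nrow(out$features), 2L)
  expect_identical(out$rejects, "not_a_lipid")
  expect_true(all(out$hits$accepted))
  expect_identical(out$hits$name, c("LPC(26:0)", "PC(44:2)"))
  # round trip: synthetic table -> features -> same row set
  tab2 <- tibble::tibble(name = c("TG(52:2)", "SM(36:1)"), a = c(1, 2))
  out2 <- features_from_names(tab2)
  expect_identical(out2$features$name, tab2$name)
  expect_identical(out2$rejects, character(0))
})
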