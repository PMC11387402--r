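test_that("monoisotopic mass is an exact, additive weighted sum", {
  # hand-summed from independent constants
  expect_equal(round(monoisotopic_mass("C34H70NO7P"), 4), 635.4890)
  expect_identical(monoisotopic_mass(""), 0)
  # one CH2 apart
  expect_equal(monoisotopic_mass("C35H72NO7P") -
                 monoisotopic_mass("C34H70NO7P"),
               14.01565, tolerance = 1e-6)
  # additive over concatenation, random formulas
  set.seed(11)
  for (i in 1:20) {
    a <- formula_string(c(C = sample(1:40, 1), H = sample(1:80, 1),
                          O = sample(0:10, 1)))
    b <- formula_string(c(C = sample(1:40, 1), N = sample(0:3, 1),
                          P = sample(0:2, 1)))
    expect_equal(monoisotopic_mass(formula_add(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b))
  }
  expect_error(monoisotopic_mass("C2Xx3"), "Xx")
})

test_that("formula parsing and rendering round-trip", {
  counts <- parse_chem_formula("C34H70NO7P")
  expect_identical(counts[["N"]], 1L)
  expect_identical(counts[["O"]], 7L)
  expect_identical(formula_string(counts), "C34H70NO7P")
  expect_error(formula_string(c(C = -1)), "Negative")
})

test_that("class expansion matches the composition oracle for every class", {
  tpl <- lipid_class_templates()
  # grid point named in the targeted assay
  lpc <- expand_class(tpl[tpl$class_code == "LPC", ])
  expect_identical(lpc$formula[lpc$n == 26 & lpc$d == 0], "C34H70NO7P")
  # one species per grid point, unique names
  pc <- tpl[tpl$class_code == "PC", ]
  pc$carbon_min <- pc$carbon_max <- 28L
  pc$db_min <- pc$db_max <- 0L
  expect_identical(nrow(expand_class(pc)), 1L)
  expect_identical(expand_class(pc)$name, "PC(28:0)")
  # every class formula rule against the independent composition oracle,
  # across a spread of grid points
  for (i in seq_len(nrow(tpl))) {
    t1 <- tpl[i, ]
    for (n in unique(c(t1$carbon_min, t1$carbon_min + 7, t1$carbon_max))) {
      for (d in c(0L, 2L)) {
        got <- parse_chem_formula(class_formula(t1, n, d))
        want <- oracle_composition(t1$class_code, n, d)
        expect_identical(got[sort(names(got))],
                         stats::setNames(as.integer(want[sort(names(want))]),
                                         sort(names(want))),
                         label = paste0(t1$class_code, "(", n, ":", d, ")"))
      }
    }
  }
  # TG tri-radyl example
  tg <- tpl[tpl$class_code == "TG", ]
  tg42 <- expand_class(tg)
  expect_identical(tg42$formula[tg42$n == 42 & tg42$d == 0], "C45H86O6")
  # rule driven into invalid territory names the offending pair
  bad <- tpl[tpl$class_code == "Cer", ]
  expect_error(class_formula(bad, 20, 25), "20:25")
})

test_that("adduct m/z follows (M + shift)/|z| with electron correction", {
  m <- monoisotopic_mass("C34H70NO7P")
  expect_equal(round(adduct_mz(m, "[M+H]+"), 2), 636.50)
  expect_equal(adduct_mz(m, "[M+H]+"), m + 1.00727646688, tolerance = 1e-9)
  # identity adduct
  expect_equal(adduct_mz(m, data.frame(shift = 0, charge = 1)), m)
  expect_error(adduct_mz(m, data.frame(shift = 0, charge = 0)), "nonzero")
  # deuterated internal standard: +4 (D - H)
  em <- element_masses()
  m_d4 <- m + 4 * (em[["D"]] - em[["H"]])
  expect_equal(round(adduct_mz(m_d4, "[M+H]+"), 2), 640.52)
})

test_that("mass ladders: CH2 steps in n, 2H steps in d", {
  tpl <- lipid_class_templates()
  catalog <- build_catalog(tpl[tpl$class_code %in% c("LPC", "TG"), ])
  for (cc in c("LPC", "TG")) {
    sub <- catalog[catalog$class_code == cc & catalog$d == 2 &
                     catalog$adduct == "[M+H]+", ]
    sub <- sub[order(sub$n), ]
    expect_true(all(abs(diff(sub$mz) - 14.01565) < 1e-6))
    # each double bond removes H2
    sub_d <- catalog[catalog$class_code == cc &
                       catalog$n == min(catalog$n[catalog$class_code == cc]) + 4 &
                       catalog$adduct == "[M+H]+", ]
    sub_d <- sub_d[order(sub_d$d), ]
    expect_true(all(abs(diff(sub_d$neutral_mass) + 2.01565) < 1e-6))
  }
})

test_that("lipid names parse, sum over chains, and round-trip", {
  p <- parse_lipid_name(c("PC(44:2)", "TG(14:0/14:0/14:0)",
                          "SM(d18:1/12:0)", "D7-CE(16:0)",
                          "1-acyl LPC(26:0)"))
  expect_identical(p$class_code, c("PC", "TG", "SM", "CE", "LPC"))
  expect_identical(p$n, c(44L, 42L, 30L, 16L, 26L))
  expect_identical(p$d, c(2L, 0L, 1L, 0L, 0L))
  expect_identical(p$label[4], "D7")
  expect_identical(p$isomer[5], "1-acyl")
  expect_error(parse_lipid_name("LPC()"), "LPC\\(\\)")
  expect_error(parse_lipid_name("not_a_lipid"), "not_a_lipid")
  # round trip over a whole expanded class
  tpl <- lipid_class_templates()
  sm <- expand_class(tpl[tpl$class_code == "SM", ])
  rt <- parse_lipid_name(sm$name)
  expect_identical(rt$class_code, sm$class_code)
  expect_identical(rt$n, as.integer(sm$n))
  expect_identical(rt$d, as.integer(sm$d))
})

test_that("catalog has |species| x |adducts| entries and rejects duplicates", {
  tpl <- toy_template("LPC", carbon = c(24, 26), db = c(0, 0),
                      adducts = c("[M+H]+", "[M+Na]+"))
  tpl$carbon_min <- 24L; tpl$carbon_max <- 26L
  catalog <- build_catalog(tpl)
  expect_identical(nrow(catalog), 3L * 2L)
  expect_false(is.unsorted(catalog$mz))
  expect_error(build_catalog(dplyr::bind_rows(tpl, tpl)), "Duplicate")
})

test_that("ppm-window queries agree with a linear scan", {
  tpl <- lipid_class_templates()
  catalog <- build_catalog(tpl[tpl$class_code == "LPC", ])
  # self-retrieval at an entry's own m/z
  hit <- query_catalog(catalog, catalog$mz[100], 1, catalog$polarity[100])
  expect_true(catalog$name[100] %in% hit$name)
  expect_true(any(abs(hit$ppm_error) < 1e-9))
  # oracle equivalence over random queries
  set.seed(7)
  n_q <- 1e4
  mzs <- runif(n_q, min(catalog$mz) - 1, max(catalog$mz) + 1)
  tols <- sample(c(1, 5, 20, 100), n_q, replace = TRUE)
  mismatches <- sum(vapply(seq_len(n_q), function(i) {
    got <- query_catalog(catalog, mzs[i], tols[i])
    want <- oracle_query(catalog, mzs[i], tols[i])
    !identical(got$name, want$name) || !identical(got$adduct, want$adduct)
  }, logical(1)))
  expect_identical(mismatches, 0L)
})
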