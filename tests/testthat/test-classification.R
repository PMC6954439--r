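test_that("the four canonical feature patterns map to the four classes", {
  rules <- classification_rules()
  # long networked structure: extension above 11 um
  expect_equal(classify_object(feat_row(E = 12, AR = 8, C = 0.2), rules),
               "filament")
  # small round structure: radius below 0.6 um
  expect_equal(classify_object(feat_row(r_eq = 0.4, C = 0.9, AR = 1.1,
                                        E = 0.2), rules), "punctum")
  # quasi-round, compact, larger than a punctum
  expect_equal(classify_object(feat_row(r_eq = 1.0, C = 0.9, AR = 1.2,
                                        S = 0.95, E = 1), rules), "swollen")
  # elongated but short of the filament threshold
  expect_equal(classify_object(feat_row(E = 5, AR = 4, C = 0.3), rules),
               "rod")
})

test_that("sequential rule order gives priority to round classes", {
  rules <- classification_rules()
  # round and small wins over a long extension (punctum rule fires first)
  expect_equal(classify_object(feat_row(C = 0.95, AR = 1.1, r_eq = 0.3,
                                        E = 20), rules), "punctum")
  # round, compact, large wins over extension
  expect_equal(classify_object(feat_row(C = 0.95, AR = 1.1, S = 0.95,
                                        r_eq = 1.2, E = 20), rules), "swollen")
  # round but loose (low solidity) and large: falls through to extension
  expect_equal(classify_object(feat_row(C = 0.95, AR = 1.1, S = 0.5,
                                        r_eq = 1.2, E = 20), rules), "filament")
})

test_that("classification is exhaustive, exclusive and order-equivariant", {
  set.seed(31)
  n <- 500
  feats <- data.frame(
    A = runif(n, 0.01, 10), C = runif(n), AR = 1 + rexp(n, 0.5),
    S = runif(n, 0.3, 1), E = runif(n, 0, 20), r_eq = runif(n, 0.05, 2))
  feats$MLE <- 2 * feats$r_eq
  cls <- classify_features(feats, classification_rules())
  expect_length(cls, n)
  expect_true(all(cls %in% c("filament", "rod", "punctum", "swollen")))
  # permuting rows permutes classes identically
  p <- sample.int(n)
  expect_identical(classify_features(feats[p, ], classification_rules()),
                   cls[p])
  # determinism
  expect_identical(classify_features(feats, classification_rules()), cls)
})

test_that("boundary sweeps switch class exactly once at the thresholds", {
  rules <- classification_rules()
  # extension sweep with elongated, non-round features held fixed
  E <- seq(5, 15, by = 0.1)
  cls <- vapply(E, function(e)
    classify_object(feat_row(E = e, AR = 5, C = 0.3, r_eq = 0.8), rules),
    character(1L))
  switches <- which(cls[-1L] != cls[-length(cls)])
  expect_length(switches, 1L)
  expect_identical(unique(cls[E <= 11]), "rod")       # strict > threshold
  expect_identical(unique(cls[E > 11]), "filament")

  # radius sweep with round, compact features held fixed
  r <- seq(0.2, 1.2, by = 0.02)
  cls_r <- vapply(r, function(x)
    classify_object(feat_row(r_eq = x, C = 0.95, AR = 1.1, S = 0.95, E = 0.5),
                    rules), character(1L))
  sw_r <- which(cls_r[-1L] != cls_r[-length(cls_r)])
  expect_length(sw_r, 1L)
  expect_identical(unique(cls_r[r < 0.6]), "punctum")  # strict < threshold
  expect_identical(unique(cls_r[r >= 0.6]), "swollen")
})

test_that("the Feret-based radius variant is honoured", {
  rules <- classification_rules(radius_feature = "feret")
  f <- feat_row(C = 0.95, AR = 1.1, S = 0.95, r_eq = 0.9, MLE = 1.0, E = 0.5)
  expect_equal(classify_object(f, rules), "punctum")   # MLE/2 = 0.5 < 0.6
  rules_eq <- classification_rules()
  expect_equal(classify_object(f, rules_eq), "swollen")
})

test_that("rule thresholds are validated", {
  expect_error(classification_rules(filament_min_extension_um = -1), "finite")
  expect_error(classification_rules(round_min_circularity = 1.2), "<= 1")
})

test_that("classify_cell appends one class per object, order preserved", {
  expect_identical(nrow(classify_cell(features = feat_row()[0, ],
                                      rules = classification_rules())), 0L)
  f3 <- rbind(feat_row(E = 12, C = 0.2, AR = 5),
              feat_row(r_eq = 0.3, C = 0.9, AR = 1.2, E = 0.1),
              feat_row(E = 3, C = 0.3, AR = 4))
  out <- classify_cell(features = f3, rules = classification_rules())
  expect_identical(out$class, c("filament", "punctum", "rod"))
})
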