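# The identity catalog, checking modes, soundness, and classification.

test_that("star algebras satisfy the left invertive law with the expected coefficients", {
  M3 <- star_algebra(3)
  a <- golden_alpha()
  a2 <- a * a; a3 <- a2 * a
  # (a1 a2) a3 and (a3 a2) a1 both give coefficients (alpha^2, alpha^3, alpha^2)
  lhs <- multiply(M3, multiply(M3, basis_element(M3, 1), basis_element(M3, 2)),
                  basis_element(M3, 3))
  rhs <- multiply(M3, multiply(M3, basis_element(M3, 3), basis_element(M3, 2)),
                  basis_element(M3, 1))
  expect_element_equal(lhs, element(M3, list(a2, a3, a2)))
  expect_element_equal(lhs, rhs)
  expect_identical(check_identity(M3, "left_invertive", mode = "basis")$verdict,
                   "holds")
  # associativity fails: a1(a2 a3) = alpha a1 + alpha^3 a2 + alpha^4 a3
  inner <- multiply(M3, basis_element(M3, 1),
                    multiply(M3, basis_element(M3, 2), basis_element(M3, 3)))
  expect_element_equal(inner, element(M3, list(a, a3, a2 * a2)))
  rep_a <- check_identity(M3, "associative", mode = "basis")
  expect_identical(rep_a$verdict, "fails")
  expect_false(is.null(rep_a$counterexample))
  rep_c <- check_identity(M3, "commutative", mode = "basis")
  expect_identical(rep_c$verdict, "fails")
})

test_that("failure witnesses re-evaluate to genuinely unequal elements", {
  M3 <- star_algebra(3)
  rep_ <- check_identity(M3, "associative", mode = "basis")
  w <- rep_$counterexample
  env <- lapply(w$assignment, function(lbl)
    basis_element(M3, match(lbl, M3$basis)))
  lhs <- multiply(M3, multiply(M3, env$x, env$y), env$z)
  rhs <- multiply(M3, env$x, multiply(M3, env$y, env$z))
  expect_false(isTRUE(lhs == rhs))
  expect_identical(format(lhs), w$lhs)
  expect_identical(format(rhs), w$rhs)
})

test_that("basis-exhaustive mode is refused for non-multilinear identities", {
  M3 <- star_algebra(3)
  expect_error(check_identity(M3, "flexible", mode = "basis"),
               "unsound.*not multilinear")
  expect_error(check_identity(M3, "nonexistent_identity"), "unknown identity")
})

test_that("flexible and generalized Jordan hold on weight-1 star samples", {
  for (A in list(star_algebra(3), star_gf4(3))) {
    for (id in c("flexible", "generalized_jordan")) {
      rep_ <- check_identity(A, id, mode = "sample", sample_size = 50, seed = 4)
      expect_identical(rep_$verdict, "holds-on-sample")
      expect_identical(rep_$mode, "weight1-sample")
    }
  }
})

test_that("basis checking and random sampling agree for multilinear identities", {
  fixtures <- list(mendelian_gametic(2), star_algebra(2),
                   random_gametic(2, seed = 13, la_variant = TRUE))
  for (A in fixtures) {
    for (id in c("commutative", "associative", "left_invertive",
                 "left_id_consequence")) {
      vb <- check_identity(A, id, mode = "basis")$verdict
      vs <- check_identity(A, id, mode = "sample", sample_size = 200,
                           seed = 2, weight1 = FALSE)$verdict
      expect_identical(vb == "holds", vs == "holds-on-sample",
                       label = sprintf("%s on %s", id,
                                       A$provenance$constructor))
    }
  }
})

test_that("left identities are found exactly when they exist", {
  D <- diagonal_algebra(field_rational(), 2)
  e <- find_left_identity(D)
  expect_element_equal(e, element(D, c(1, 1)))
  # Mendelian: e a1 = a1 forces e = a1, but a1 a2 != a2
  expect_null(find_left_identity(mendelian_gametic(2)))
  expect_null(find_left_identity(star_algebra(2)))
  # a left-invertive algebra with a left identity satisfies (xy)z = y(xz)
  expect_identical(check_identity(D, "left_invertive", mode = "basis")$verdict,
                   "holds")
  expect_identical(
    check_identity(D, "left_id_consequence", mode = "basis")$verdict, "holds")
})

test_that("every catalog identity holds on the commutative-associative fixture", {
  D <- diagonal_algebra(gf4(), 2)
  for (id in names(identity_catalog())) {
    mode <- if (identity_catalog()[[id]]$multilinear) "basis" else "exhaustive"
    rep_ <- check_identity(D, id, mode = mode, weight1 = FALSE)
    expect_identical(rep_$verdict, "holds", label = id)
  }
})

test_that("product_power on weight-1 star elements degenerates to ab = ab", {
  # on weight-1 elements x^2 = x, so (ab)^2 = a^2 b^2 carries no new content;
  # the checker must still confirm it
  M2 <- star_algebra(2)
  rep_ <- check_identity(M2, "product_power", mode = "sample",
                         sample_size = 50, seed = 6, weight1 = TRUE)
  expect_identical(rep_$verdict, "holds-on-sample")
})

test_that("classification gates the derived suite on the LA + alternative hypothesis", {
  cl3 <- classify(star_algebra(3), sample_size = 40, seed = 1)
  expect_identical(unname(cl3$verdicts["left_invertive"]), "holds")
  expect_identical(unname(cl3$verdicts["commutative"]), "fails")
  expect_identical(unname(cl3$verdicts["associative"]), "fails")
  # star algebras are not alternative, so the derived suite must not be asserted
  expect_false(cl3$gate_passed)
  expect_identical(unname(cl3$verdicts["power_sum"]), "not-applicable")
  clG <- classify(mendelian_gametic(2), sample_size = 40, seed = 1)
  expect_identical(unname(clG$verdicts["commutative"]), "holds")
  expect_identical(unname(clG$verdicts["associative"]), "fails")
  # the diagonal fixture passes everything
  clD <- classify(diagonal_algebra(gf4(), 2), sample_size = 40, seed = 1)
  expect_true(clD$gate_passed)
  expect_true(all(clD$verdicts %in% c("holds", "holds-on-sample")))
})
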