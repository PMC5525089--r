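# Bilinear multiplication, weights, principal powers, change of basis.

test_that("products follow the structure tensor exactly", {
  G <- mendelian_gametic(2)
  expect_element_equal(multiply(G, basis_element(G, 1), basis_element(G, 2)),
                       element(G, c("1/2", "1/2")))
  expect_element_equal(multiply(G, basis_element(G, 1), basis_element(G, 1)),
                       basis_element(G, 1))
  # zero annihilates
  x <- element(G, c("1/3", "2/3"))
  expect_element_equal(multiply(G, zero_element(G), x), zero_element(G))
  # star product: a_j * a_k = alpha a_j + alpha^2 a_k
  M3 <- star_algebra(3)
  a <- golden_alpha()
  expect_element_equal(multiply(M3, basis_element(M3, 2), basis_element(M3, 3)),
                       element(M3, list(scalar(M3$field, 0), a, a * a)))
  expect_error(multiply(G, x, element(mendelian_gametic(3), c(1, 0, 0))),
               "dimension|length|coefficients")
})

test_that("multiplication is bilinear on random exact inputs", {
  set.seed(7)
  for (A in list(mendelian_gametic(3),
                 random_gametic(3, seed = 11, la_variant = TRUE),
                 star_algebra(3))) {
    for (rep in 1:10) {
      x <- random_element(A, weight1 = FALSE)
      xp <- random_element(A, weight1 = FALSE)
      y <- random_element(A, weight1 = FALSE)
      al <- scalar(A$field, sample(-3:3, 1))
      be <- scalar(A$field, sample(-3:3, 1))
      lin <- element(A, mapply(function(u, v) al * u + be * v,
                               x$coeffs, xp$coeffs, SIMPLIFY = FALSE))
      lhs <- multiply(A, lin, y)
      rhs <- mapply(function(u, v) al * u + be * v,
                    multiply(A, x, y)$coeffs, multiply(A, xp, y)$coeffs,
                    SIMPLIFY = FALSE)
      expect_element_equal(lhs, element(A, rhs))
      # and in the right slot
      lhs2 <- multiply(A, y, lin)
      rhs2 <- mapply(function(u, v) al * u + be * v,
                     multiply(A, y, x)$coeffs, multiply(A, y, xp)$coeffs,
                     SIMPLIFY = FALSE)
      expect_element_equal(lhs2, element(A, rhs2))
    }
  }
})

test_that("weight is the coefficient sum and a homomorphism for stochastic tensors", {
  G <- mendelian_gametic(3)
  one <- scalar(G$field, 1)
  expect_scalar_equal(weight(element(G, c("1/2", "1/3", "1/6"))), one)
  expect_scalar_equal(weight(basis_element(G, 2)), one)
  # b = D - R in the mutation algebra has weight 0
  Mu <- mutation_algebra("1/4", "1/2")
  b <- basis_element(Mu, 1) - basis_element(Mu, 2)
  expect_scalar_equal(weight(b), scalar(Mu$field, 0))
  # w(xy) = w(x) w(y) for row-stochastic tensors, on random exact elements
  set.seed(3)
  for (A in list(G, random_gametic(3, seed = 5), star_algebra(2))) {
    for (rep in 1:10) {
      x <- random_element(A, weight1 = FALSE)
      y <- random_element(A, weight1 = FALSE)
      expect_scalar_equal(weight(multiply(A, x, y)), weight(x) * weight(y))
    }
  }
})

test_that("principal powers are left-normed and match known squares", {
  G <- mendelian_gametic(3)
  x <- element(G, c("1/2", "1/3", "1/6"))
  expect_element_equal(principal_power(G, x, 1), x)
  # weight-1 elements of the Mendelian algebra are idempotent
  expect_element_equal(principal_power(G, x, 2), x)
  Mu <- mutation_algebra("1/4", "1/2")
  expect_element_equal(principal_power(Mu, basis_element(Mu, 1), 2),
                       element(Mu, c("3/4", "1/4")))
  expect_error(principal_power(G, x, 0), "m >= 1")
})

test_that("change of basis round-trips and commutes with multiplication", {
  A <- mendelian_gametic(3)
  expect_true(tensors_equal(A, change_of_basis(A, diag(3), A$basis)))
  M <- matrix(c("1", "1/2", "0",
                "0", "1",   "-1",
                "1", "0",   "2"), 3, 3, byrow = TRUE)
  B <- change_of_basis(A, M, c("b1", "b2", "b3"))
  # exact inverse agrees with the numeric one computed independently
  f <- A$field
  Minv_m <- laalgebra:::.mat_inv(f, laalgebra:::.mat_from(f, M))
  Minv_num <- solve(matrix(c(1, 1/2, 0, 0, 1, -1, 1, 0, 2), 3, 3, byrow = TRUE))
  got <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) got[i, j] <- as.numeric(Minv_m[[i, j]])
  expect_equal(got, unname(Minv_num), tolerance = 1e-12)
  # round trip through the inverse restores the original tensor exactly
  back <- change_of_basis(B, Minv_m, A$basis)
  expect_true(tensors_equal(A, back))
  set.seed(9)
  for (rep in 1:5) {
    x <- random_element(A, weight1 = FALSE)
    y <- random_element(A, weight1 = FALSE)
    to_new <- function(v) laalgebra:::.el_to_new_basis(f, Minv_m, v)
    expect_element_equal(multiply(B, to_new(x), to_new(y)),
                         to_new(multiply(A, x, y)))
  }
  sing <- matrix(c("1", "2", "2", "4"), 2, 2, byrow = TRUE)
  expect_error(change_of_basis(mendelian_gametic(2), sing), "singular")
})
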