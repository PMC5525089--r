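# Constructors: gametic, zygotic, mutation, Gonshor basis, star algebras,
# and the seeded random-tensor fixture generator.

test_that("gametic tensor validation enforces the defining constraints", {
  G <- mendelian_gametic(3)
  # the Mendelian tensor itself validates as a classical gametic algebra
  expect_s3_class(gametic_from_tensor(G$tensor, la_variant = FALSE),
                  "laa_algebra")
  # asymmetric tensor: rejected classically, accepted as the LA variant
  f <- field_rational()
  ent <- array("0", dim = c(2, 2, 2))
  ent[1, 1, 1] <- "1"; ent[2, 2, 2] <- "1"
  ent[1, 2, 1] <- "1"                      # a1 a2 = a1
  ent[2, 1, 2] <- "1"                      # a2 a1 = a2  (noncommutative)
  expect_error(gametic_from_tensor(structure_tensor(f, ent)),
               "symmetry gamma\\[1,2,")
  expect_s3_class(gametic_from_tensor(structure_tensor(f, ent),
                                      la_variant = TRUE), "laa_algebra")
  # row sum 3/4: rejected with the offending pair named
  bad <- array("0", dim = c(2, 2, 2))
  bad[1, 1, 1] <- "3/4"; bad[1, 2, 1] <- "1/2"; bad[1, 2, 2] <- "1/2"
  bad[2, 1, 1] <- "1/2"; bad[2, 1, 2] <- "1/2"; bad[2, 2, 2] <- "1"
  expect_error(gametic_from_tensor(structure_tensor(f, bad)),
               "row sum for \\(i=1, j=1\\) is 3/4")
  # entries outside [0, 1]
  neg <- array("0", dim = c(2, 2, 2))
  neg[1, 1, 1] <- "2"; neg[1, 1, 2] <- "-1"
  neg[1, 2, 1] <- "1/2"; neg[1, 2, 2] <- "1/2"
  neg[2, 1, 1] <- "1/2"; neg[2, 1, 2] <- "1/2"; neg[2, 2, 2] <- "1"
  expect_error(gametic_from_tensor(structure_tensor(f, neg)),
               "outside \\[0, 1\\]")
})

test_that("random gametic algebras are reproducible and valid", {
  A1 <- random_gametic(3, seed = 7)
  A2 <- random_gametic(3, seed = 7)
  expect_true(tensors_equal(A1, A2))
  expect_false(tensors_equal(A1, random_gametic(3, seed = 8)))
  # every output passes its own validation on re-construction
  for (s in c(1, 5, 9)) {
    A <- random_gametic(3, seed = s)
    expect_s3_class(gametic_from_tensor(A$tensor), "laa_algebra")
  }
  # the RNG state of the session is left untouched
  set.seed(123); before <- .Random.seed
  invisible(random_gametic(3, seed = 99))
  expect_identical(before, .Random.seed)
  # LA-variant draws break the symmetry for at least some seeds
  asym <- vapply(1:20, function(s) {
    A <- random_gametic(3, seed = s, la_variant = TRUE)
    !tryCatch({ validate_tensor(A$field, A$tensor, "symmetric"); TRUE },
              error = function(e) FALSE)
  }, logical(1))
  expect_true(any(asym))
})

test_that("zygotic duplication reproduces Mendelian genotype ratios", {
  Z <- zygotic_duplicate(mendelian_gametic(2))
  A <- Z$algebra
  expect_identical(A$basis, c("e11", "e12", "e22"))
  expect_identical(Z$index$i, c(1L, 1L, 2L))
  expect_identical(Z$index$j, c(1L, 2L, 2L))
  h <- basis_element(A, 2)
  # heterozygote cross: 1:2:1
  expect_element_equal(multiply(A, h, h), element(A, c("1/4", "1/2", "1/4")))
  # homozygote cross with itself breeds true
  expect_element_equal(multiply(A, basis_element(A, 1), basis_element(A, 1)),
                       basis_element(A, 1))
  # every duplicated row sums to 1
  expect_true(validate_tensor(A$field, A$tensor, "row_stochastic"))
  # duplication preserves the weight homomorphism
  set.seed(21)
  for (rep in 1:5) {
    x <- random_element(A, weight1 = FALSE)
    y <- random_element(A, weight1 = FALSE)
    expect_scalar_equal(weight(multiply(A, x, y)), weight(x) * weight(y))
  }
  expect_no_error(zygotic_duplicate(star_algebra(2)))   # star rows sum to 1 too
})

test_that("the mutation algebra interpolates between Mendel and mutation pressure", {
  # no mutation: exactly the 2-allele Mendelian gametic algebra
  expect_true(tensors_equal(mutation_algebra(0, 0), mendelian_gametic(2)))
  Mu <- mutation_algebra("1/4", "1/2")
  D <- basis_element(Mu, 1); R <- basis_element(Mu, 2)
  expect_element_equal(multiply(Mu, D, D), element(Mu, c("3/4", "1/4")))
  expect_element_equal(multiply(Mu, D, R), element(Mu, c("5/8", "3/8")))
  expect_element_equal(multiply(Mu, R, D), multiply(Mu, D, R))
  expect_error(mutation_algebra("5/4", 0), "\\[0, 1\\]")
  expect_error(mutation_algebra("1/4", "1/2", field = gf4()),
               "characteristic 2|ordered")
})

test_that("the Gonshor basis change gives a^2 = a - r b, ab = (1-r-s)/2 b, b^2 = 0", {
  # verify the coefficient identities on a grid of exact rates (the entries
  # are low-degree polynomials in r and s, so a grid check proves them)
  rates <- c("0", "1/4", "1/2", "2/3", "1")
  f <- field_rational()
  half <- scalar(f, "1/2"); one <- scalar(f, 1); zero <- scalar(f, 0)
  for (rs in rates) for (ss in rates) {
    r <- scalar(f, rs); s <- scalar(f, ss)
    Go <- gonshor_basis(mutation_algebra(r, s))
    a <- basis_element(Go, 1); b <- basis_element(Go, 2)
    expect_element_equal(multiply(Go, a, a),
                         element(Go, list(one, -r)))           # a^2 = a - r b
    expect_element_equal(multiply(Go, a, b),
                         element(Go, list(zero, half * (one - r - s))))
    expect_element_equal(multiply(Go, b, b), zero_element(Go)) # b^2 = 0
  }
  # worked instance: ab = b/8 at r = 1/4, s = 1/2
  Go <- gonshor_basis(mutation_algebra("1/4", "1/2"))
  expect_element_equal(multiply(Go, basis_element(Go, 1), basis_element(Go, 2)),
                       element(Go, c("0", "1/8")))
  # the inverse change of basis restores the (D, R) products exactly
  Mu <- mutation_algebra("1/4", "1/2")
  M <- matrix(c("1", "0", "1", "-1"), 2, 2, byrow = TRUE)
  Minv <- laalgebra:::.mat_inv(Mu$field, laalgebra:::.mat_from(Mu$field, M))
  expect_true(tensors_equal(Mu, change_of_basis(Go, Minv, c("D", "R"))))
  expect_error(gonshor_basis(mendelian_gametic(2)), "mutation_algebra")
})

test_that("star algebras require alpha + alpha^2 = 1 and are noncommutative", {
  expect_error(star_algebra(3, field_rational(), scalar(field_rational(), "1/2")),
               "alpha \\+ alpha\\^2 = 1")
  for (A in list(star_algebra(3), star_gf4(3),
                 star_algebra(3, field_quadratic(5), golden_alpha(-1)))) {
    # diagonal products collapse: a_i * a_i = a_i
    for (i in 1:3)
      expect_element_equal(multiply(A, basis_element(A, i), basis_element(A, i)),
                           basis_element(A, i))
    a12 <- multiply(A, basis_element(A, 1), basis_element(A, 2))
    a21 <- multiply(A, basis_element(A, 2), basis_element(A, 1))
    expect_false(isTRUE(a12 == a21))
    # rows sum to 1: the star tensor is row-stochastic
    expect_true(validate_tensor(A$field, A$tensor, "row_stochastic"))
  }
})
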