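# Idempotents as population equilibria; the random-mating squaring map.

test_that("the mutation algebra has the unique equilibrium (s/(r+s), r/(r+s))", {
  Mu <- mutation_algebra("1/4", "1/2")
  E <- find_idempotents(Mu, weight1 = TRUE)
  expect_identical(E$kind, "isolated")
  expect_length(E$points, 1)
  expect_element_equal(E$points[[1]], element(Mu, c("2/3", "1/3")))
  # zero residual on substitution
  p <- E$points[[1]]
  expect_element_equal(multiply(Mu, p, p), p)
  # without the weight restriction the zero element joins the set
  E0 <- find_idempotents(Mu, weight1 = FALSE)
  expect_true(any(vapply(E0$points, function(q) isTRUE(q == zero_element(Mu)),
                         logical(1))))
})

test_that("Mendelian gametic algebras are a continuum of equilibria", {
  for (n in 2:3) {
    G <- mendelian_gametic(n)
    E <- find_idempotents(G, weight1 = TRUE)
    expect_identical(E$kind, "continuum")
    expect_match(E$constraints[1], "weight-1 set")
    for (p in E$points) expect_element_equal(multiply(G, p, p), p)
  }
})

test_that("over GF(4) every weight-1 element of the star algebra is idempotent", {
  M4 <- star_gf4(4)
  E <- find_idempotents(M4, weight1 = TRUE)
  # 4^3 = 64 weight-1 coefficient vectors, all idempotent
  expect_length(E$points, 64)
  lbls <- vapply(E$points, format, character(1))
  for (i in 1:4)
    expect_true(format(basis_element(M4, i)) %in% lbls)
  # dropping the weight restriction keeps exactly the idempotents:
  # x * x = weight(x) x, so idempotents are weight-1 elements and 0
  E0 <- find_idempotents(M4, weight1 = FALSE)
  expect_length(E0$points, 65)
})

test_that("zygotic Mendelian equilibria are the Hardy-Weinberg states", {
  Z <- zygotic_duplicate(mendelian_gametic(2))$algebra
  E <- find_idempotents(Z, weight1 = TRUE)
  expect_identical(E$kind, "continuum")
  expect_true(length(E$points) >= 3)
  f <- Z$field
  four <- scalar(f, 4)
  for (p in E$points) {
    # (e11, e12, e22) = (p^2, 2pq, q^2)  <=>  x2^2 = 4 x1 x3 on weight-1 x
    x <- p$coeffs
    expect_scalar_equal(x[[2]] * x[[2]], four * x[[1]] * x[[3]])
    expect_element_equal(multiply(Z, p, p), p)
  }
  # the parametrized family (p^2, 2pq, q^2) is idempotent for exact p
  for (ps in c("0", "1/5", "1/2", "3/4", "1")) {
    pp <- scalar(f, ps); qq <- scalar(f, 1) - pp
    hw <- element(Z, list(pp * pp, scalar(f, 2) * pp * qq, qq * qq))
    expect_element_equal(multiply(Z, hw, hw), hw)
  }
})

test_that("mutation trajectories contract geometrically to the equilibrium", {
  Mu <- mutation_algebra("1/4", "1/2")
  tr <- evolve(Mu, basis_element(Mu, 1), generations = 12, tol = 1e-6)
  expect_true(tr$converged)
  ustar <- scalar(Mu$field, "2/3")
  ratio <- scalar(Mu$field, "1/4")       # 1 - r - s
  for (g in 1:12) {
    d_prev <- tr$iterates[[g]]$coeffs[[1]] - ustar
    d_next <- tr$iterates[[g + 1]]$coeffs[[1]] - ustar
    expect_scalar_equal(d_next, ratio * d_prev)   # exact geometric decay
  }
  # trajectories stay on weight 1
  for (x in tr$iterates) expect_scalar_equal(weight(x), scalar(Mu$field, 1))
})

test_that("equilibria are fixed points of evolution", {
  G <- mendelian_gametic(3)
  x0 <- element(G, c("1/2", "1/3", "1/6"))
  tr <- evolve(G, x0, generations = 3)
  for (x in tr$iterates) expect_element_equal(x, x0)
  Mu <- mutation_algebra("1/8", "3/8")
  p <- find_idempotents(Mu)$points[[1]]
  tr2 <- evolve(Mu, p, generations = 3)
  for (x in tr2$iterates) expect_element_equal(x, p)
})

test_that("random mutation rates: equilibria match trajectory limits", {
  set.seed(31)
  f <- field_rational()
  one <- scalar(f, 1)
  for (rep in 1:10) {
    qd <- sample(2:4, 2, replace = TRUE)
    rn <- sample.int(qd[1], 1); sn <- sample.int(qd[2], 1)   # r, s in (0, 1]
    r <- scalar(f, paste0(rn, "/", qd[1]))
    s <- scalar(f, paste0(sn, "/", qd[2]))
    Mu <- mutation_algebra(r, s)
    E <- find_idempotents(Mu)
    expect_length(E$points, 1)
    rps <- r + s
    star <- element(Mu, list(s / rps, r / rps))
    expect_element_equal(E$points[[1]], star)
    # the deviation from equilibrium contracts by exactly (1 - r - s) per
    # generation, so trajectories converge whenever |1 - r - s| < 1
    ratio <- one - r - s
    tr <- evolve(Mu, basis_element(Mu, 2), generations = 6)
    for (g in 1:6) {
      d_prev <- tr$iterates[[g]]$coeffs[[1]] - star$coeffs[[1]]
      d_next <- tr$iterates[[g + 1]]$coeffs[[1]] - star$coeffs[[1]]
      expect_scalar_equal(d_next, ratio * d_prev)
    }
    if (abs(as.numeric(ratio)) < 1) {
      drop0 <- abs(as.numeric(tr$iterates[[1]]$coeffs[[1]]) - as.numeric(star$coeffs[[1]]))
      drop8 <- abs(as.numeric(tr$limit$coeffs[[1]]) - as.numeric(star$coeffs[[1]]))
      expect_lt(drop8, drop0 * abs(as.numeric(ratio))^5 + 1e-12)
    }
  }
})

test_that("distances to equilibrium sets are exact and contract under evolution", {
  Mu <- mutation_algebra("1/4", "1/2")
  E <- find_idempotents(Mu)
  expect_scalar_equal(distance_to_set(E$points[[1]], E), scalar(Mu$field, 0))
  expect_scalar_equal(distance_to_set(element(Mu, c(1, 0)), E),
                      scalar(Mu$field, "1/3"))
  tr <- evolve(Mu, basis_element(Mu, 1), generations = 6)
  dists <- lapply(tr$iterates, distance_to_set, E = E)
  for (g in 1:6)
    expect_true(dists[[g + 1]] <= dists[[g]])
  # the full weight-1 continuum: distance is |weight(x) - 1| / n
  G <- mendelian_gametic(2)
  EG <- find_idempotents(G)
  y <- element(G, c("1", "1/2"))          # weight 3/2
  expect_scalar_equal(distance_to_set(y, EG), scalar(G$field, "1/4"))
  expect_error(distance_to_set(basis_element(star_gf4(2), 1),
                               find_idempotents(star_gf4(2))), "ordered")
})

test_that("the numeric grid method recovers attracting equilibria exactly", {
  Mu <- mutation_algebra("1/4", "1/2")
  E <- find_idempotents(Mu, method = "grid")
  expect_true(any(vapply(E$points, function(p)
    isTRUE(p == element(Mu, c("2/3", "1/3"))), logical(1))))
  for (p in E$points) expect_element_equal(multiply(Mu, p, p), p)
})

test_that("symbolic solving is refused beyond two free coordinates", {
  # the whole-simplex continuum is detected in any dimension
  expect_identical(find_idempotents(mendelian_gametic(4), weight1 = TRUE)$kind,
                   "continuum")
  Z3 <- zygotic_duplicate(mendelian_gametic(3))$algebra    # dim 6
  expect_error(find_idempotents(Z3, weight1 = TRUE, method = "symbolic"),
               "at most 2 free coordinates")
})
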