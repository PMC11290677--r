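test_that("residualization removes the covariate signal", {
  x <- c(1, 2, 3, 4)
  expect_equal(residualize(2 * x, x), rep(0, 4))
  expect_equal(residualize(rep(5, 4), x), rep(0, 4))
  # hand OLS: slope 0.5, intercept 1
  expect_equal(residualize(c(1, 3, 2), c(1, 2, 3)), c(-0.5, 1, -0.5))
  # residuals always sum to zero
  set.seed(3)
  for (i in 1:5) {
    y <- rnorm(10); xx <- rnorm(10)
    expect_lt(abs(sum(residualize(y, xx))), 1e-9)
  }
  expect_error(residualize(c(1, 2, 3), rep(1, 3)), "constant")
})

test_that("gower distance matches hand computation and the definition", {
  df <- data.frame(x = c(0, 5, 10), b = c("0", "1", "0"),
                   row.names = c("sp1", "sp2", "sp3"))
  tt <- trait_table(df, types = c("numeric", "binary"))
  d <- gower_distance(tt)
  # observed range of x is 10, so sp1-sp2: (0.5 + 1)/2
  expect_equal(d["sp1", "sp2"], 0.75)
  expect_equal(diag(d), c(sp1 = 0, sp2 = 0, sp3 = 0))

  ident <- trait_table(data.frame(a = c(1, 1), b = c("x", "x"),
                                  row.names = c("s1", "s2")))
  expect_equal(gower_distance(ident)["s1", "s2"], 0)

  allbin <- trait_table(data.frame(a = c("0", "1"), b = c("1", "0"),
                                   row.names = c("s1", "s2")))
  expect_equal(gower_distance(allbin)["s1", "s2"], 1)

  # random mixed tables agree with an independent implementation
  set.seed(21)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    raw <- data.frame(
      num1 = rnorm(n), num2 = runif(n, 0, 100),
      cat1 = sample(letters[1:3], n, replace = TRUE),
      bin1 = sample(c("0", "1"), n, replace = TRUE),
      row.names = paste0("s", 1:n)
    )
    raw$num1[sample(n, 1)] <- NA  # exercise pairwise deletion
    w <- runif(4, 0.2, 2)
    types <- c("numeric", "numeric", "categorical", "binary")
    got <- gower_distance(trait_table(raw, types = types, weights = w))
    want <- oracle_gower(raw, types, w)
    expect_equal(got, want, tolerance = 1e-10)
    expect_true(all(got >= 0 & got <= 1))
    expect_equal(got, t(got))
  }
})

test_that("gower distance is invariant to weight scaling and affine rescaling", {
  set.seed(5)
  raw <- data.frame(x = rnorm(6), y = runif(6),
                    g = sample(c("u", "v"), 6, replace = TRUE),
                    row.names = paste0("s", 1:6))
  w <- c(1, 2, 0.5)
  d1 <- gower_distance(trait_table(raw, weights = w))
  d2 <- gower_distance(trait_table(raw, weights = 2 * w))
  expect_equal(d1, d2)

  raw2 <- raw
  raw2$x <- 3 * raw$x - 7  # affine rescale of a numeric trait
  expect_equal(gower_distance(trait_table(raw2, weights = w)), d1,
               tolerance = 1e-10)

  expect_error(trait_table(raw, weights = c(0, 0, 0)), "positive")
  nocommon <- data.frame(a = c(1, NA, 2), b = c(NA, 1, 2),
                         row.names = c("s1", "s2", "s3"))
  expect_error(gower_distance(trait_table(nocommon)), "comparable")
})

test_that("functional trees sit on the gower distances", {
  two <- trait_table(data.frame(x = c(0, 5, 10), b = c("0", "1", "0"),
                                row.names = c("sp1", "sp2", "sp3")),
                     types = c("numeric", "binary"))
  d <- gower_distance(two)
  tr <- functional_tree(two)
  expect_setequal(tr$tip.label, rownames(two))
  # NJ on 3 taxa is exact, so path lengths reproduce the distances
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)

  # a block of functionally identical species collapses to ~0 path length
  blk <- trait_table(data.frame(x = c(1, 1, 1, 9), g = c("a", "a", "a", "b"),
                                row.names = paste0("s", 1:4)))
  btr <- functional_tree(blk)
  cd <- ape::cophenetic.phylo(btr)
  expect_lt(cd["s1", "s2"], 1e-9)
  expect_lt(cd["s1", "s3"], 1e-9)

  # two species: a single split carrying the full gower distance
  pair <- trait_table(data.frame(x = c(0, 1), row.names = c("p", "q")))
  expect_equal(total_length(functional_tree(pair)), 1)
})

test_that("trait tables read from CSV + YAML config", {
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines("species,size,web\nsp1,1.5,orb\nsp2,3.0,sheet\nsp3,2.2,orb", csv)
  writeLines("traits:\n  size: {type: numeric, weight: 1}\n  web: {type: categorical, weight: 0.5}",
             yml)
  tt <- read_trait_table(csv, yml)
  expect_s3_class(tt, "trait_table")
  expect_equal(attr(tt, "weights"), c(size = 1, web = 0.5))
  expect_equal(rownames(tt), c("sp1", "sp2", "sp3"))
  d <- gower_distance(tt)
  # sp1 vs sp3: numeric only differs: (0.7/1.5 * 1 + 0 * 0.5) / 1.5
  expect_equal(d["sp1", "sp3"], (0.7 / 1.5) / 1.5, tolerance = 1e-10)
})
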