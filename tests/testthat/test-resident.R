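test_that("one life-cycle step conserves frequencies and respects symmetry", {
  ft <- fitness_table(fitness_spec(S = 0.1, theta = 0.5, phi = 0.3, k = 2))
  gt <- gamete_tensor(linkage_map(k = 2, r = 0.2))
  set.seed(42)
  x1 <- runif(4); x1 <- x1 / sum(x1)
  x2 <- runif(4); x2 <- x2 / sum(x2)
  nxt <- life_cycle_step(x1, x2, ft, gt, m = 0.05)
  expect_equal(sum(nxt$x1), 1, tolerance = 1e-12)
  expect_equal(sum(nxt$x2), 1, tolerance = 1e-12)
  expect_true(all(nxt$x1 >= 0 & nxt$x2 >= 0))
  expect_error(life_cycle_step(2 * x1, x2, ft, gt, 0.05), "sum to 1")

  # neutral fitness, no migration: allele frequencies at every locus conserved
  ft1 <- ft
  ft1$W <- list(matrix(1, 4, 4), matrix(1, 4, 4))
  B <- migmod:::all_haplotypes(2)
  neutral <- life_cycle_step(x1, x2, ft1, gt, m = 0)
  expect_equal(colSums(neutral$x1 * B), colSums(x1 * B), tolerance = 1e-12)
  expect_equal(colSums(neutral$x2 * B), colSums(x2 * B), tolerance = 1e-12)

  # mirror-symmetric demes stay mirror images under symmetric parameters
  ftsym <- fitness_table(fitness_spec(S = 0.1, theta = 0, phi = 0, k = 2))
  comp <- 4:1
  xs <- c(0.7, 0.12, 0.08, 0.1)
  mir <- life_cycle_step(xs, xs[comp], ftsym, gt, m = 0.05)
  expect_equal(mir$x1, mir$x2[comp], tolerance = 1e-12)
  expect_equal(mir$w_bar[1], mir$w_bar[2], tolerance = 1e-12)
})

test_that("the recursion matches a genotype-space one-locus oracle", {
  for (prm in list(list(S = 0.1, m = 0.05, theta = 0, phi = 0),
                   list(S = 0.25, m = 0.1, theta = 1.2, phi = -0.7))) {
    ft <- fitness_table(fitness_spec(S = prm$S, theta = prm$theta,
                                     phi = prm$phi, k = 1))
    gt <- gamete_tensor(linkage_map(k = 1))
    x1 <- c(0.2, 0.8)   # haplotype order: allele 0, allele 1
    x2 <- c(0.9, 0.1)
    p <- c(x1[2], x2[2])
    for (gen in 1:60) {
      nxt <- life_cycle_step(x1, x2, ft, gt, m = prm$m)
      orc <- oracle_onelocus_step(p, prm$S, prm$m, prm$theta, prm$phi)
      expect_equal(c(nxt$x1[2], nxt$x2[2]), orc$p, tolerance = 1e-12)
      expect_equal(nxt$w_bar, orc$w_bar, tolerance = 1e-12)
      x1 <- nxt$x1; x2 <- nxt$x2; p <- orc$p
    }
  }
})

test_that("the recursion matches a naive triple-loop implementation (k = 2)", {
  ft <- fitness_table(fitness_spec(S = 0.15, theta = c(0.8, -0.3), phi = 0.5, k = 2))
  gt <- gamete_tensor(linkage_map(k = 2, r = 0.17))
  m <- c(0.04, 0.09)
  set.seed(7)
  x <- list(runif(4), runif(4))
  x <- lapply(x, function(v) v / sum(v))
  nxt <- life_cycle_step(x[[1]], x[[2]], ft, gt, m)
  for (d in 1:2) {
    e <- 3 - d
    xprime <- numeric(4)
    for (i in 1:4) {
      for (j in 1:4) for (l in 1:4) {
        xprime[i] <- xprime[i] + ft$W[[d]][j, l] *
          (x[[d]][j] * x[[d]][l] * (1 - m[d]) + x[[e]][j] * x[[e]][l] * m[e]) *
          gt$G[i, j, l]
      }
    }
    expect_equal(nxt$w_bar[d], sum(xprime), tolerance = 1e-14)
    expect_equal(if (d == 1) nxt$x1 else nxt$x2, xprime / sum(xprime),
                 tolerance = 1e-14)
  }
})

test_that("baseline equilibrium is converged, polymorphic, and symmetric", {
  eq <- solve_equilibrium(k = 2, tol = 1e-12, max_gen = 20000)
  expect_true(eq$converged)
  expect_true(check_polymorphic(eq))
  L <- migration_load(eq)
  expect_gt(L[1], 0)
  expect_lt(abs(L[1] - L[2]), 1e-8)
  expect_true(all(eq$w_bar >= 0.9 & eq$w_bar <= 1))
  # deme 2 is the allele-complement mirror of deme 1
  expect_lt(max(abs(eq$x[[1]] - rev(eq$x[[2]]))), 1e-8)
  # fixed point: one more generation moves nothing
  ft <- fitness_table(fitness_spec(S = 0.1, theta = 0, phi = 0, k = 2))
  gt <- gamete_tensor(linkage_map(k = 2, r = 0.5))
  nxt <- life_cycle_step(eq$x[[1]], eq$x[[2]], ft, gt, m = 0.05)
  expect_lt(max(abs(nxt$x1 - eq$x[[1]])), 1e-11)
})

test_that("no migration fixes each deme on its favored haplotype", {
  eq <- solve_equilibrium(k = 2, m = 0, tol = 1e-10)
  expect_true(eq$converged)
  expect_equal(eq$x[[1]][4], 1, tolerance = 1e-6)
  expect_equal(eq$x[[2]][1], 1, tolerance = 1e-6)
  expect_equal(unname(migration_load(eq)), c(0, 0), tolerance = 1e-6)
  expect_false(check_polymorphic(eq))
})

test_that("the stable equilibrium does not depend on the random start", {
  eq1 <- solve_equilibrium(k = 2, tol = 1e-10, seed = 1)
  eq1b <- solve_equilibrium(k = 2, tol = 1e-10, seed = 1, cache = FALSE)
  expect_identical(eq1$x, eq1b$x)   # same seed: bitwise identical
  eq2 <- solve_equilibrium(k = 2, tol = 1e-10, seed = 999)
  expect_equal(eq1$x[[1]], eq2$x[[1]], tolerance = 1e-6)
  expect_equal(eq1$w_bar, eq2$w_bar, tolerance = 1e-8)
})

test_that("unconverged runs are flagged, not raised", {
  expect_warning(
    eq <- solve_equilibrium(k = 2, max_gen = 3, cache = FALSE) |> migration_load(),
    "not converged"
  )
})

test_that("tidiers and exports expose the equilibrium", {
  eq <- solve_equilibrium(k = 2)
  td <- tidy(eq)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 8L)
  expect_equal(sum(td$frequency), 2, tolerance = 1e-10)
  gl <- glance(eq)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_true(gl$polymorphic)
  tmp_csv <- withr::local_tempfile(fileext = ".csv")
  tmp_json <- withr::local_tempfile(fileext = ".json")
  write_equilibrium(eq, tmp_csv, tmp_json)
  back <- readr::read_csv(tmp_csv, show_col_types = FALSE)
  expect_equal(back$frequency, td$frequency)
  meta <- jsonlite::read_json(tmp_json)
  expect_equal(meta$k, 2)
  expect_true(meta$converged)
})
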