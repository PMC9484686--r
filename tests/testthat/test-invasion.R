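test_that("a null modifier is exactly neutral", {
  for (prm in list(list(k = 1, S = 0.1, m = 0.05),
                   list(k = 2, S = 0.2, m = 0.1),
                   list(k = 3, S = 0.1, m = 0.02))) {
    eq <- solve_equilibrium(k = prm$k, S = prm$S, m = prm$m, tol = 1e-11)
    inv <- invasion_analysis(eq)
    expect_equal(inv$lambda, 1, tolerance = 1e-8)
    expect_identical(inv$type, "null")
  }
  # an unlinked but otherwise-null modifier is still neutral
  eq <- solve_equilibrium(k = 2, tol = 1e-11)
  inv <- invasion_analysis(eq, modifier_spec(r_m_hat = 0.5))
  expect_equal(inv$lambda, 1, tolerance = 1e-8)
})

test_that("reproduction blocks transmit the modifier Mendelianly", {
  eq <- solve_equilibrium(k = 2, tol = 1e-10)
  for (rm in c(0, 0.2, 0.5)) {
    gt_mut <- gamete_tensor(linkage_map(k = 2, r = 0.5, r_m = rm))
    R1 <- migmod:::build_reproduction_block(eq$x[[1]], gt_mut, 2L)
    # each carrier adult passes the modifier to half its two gametes
    expect_equal(unname(rowSums(R1)), rep(1, 16), tolerance = 1e-12)
    expect_true(all(R1 >= 0))
  }
})

test_that("dispersal blocks place carriers where the mutant rates send them", {
  R1 <- matrix(1:4 / 10, 2, 2)
  R2 <- matrix(5:8 / 10, 2, 2)
  D0 <- migmod:::build_dispersal_block(R1, R2, c(0, 0))
  expect_equal(D0[1:2, 3:4], matrix(0, 2, 2))
  expect_equal(D0[3:4, 1:2], matrix(0, 2, 2))
  D1 <- migmod:::build_dispersal_block(R1, R2, c(1, 1))
  expect_equal(D1[1:2, 1:2], matrix(0, 2, 2))
  expect_equal(D1[1:2, 3:4], R1)
})

test_that("the selection vector reflects only the loci a modifier touches", {
  eq <- solve_equilibrium(k = 2, tol = 1e-10)
  f_null <- migmod:::build_selection_vector(eq, migmod:::resolve_modifier(eq, modifier_spec()))
  # a fully adapted carrier genotype in deme 1 beats the deme mean
  # state (mu = 11, rho = 11) in deme 1 sits at position 4*3 + 3 + 1 = 16
  expect_gt(f_null[16], 1)
  # a dominance modifier of locus 2 only changes states heterozygous at locus 2
  hat <- migmod:::resolve_modifier(eq, modifier_spec(theta_hat = 5, affected_loci = 2L))
  f_dom <- migmod:::build_selection_vector(eq, hat)
  B <- migmod:::all_haplotypes(2)
  state_het2 <- as.vector(outer(B[, 2], B[, 2], "!="))  # rho fastest, per deme
  changed <- abs(f_dom - f_null) > 1e-14
  expect_identical(unname(changed), rep(state_het2, 2))
  # an S_hat = 0 modifier makes every carrier load-free before normalisation
  hat0 <- migmod:::resolve_modifier(eq, modifier_spec(S_hat = 0))
  f0 <- migmod:::build_selection_vector(eq, hat0)
  expect_equal(f0, rep(1 / eq$w_bar, each = 16), tolerance = 1e-12)
})

test_that("eigenvalues agree with an independent power iteration", {
  eq <- solve_equilibrium(k = 2, tol = 1e-10)
  mods <- list(modifier_spec(phi_hat = 10),
               modifier_spec(theta_hat = 10),
               modifier_spec(r_hat = 0, r_m_hat = 0),
               modifier_spec(m_hat = 0))
  for (mod in mods) {
    A <- invasion_matrix(eq, mod)
    expect_equal(dominant_eigenvalue(A, method = "eigen"),
                 oracle_power_lambda(A), tolerance = 1e-8)
    expect_equal(dominant_eigenvalue(A, method = "power"),
                 dominant_eigenvalue(A, method = "eigen"), tolerance = 1e-8)
  }
})

test_that("eigenvalues match the full nonlinear invasion simulation", {
  eq1 <- solve_equilibrium(k = 1, tol = 1e-12, max_gen = 20000)
  eq2 <- solve_equilibrium(k = 2, tol = 1e-12, max_gen = 20000)
  cases <- list(
    list(eq1, modifier_spec()),
    list(eq1, modifier_spec(m_hat = 0)),
    list(eq2, modifier_spec(phi_hat = 10)),
    list(eq2, modifier_spec(theta_hat = 10)),
    list(eq2, modifier_spec(theta_hat = 10, affected_loci = 2L)),
    list(eq2, modifier_spec(r_hat = 0, r_m_hat = 0)),
    list(eq2, modifier_spec(S_hat = 0.05))
  )
  for (cs in cases) {
    lam <- invasion_analysis(cs[[1]], cs[[2]])$lambda
    expect_equal(lam, oracle_modifier_growth(cs[[1]], cs[[2]]), tolerance = 1e-4)
  }
})

test_that("no bounded modifier beats the theoretical maximum", {
  eq <- solve_equilibrium(k = 2, tol = 1e-10)
  bound <- theoretical_max(eq)
  # symmetric demes: the bound is L / (1 - L)
  L <- mean(eq$load)
  expect_equal(bound, L / (1 - L), tolerance = 1e-9)
  mods <- list(modifier_spec(), modifier_spec(phi_hat = 10),
               modifier_spec(theta_hat = 10), modifier_spec(theta_hat = -10),
               modifier_spec(r_hat = 0, r_m_hat = 0), modifier_spec(m_hat = 0),
               modifier_spec(S_hat = 0.02))
  for (mod in mods) {
    inv <- invasion_analysis(eq, mod)
    expect_lte(inv$selection, bound + 1e-9)
  }
  # the cost-erasing modifier attains the bound exactly
  inv0 <- invasion_analysis(eq, modifier_spec(S_hat = 0))
  expect_equal(inv0$selection, bound, tolerance = 1e-10)
})

test_that("continent-island inversions approach the load-minus-migration rule", {
  # one-way migration from continent (deme 2) onto the island (deme 1),
  # additive multiplicative fitness; weak migration
  eq <- solve_equilibrium(k = 2, m = c(0, 0.01), tol = 1e-11, max_gen = 20000)
  inv <- invasion_analysis(eq, modifier_spec(r_hat = 0, r_m_hat = 0))
  L <- eq$load[1]
  expect_gt(inv$selection, 0)
  # first-order rule: within 20% at m = 0.01
  expect_equal(inv$selection, L - 0.01, tolerance = 0.2)
})

test_that("invasion requires a converged resident and reports structure", {
  bad <- solve_equilibrium(k = 2, max_gen = 2, cache = FALSE)
  expect_error(invasion_analysis(bad, modifier_spec()), "not converged")
  eq <- solve_equilibrium(k = 2, tol = 1e-10)
  inv <- invasion_analysis(eq, modifier_spec(phi_hat = 10), keep_matrix = TRUE)
  expect_identical(dim(inv$A), c(32L, 32L))   # 2^(2k+1)
  expect_identical(inv$type, "epistasis")
  td <- tidy(inv)
  expect_identical(nrow(td), 1L)
  expect_equal(td$lambda - 1, td$selection)
  gl <- glance(inv)
  expect_true(all(c("k", "S", "type", "selection", "selection_max") %in% names(gl)))
})
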