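test_that("reaction terms at the origin reduce to baseline production", {
  p <- random_params(11)
  sys <- build_system(p, "U:AB,V:AB")
  expect_equal(eval_reaction_terms(sys, rep(0, 4)), unname(sys$alpha),
               ignore_attr = TRUE)
})

test_that("with gamma = 0 the reaction terms are linear", {
  p <- random_params(12)
  for (k in rate_keys()) p$rates[[k]]["gamma"] <- 0
  p <- validate_params(p)
  sys <- build_system(p, "U:AB,V:AB")
  s <- c(0.4, 1.2, 0.05, 2.2)
  expect_equal(eval_reaction_terms(sys, s),
               unname(sys$alpha - sys$beta * s), ignore_attr = TRUE)
})

test_that("diploid reaction terms match a term-by-term transcription", {
  # independent oracle: each of the four equations written out directly from
  # the allele-resolved rate and binding tables
  for (seed in c(13, 14)) {
    p <- random_params(seed)
    sys <- build_diploid_system(p, "U:AB,V:AB")
    set.seed(seed + 100)
    st <- runif(4, 0, 3)
    r <- eval_reaction_terms(sys, st)
    kap <- p$kappa
    hill <- function(num, den_v) (num / (1 + num + den_v))^2
    # species u: allele A activator
    expect_equal(r[1], unname(
      p$rates$u_A["alpha"] - p$rates$u_A["beta"] * st[1] +
        p$rates$u_A["gamma"] *
        hill(kap["uu_AA"] * st[1] + kap["uu_AB"] * st[3],
             kap["uv_AA"] * st[2] + kap["uv_AB"] * st[4])))
    # species v: allele A inhibitor
    expect_equal(r[2], unname(
      p$rates$v_A["alpha"] - p$rates$v_A["beta"] * st[2] +
        p$rates$v_A["gamma"] *
        hill(kap["vu_AA"] * st[1] + kap["vu_AB"] * st[3],
             kap["vv_AA"] * st[2] + kap["vv_AB"] * st[4])))
    # species uh: allele B activator (trans binding first)
    expect_equal(r[3], unname(
      p$rates$u_B["alpha"] - p$rates$u_B["beta"] * st[3] +
        p$rates$u_B["gamma"] *
        hill(kap["uu_BA"] * st[1] + kap["uu_BB"] * st[3],
             kap["uv_BA"] * st[2] + kap["uv_BB"] * st[4])))
    # species vh: allele B inhibitor
    expect_equal(r[4], unname(
      p$rates$v_B["alpha"] - p$rates$v_B["beta"] * st[4] +
        p$rates$v_B["gamma"] *
        hill(kap["vu_BA"] * st[1] + kap["vu_BB"] * st[3],
             kap["vv_BA"] * st[2] + kap["vv_BB"] * st[4])))
  }
})

test_that("reaction terms reject dimension mismatch and negative state", {
  p <- random_params(15)
  sys <- build_system(p, "U:AB,V:AB")
  expect_error(eval_reaction_terms(sys, c(1, 2)), "length")
  expect_error(eval_reaction_terms(sys, c(1, -0.1, 1, 1)), "negative")
})

test_that("homozygous parents have identical equations for the two haplotypes", {
  p <- random_params(16)
  sysA <- build_diploid_system(p, "U:AA,V:AA")
  st <- c(0.3, 0.8, 0.3, 0.8)
  r <- eval_reaction_terms(sysA, st)
  expect_equal(r[1], r[3])
  expect_equal(r[2], r[4])
  # parent B is parent A with B substituted everywhere
  sysB <- build_diploid_system(p, "U:BB,V:BB")
  expect_equal(unname(sysB$kappa_keys[1, 1]), "uu_BB")
  expect_true(all(substr(as.vector(sysB$kappa_keys), 4, 5) == "BB"))
})

test_that("contraction doubles zeroth-order rates and keeps beta", {
  p <- random_params(17)
  full <- build_diploid_system(p, "U:AA,V:AA")
  con <- contract_system(full)
  expect_equal(n_species(con), 2)
  expect_equal(con$alpha, 2 * full$alpha[1:2], ignore_attr = TRUE)
  expect_equal(con$gamma, 2 * full$gamma[1:2], ignore_attr = TRUE)
  expect_equal(con$beta, full$beta[1:2], ignore_attr = TRUE)
  # singly heterozygous genotype keeps the split locus
  c3 <- build_system(p, "U:AB,V:BB")
  expect_equal(n_species(c3), 3)
  expect_setequal(c3$species, c("u", "uh", "vb"))
  vb <- which(c3$species == "vb")
  expect_equal(unname(c3$alpha[vb]), 2 * unname(p$rates$v_B["alpha"]))
  expect_equal(unname(c3$gamma[vb]), 2 * unname(p$rates$v_B["gamma"]))
  # the doubly heterozygous system contracts to itself
  f1 <- build_diploid_system(p, "U:AB,V:AB")
  expect_identical(contract_system(f1), f1)
})

test_that("contracted reaction terms equal the summed full-system terms", {
  # on the symmetric manifold (equal split across haplotypes) the contracted
  # rate of each merged species is the sum of its copies' rates
  p <- random_params(18)
  for (g in c("U:AA,V:AA", "U:BB,V:AA", "U:AB,V:BB")) {
    full <- build_diploid_system(p, g)
    con <- contract_system(full)
    set.seed(18)
    s <- runif(n_species(con), 0.1, 2)
    # expand contracted state: merged species split evenly over the pair
    expand <- vapply(seq_len(4), function(i) {
      sp <- full$species[i]
      merged <- (sp %in% c("u", "uh") && !"u" %in% con$species) ||
        (sp %in% c("v", "vh") && !"v" %in% con$species)
      if (sp %in% c("u", "uh")) {
        j <- which(con$species %in% c("ub", "u", "uh"))
        if (merged) s[which(con$species == "ub")] / 2
        else s[which(con$species == sp)]
      } else {
        if (merged) s[which(con$species == "vb")] / 2
        else s[which(con$species == sp)]
      }
    }, 0)
    rc <- eval_reaction_terms(con, s)
    rf <- eval_reaction_terms(full, expand)
    for (j in seq_len(n_species(con))) {
      sp <- con$species[j]
      expect_equal(rc[j], switch(sp,
                                 ub = rf[1] + rf[3],
                                 vb = rf[2] + rf[4],
                                 u = rf[1], v = rf[2],
                                 uh = rf[3], vh = rf[4]),
                   tolerance = 1e-12)
    }
  }
})

test_that("full and contracted systems integrate to the same trajectories", {
  # independent integrator (deSolve::lsoda) on both descriptions; split
  # initial conditions evenly across the haplotype pair
  skip_if_not_installed("deSolve")
  p <- random_params(19)
  for (g in c("U:AA,V:BB", "U:AB,V:AA")) {
    full <- build_diploid_system(p, g)
    con <- contract_system(full)
    x0 <- con$alpha / con$beta * 1.7
    expand0 <- numeric(4)
    for (i in seq_len(4)) {
      sp <- full$species[i]
      tgt <- if (sp %in% c("u", "uh")) {
        if ("ub" %in% con$species) c("ub", 2) else c(sp, 1)
      } else {
        if ("vb" %in% con$species) c("vb", 2) else c(sp, 1)
      }
      expand0[i] <- x0[which(con$species == tgt[1])] / as.numeric(tgt[2])
    }
    rhs <- function(sys) function(t, y, parms)
      list(as.vector(mgturing:::reaction_rates(sys, matrix(pmax(y, 0), 1))))
    times <- seq(0, 20, by = 0.5)
    sol_c <- deSolve::lsoda(x0, times, rhs(con), rtol = 1e-10, atol = 1e-12)
    sol_f <- deSolve::lsoda(expand0, times, rhs(full), rtol = 1e-10,
                            atol = 1e-12)
    for (j in seq_len(n_species(con))) {
      sp <- con$species[j]
      summed <- switch(sp,
                       ub = sol_f[, 2] + sol_f[, 4],
                       vb = sol_f[, 3] + sol_f[, 5],
                       u = sol_f[, 2], v = sol_f[, 3],
                       uh = sol_f[, 4], vh = sol_f[, 5])
      expect_equal(sol_c[, j + 1], summed, tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("Hill terms stay in [0, 1) and rates are bounded below by -beta x", {
  for (seed in 21:25) {
    p <- random_params(seed)
    sys <- build_system(p, sample(enumerate_f2()$genotype, 1))
    set.seed(seed)
    for (i in 1:20) {
      st <- runif(n_species(sys), 0, 10^runif(1, -2, 2))
      hp <- mgturing:::hill_parts(sys, matrix(st, 1))
      expect_true(all(hp$H >= 0 & hp$H < 1))
      r <- eval_reaction_terms(sys, st)
      expect_true(all(r >= -sys$beta * st + unname(sys$alpha) - 1e-12))
    }
  }
})
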