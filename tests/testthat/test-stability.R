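test_that("with gamma = 0 the steady state is alpha/beta, unique, with J = -diag(beta)", {
  p <- random_params(31)
  for (k in rate_keys()) p$rates[[k]]["gamma"] <- 0
  p <- validate_params(p)
  sys <- build_system(p, "U:AB,V:AB")
  ss <- find_steady_state(sys)
  expect_true(ss$unique)
  expect_equal(unname(ss$concentrations), unname(sys$alpha / sys$beta),
               tolerance = 1e-9)
  J <- reaction_jacobian(sys, ss$concentrations)
  expect_equal(J, diag(-sys$beta, 4), ignore_attr = TRUE)
})

test_that("analytic Jacobian matches central finite differences on random systems", {
  n_checked <- 0
  for (seed in 41:75) {
    p <- random_params(seed)
    genos <- enumerate_f2()$genotype
    set.seed(seed)
    for (g in genos[sample.int(9, 3)]) {
      sys <- build_system(p, g)
      st <- runif(n_species(sys), 0.05, 3)
      J <- reaction_jacobian(sys, st)
      eps <- 1e-6
      Jfd <- vapply(seq_len(n_species(sys)), function(j) {
        e <- rep(0, n_species(sys)); e[j] <- eps
        (eval_reaction_terms(sys, st + e) -
           eval_reaction_terms(sys, st - e)) / (2 * eps)
      }, numeric(n_species(sys)))
      expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("the Jacobian of a symmetric homozygote commutes with the haplotype swap", {
  p <- random_params(32)
  sys <- build_diploid_system(p, "U:AA,V:AA")
  st <- c(0.4, 1.1, 0.4, 1.1)
  J <- reaction_jacobian(sys, st)
  P <- diag(4)[c(3, 4, 1, 2), ]  # u<->uh, v<->vh
  expect_equal(P %*% J, J %*% P, ignore_attr = TRUE)
})

test_that("contracted steady state is the componentwise sum of the full system's", {
  p <- mg_fixture("general")
  for (g in c("U:AA,V:AA", "U:BB,V:BB", "U:AB,V:BB")) {
    full <- build_diploid_system(p, g)
    con <- contract_system(full)
    ss_f <- find_steady_state(full)
    ss_c <- find_steady_state(con)
    for (j in seq_len(n_species(con))) {
      sp <- con$species[j]
      x <- ss_f$concentrations
      summed <- switch(sp, ub = x[["u"]] + x[["uh"]],
                       vb = x[["v"]] + x[["vh"]], x[[sp]])
      expect_equal(unname(ss_c$concentrations[j]), unname(summed),
                   tolerance = 1e-8)
    }
  }
})

test_that("a three-root system is flagged non-unique, confirmed by nullcline scan", {
  # deterministic scan for a multistable two-species draw in the
  # strong-autocatalysis regime of the search bounds
  set.seed(101)
  b <- default_search_bounds()
  found <- NULL
  for (try in 1:40) {
    dd <- mgturing:::draw_params_general(b)
    p <- mg_params(dd$rates, dd$kappa, 1, 20)
    for (g in c("U:AA,V:AA", "U:BB,V:BB")) {
      sys <- build_system(p, g)
      ss <- tryCatch(find_steady_state(sys), error = function(e) NULL)
      if (!is.null(ss) && !ss$unique && length(ss$roots) == 3) {
        found <- list(sys = sys, ss = ss)
        break
      }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  # oracle: scan u on a dense grid; solve the inhibitor nullcline for v by
  # bisection; count sign changes of the activator nullcline residual
  sys <- found$sys
  resid_u <- function(u) {
    g_of_v <- function(v) eval_reaction_terms(sys, c(u, v))[2]
    v <- stats::uniroot(g_of_v, c(0, 1e4), tol = 1e-12)$root
    eval_reaction_terms(sys, c(u, v))[1]
  }
  us <- exp(seq(log(1e-4), log(1e3), length.out = 2000))
  r <- vapply(us, resid_u, 0)
  expect_equal(sum(diff(sign(r)) != 0), 3)
})

test_that("dispersion relation behaves at its limits and flags unstable kinetics", {
  p <- mg_fixture("general")
  sys <- build_system(p, "U:AB,V:AB")
  ss <- find_steady_state(sys)
  J <- reaction_jacobian(sys, ss$concentrations)
  k <- c(0, 0.1, 1, 100)
  disp <- dispersion(sys, ss, d = 30, k = k)
  expect_equal(disp$growth_rate[1],
               max(Re(eigen(J, only.values = TRUE)$values)))
  expect_lt(disp$growth_rate[4], -1e3 * abs(disp$growth_rate[1]))
  # dominated by -k^2 D at large k
  # growth rates eventually decrease in k
  dense <- dispersion(sys, ss, d = 30,
                      k = seq(0.5, 5, length.out = 50))
  tail_gr <- dense$growth_rate[30:50]
  expect_true(all(diff(tail_gr) < 0))
  # a system whose kinetics are unstable is rejected
  bad <- diffusion_only_system()
  bad$alpha <- c(1, 1)
  bad$beta <- c(-0.1, 0.5)  # growing mode at k = 0
  expect_error(dispersion(bad, c(1, 1), d = 30), "stable")
  expect_error(critical_diffusion_ratio(bad, c(1, 1)), "stable")
})

test_that("positive-growth band edges match the closed-form 2-species criterion", {
  # independent oracle: for a 2x2 Jacobian the marginal wavenumbers solve
  # det(J - k^2 diag(Du, d Du)) = 0, a quadratic in k^2
  p <- mg_fixture("general")
  sys <- build_system(p, "U:BB,V:AA")   # Turing-unstable at fixture d
  ss <- find_steady_state(sys)
  d <- p$D_v / p$D_u
  J <- reaction_jacobian(sys, ss$concentrations)
  Du <- sys$D_u
  a2 <- d * Du^2
  a1 <- -(d * Du * J[1, 1] + Du * J[2, 2])
  a0 <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  k2roots <- sort(Re(polyroot(c(a0, a1, a2))))
  expect_true(all(abs(Im(polyroot(c(a0, a1, a2)))) < 1e-8))
  growth <- function(k) mgturing:::growth_at(J, c(Du, d * Du), k^2)
  for (k2 in k2roots) {
    k <- sqrt(k2)
    expect_lt(abs(growth(k)), 1e-8 * max(abs(J)))
    # growth is positive strictly inside the band
  }
  kmid <- sqrt(mean(k2roots))
  expect_gt(growth(kmid), 0)
  expect_lt(growth(sqrt(k2roots[1]) * 0.8), 0)
  expect_lt(growth(sqrt(k2roots[2]) * 1.2), 0)
})

test_that("d* brackets the Turing bifurcation and exceeds 1", {
  p <- mg_fixture("general")
  sys <- build_system(p, "U:AB,V:AB")
  ss <- find_steady_state(sys)
  dstar <- critical_diffusion_ratio(sys, ss)
  expect_gt(as.numeric(dstar), 1)
  eps <- 1e-4 * as.numeric(dstar)
  expect_gt(max_growth_rate(sys, ss, as.numeric(dstar) + eps)$value, 0)
  expect_lt(max_growth_rate(sys, ss, as.numeric(dstar) - eps)$value, 0)
  # a Turing-incapable direction returns the +Inf sentinel
  lin <- random_params(33)
  for (k in rate_keys()) lin$rates[[k]]["gamma"] <- 0
  lin <- validate_params(lin)
  lsys <- build_system(lin, "U:AA,V:AA")
  lss <- find_steady_state(lsys)
  expect_identical(critical_diffusion_ratio(lsys, lss), Inf)
})

test_that("admissibility requires allele-dependent parameters and d in the gap", {
  # allele-independent parameters: F1 identical to parents, no d separates
  p <- unit_params()
  rep <- check_admissibility(p, d = 20)
  expect_false(rep$verdict)

  fix <- mg_fixture("general")
  rep <- check_admissibility(fix)
  expect_true(rep$verdict)
  expect_lt(rep$d_star_F1, fix$D_v / fix$D_u)
  expect_gt(min(rep$d_star_A, rep$d_star_B), fix$D_v / fix$D_u)

  # relabeling the alleles exchanges the parent critical ratios
  swap_key <- function(k) chartr("AB", "BA", k)
  q <- fix
  q$rates <- setNames(fix$rates[swap_key(rate_keys())], rate_keys())
  q$kappa <- setNames(unname(fix$kappa[swap_key(kappa_keys())]), kappa_keys())
  q <- validate_params(q)
  rep_q <- check_admissibility(q)
  expect_equal(rep_q$d_star_A, rep$d_star_B, tolerance = 1e-5)
  expect_equal(rep_q$d_star_B, rep$d_star_A, tolerance = 1e-5)
  expect_equal(rep_q$d_star_F1, rep$d_star_F1, tolerance = 1e-5)
})

test_that("the admissible-set search is deterministic and reports rejections", {
  r1 <- search_admissible(seed = 20260930, max_tries = 50)
  r2 <- search_admissible(seed = 20260930, max_tries = 50)
  expect_equal(r1$params$kappa, r2$params$kappa)
  expect_equal(r1$params$D_v, r2$params$D_v)
  expect_equal(r1$tries, r2$tries)
  expect_true(r1$report$verdict)

  # degenerate bounds force allele-independent kappa: never admissible
  b <- default_search_bounds()
  b$kappa <- c(5, 5)
  expect_error(search_admissible(seed = 1, bounds = b, max_tries = 3),
               "identical to parents")
})
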